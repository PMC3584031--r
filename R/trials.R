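#' Specify one forced-choice trial
#'
#' An identification trial presents the correct word `C` together with the
#' appearances of `C` and of each rival, and asks which appearance belongs
#' to `C`.  A naming trial presents the appearance of `C` together with the
#' words `C` and the rivals, and asks which word the appearance belongs to.
#' The system additionally knows the appearances of the `known` words,
#' which are disjoint from `C` and the rivals.
#'
#' @param task `"identification"` or `"naming"`.
#' @param correct The correct word `C`.
#' @param rivals Character vector of rival words (>= 1), distinct from
#'   `correct` and from `known`.
#' @param known Character vector of already-known words (>= 2 for
#'   MIRRORING).
#' @param strategy `"mirroring"`, `"proxy"` or `"foil"`.
#' @param k Reference-set size for PROXY/FOIL (<= `length(known)`).
#' @param modality `"colour"`, `"texton"` or `"both"`.
#' @param seed Optional per-trial RNG seed (used only for tie-breaking).
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(task = c("identification", "naming"), correct, rivals,
                       known, strategy = c("mirroring", "proxy", "foil"),
                       k = NULL, modality = c("both", "colour", "texton"),
                       seed = NULL) {
  task <- match.arg(task)
  strategy <- match.arg(strategy)
  modality <- match.arg(modality)
  if (length(rivals) < 1) stop("at least one rival is required")
  if (correct %in% known || any(rivals %in% known) || correct %in% rivals)
    stop("correct word, rivals and known words must be disjoint")
  if (strategy %in% c("proxy", "foil")) {
    if (is.null(k)) stop("k is required for PROXY/FOIL")
    if (k > length(known)) stop("k must not exceed the number of known words")
  }
  structure(list(task = task, correct = correct, rivals = rivals,
                 known = known, strategy = strategy, k = k,
                 modality = modality, seed = seed), class = "trial_spec")
}

#' Candidate word-appearance pairings of a trial
#'
#' Candidate 1 is by convention the correct pairing; the decision functions
#' never see which one that is.
#'
#' @param spec A [trial_spec()].
#' @return Data frame with columns `word` and `appearance` (the category
#'   whose appearance set is used), one row per candidate.
#' @export
candidate_pairings <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  if (spec$task == "identification")
    data.frame(word = spec$correct,
               appearance = c(spec$correct, spec$rivals))
  else
    data.frame(word = c(spec$correct, spec$rivals),
               appearance = spec$correct)
}

#' MIRRORING score of one word-appearance pairing
#'
#' The Pearson correlation, across the known items `x`, between the
#' distributional distance from the pairing's word to `x` and the
#' appearance distance from the pairing's appearance to the appearance of
#' `x`.  A correct pairing tends to mirror better (more positive
#' correlation).  If either coordinate has zero variance the correlation is
#' undefined and the score is 0, so the trial resolves by tie-break.
#'
#' @param word,appearance The pairing: a word and the category whose
#'   appearance set it is paired with.
#' @param known Character vector of known words (>= 2).
#' @param models A `da_models`.
#' @param modality `"colour"` or `"texton"`.
#' @return Correlation in `[-1, 1]`.
#' @export
mirroring_score <- function(word, appearance, known, models,
                            modality = c("colour", "texton")) {
  modality <- match.arg(modality)
  if (length(known) < 2) stop("MIRRORING requires >= 2 known words")
  dw <- models$D_word[word, known]
  da <- models[[paste0("D_", modality)]][appearance, known]
  if (stats::sd(dw) == 0 || stats::sd(da) == 0) return(0)
  stats::cor(dw, da)
}

# Per-candidate scores (higher = preferred) in one modality under one
# strategy.  Internal fast path shared by run_trial() and the harness.
.candidate_scores <- function(models, task, correct, rivals, known,
                              strategy, k, modality) {
  unname(.candidate_scores_named(models, task, correct, rivals, known,
                                 strategy, k, modality))
}

.candidate_scores_named <- function(models, task, correct, rivals, known,
                                    strategy, k, modality) {
  Da <- models[[paste0("D_", modality)]]
  Dw <- models$D_word
  if (task == "identification") {
    cand_app <- c(correct, rivals)
    if (strategy == "mirroring") {
      dw <- Dw[correct, known]
      if (stats::sd(dw) == 0) return(numeric(length(cand_app)))
      vapply(cand_app, function(a) {
        da <- Da[a, known]
        if (stats::sd(da) == 0) 0 else stats::cor(dw, da)
      }, numeric(1))
    } else {
      ref <- .reference_set(Dw[correct, known], known, k, strategy)
      m <- vapply(cand_app, function(a) mean(Da[a, ref]), numeric(1))
      if (strategy == "proxy") -m else m
    }
  } else {
    cand_word <- c(correct, rivals)
    if (strategy == "mirroring") {
      da <- Da[correct, known]
      if (stats::sd(da) == 0) return(numeric(length(cand_word)))
      vapply(cand_word, function(w) {
        dw <- Dw[w, known]
        if (stats::sd(dw) == 0) 0 else stats::cor(dw, da)
      }, numeric(1))
    } else {
      ref <- .reference_set(Da[correct, known], known, k, strategy)
      m <- vapply(cand_word, function(w) mean(Dw[w, ref]), numeric(1))
      if (strategy == "proxy") -m else m
    }
  }
}

# The k nearest (proxy) or k most distant (foil) known items w.r.t. the
# given distances; ties resolved by stable order over `known`.
.reference_set <- function(dist_to_known, known, k, strategy) {
  ord <- order(dist_to_known, method = "radix")
  if (strategy == "foil") ord <- rev(ord)
  known[ord[seq_len(k)]]
}

# argmax with uniform random tie-break; returns list(chosen, tie)
.pick_max <- function(scores) {
  scores <- unname(scores)
  top <- which(scores == max(scores))
  if (length(top) == 1L) list(chosen = top, tie = FALSE)
  else list(chosen = top[sample.int(length(top), 1)], tie = TRUE)
}

#' Decide a trial from MIRRORING scores
#'
#' Chooses the candidate with the largest score; exact ties are broken
#' uniformly at random with the current RNG and flagged.
#'
#' @param scores Numeric vector, one score per candidate.
#' @return List with `chosen` (candidate index) and `tie`.
#' @export
decide_mirroring <- function(scores) .pick_max(scores)

#' Decide a trial with the PROXY strategy
#'
#' PROXY focuses on the most similar known items.  For identification the
#' reference set is the `k` known words distributionally closest to the
#' correct word, and each candidate appearance is scored by its mean
#' appearance distance to those `k` appearance sets (smallest wins).  For
#' naming the reference set is the `k` known appearance sets closest to the
#' trial appearance, and each candidate word is scored by its mean
#' distributional distance to those `k` words (smallest wins).
#'
#' @param spec A [trial_spec()] (its `strategy` field is ignored here).
#' @param models A `da_models`.
#' @param modality `"colour"` or `"texton"`.
#' @return List with `chosen`, `tie` and the per-candidate `scores`
#'   (negated mean distances, so higher = preferred).
#' @export
decide_proxy <- function(spec, models, modality = c("colour", "texton")) {
  modality <- match.arg(modality)
  if (spec$k > length(spec$known)) stop("k exceeds the number of known words")
  s <- .candidate_scores(models, spec$task, spec$correct, spec$rivals,
                         spec$known, "proxy", spec$k, modality)
  c(.pick_max(s), list(scores = s))
}

#' Decide a trial with the FOIL strategy
#'
#' FOIL focuses on the most dissimilar known items: the reference set is
#' the `k` most distant known items, and the candidate with the LARGEST
#' mean distance to that set is chosen (what looks least like the foils is
#' taken to be the unfamiliar target).
#'
#' @inheritParams decide_proxy
#' @return List with `chosen`, `tie` and the per-candidate `scores` (mean
#'   distances to the foil set, higher = preferred).
#' @export
decide_foil <- function(spec, models, modality = c("colour", "texton")) {
  modality <- match.arg(modality)
  if (spec$k > length(spec$known)) stop("k exceeds the number of known words")
  s <- .candidate_scores(models, spec$task, spec$correct, spec$rivals,
                         spec$known, "foil", spec$k, modality)
  c(.pick_max(s), list(scores = s))
}

#' Combine colour- and texton-based answers
#'
#' Answers are computed separately per modality and the modality giving the
#' more unequivocal answer is followed: the margin of a modality is its top
#' score minus its runner-up score, and the larger margin wins.  (With
#' scores of 0.3/0.1 for colour and 0.4/0.5 for textons, colour's margin
#' 0.2 beats textons' 0.1, so the colour-based answer is followed.)  Equal
#' margins follow textons; remaining ties within the followed modality are
#' broken at random.
#'
#' @param colour_scores,texton_scores Per-candidate score vectors (higher
#'   = preferred) of equal length.
#' @return List with `chosen` (candidate index), `modality` followed, and
#'   `tie`.
#' @export
combine_modalities <- function(colour_scores, texton_scores) {
  stopifnot(length(colour_scores) == length(texton_scores),
            length(colour_scores) >= 2)
  margin <- function(s) {
    o <- sort(s, decreasing = TRUE)
    o[1] - o[2]
  }
  use <- if (margin(colour_scores) > margin(texton_scores)) "colour"
         else "texton"
  pick <- .pick_max(if (use == "colour") colour_scores else texton_scores)
  list(chosen = pick$chosen, modality = use, tie = pick$tie)
}

#' Run one forced-choice trial
#'
#' Builds the candidate pairings, computes per-candidate scores per
#' modality under the requested strategy, combines modalities when
#' `modality = "both"`, and records the outcome.  Deterministic given the
#' RNG state (or `spec$seed`) -- randomness enters only through
#' tie-breaking.
#'
#' @param spec A [trial_spec()].
#' @param models A `da_models`.
#' @return A list of class `trial_outcome`: `chosen` (candidate index;
#'   1 is the correct pairing), `correct`, `scores` (matrix, candidates x
#'   modalities), `modality_used`, `tie`.
#' @export
run_trial <- function(spec, models) {
  stopifnot(inherits(spec, "trial_spec"), inherits(models, "da_models"))
  all_w <- c(spec$correct, spec$rivals, spec$known)
  missing <- setdiff(all_w, models$words)
  if (length(missing))
    stop("words not in the models: ", paste(missing, collapse = ", "))
  if (spec$strategy == "mirroring" && length(spec$known) < 2)
    stop("MIRRORING requires >= 2 known words")
  if (!is.null(spec$seed)) set.seed(spec$seed)

  mods <- if (spec$modality == "both") c("colour", "texton") else spec$modality
  scores <- vapply(mods, function(m)
    .candidate_scores(models, spec$task, spec$correct, spec$rivals,
                      spec$known, spec$strategy, spec$k, m),
    numeric(1 + length(spec$rivals)))
  if (spec$modality == "both") {
    dec <- combine_modalities(scores[, "colour"], scores[, "texton"])
  } else {
    pick <- .pick_max(scores[, 1])
    dec <- list(chosen = pick$chosen, modality = spec$modality,
                tie = pick$tie)
  }
  structure(list(chosen = dec$chosen, correct = dec$chosen == 1L,
                 scores = scores, modality_used = dec$modality,
                 tie = dec$tie), class = "trial_outcome")
}
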