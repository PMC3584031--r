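#' Run a batch of randomly sampled trials
#'
#' For every trial a fresh known set, correct word `C` and rival(s) `R` are
#' drawn without replacement from the model's categories, the trial is
#' decided, and one log row is recorded.  The log retains everything needed
#' to re-decide the trials (for image-level bootstrap resampling).
#'
#' @param models A `da_models`.
#' @param n_trials Number of trials.
#' @param n_known Number of already-known appearances per trial.
#' @param task `"identification"` or `"naming"`.
#' @param strategy `"mirroring"`, `"proxy"` or `"foil"`.
#' @param modality `"both"`, `"colour"` or `"texton"`.
#' @param m_rivals Number of rivals (default 1).
#' @param k PROXY/FOIL reference-set size; capped at `n_known`.
#' @param seed Optional RNG seed.
#' @return Data frame with one row per trial: `task`, `n_known`,
#'   `strategy`, `modality`, `C`, `correct`, `tie`, `modality_used`, plus
#'   list-columns `rivals` and `known`.
#' @export
run_trials <- function(models, n_trials, n_known,
                       task = c("identification", "naming"),
                       strategy = c("mirroring", "proxy", "foil"),
                       modality = c("both", "colour", "texton"),
                       m_rivals = 1, k = 4, seed = NULL) {
  task <- match.arg(task)
  strategy <- match.arg(strategy)
  modality <- match.arg(modality)
  if (!is.null(seed)) set.seed(seed)
  W <- models$words
  V <- length(W)
  if (n_known + 1 + m_rivals > V)
    stop(sprintf("n_known = %d with %d rival(s) needs > %d categories",
                 n_known, m_rivals, n_known + m_rivals))
  if (strategy == "mirroring" && n_known < 2)
    stop("MIRRORING requires n_known >= 2")
  k_use <- min(k, n_known)
  mods <- if (modality == "both") c("colour", "texton") else modality

  C_col <- character(n_trials)
  correct <- tie <- logical(n_trials)
  mod_used <- character(n_trials)
  rivals_l <- known_l <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    sel <- sample(W, n_known + 1L + m_rivals)
    known <- sel[seq_len(n_known)]
    C <- sel[n_known + 1L]
    R <- sel[(n_known + 2L):(n_known + 1L + m_rivals)]
    sc <- vapply(mods, function(m)
      .candidate_scores(models, task, C, R, known, strategy, k_use, m),
      numeric(1L + m_rivals))
    dec <- if (modality == "both")
      combine_modalities(sc[, "colour"], sc[, "texton"])
    else c(.pick_max(sc[, 1]), list(modality = modality))
    C_col[t] <- C
    correct[t] <- dec$chosen == 1L
    tie[t] <- dec$tie
    mod_used[t] <- dec$modality
    rivals_l[[t]] <- R
    known_l[[t]] <- known
  }
  out <- data.frame(task = task, n_known = n_known, strategy = strategy,
                    modality = modality, C = C_col, correct = correct,
                    tie = tie, modality_used = mod_used,
                    stringsAsFactors = FALSE)
  out$rivals <- rivals_l
  out$known <- known_l
  out$k <- if (strategy == "mirroring") NA_integer_ else k_use
  out
}

# Re-decide every logged trial against (possibly perturbed) models.
.redecide <- function(log, models) {
  vapply(seq_len(nrow(log)), function(t) {
    mods <- if (log$modality[t] == "both") c("colour", "texton")
            else log$modality[t]
    sc <- vapply(mods, function(m)
      .candidate_scores(models, log$task[t], log$C[t], log$rivals[[t]],
                        log$known[[t]], log$strategy[t], log$k[t], m),
      numeric(1L + length(log$rivals[[t]])))
    dec <- if (log$modality[t] == "both")
      combine_modalities(sc[, "colour"], sc[, "texton"])
    else .pick_max(sc[, 1])
    dec$chosen == 1L
  }, logical(1))
}

#' Correct-rate curve over a grid of known-set sizes
#'
#' @param models A `da_models`.
#' @param grid Integer vector of known-set sizes, e.g. `c(2, 4, 8, 16)`.
#'   Defaults to powers of two up to the vocabulary minus two.
#' @param n_trials Trials per grid point (default 1000).
#' @param tasks,strategies Conditions to cross with the grid.
#' @param modality,m_rivals,k,seed As in [run_trials()].
#' @return Data frame with one row per (grid point, task, strategy):
#'   `n_known`, `task`, `strategy`, `modality`, `n_trials`, `rate`.
#' @export
performance_curve <- function(models, grid = NULL, n_trials = 1000,
                              tasks = c("identification", "naming"),
                              strategies = "mirroring", modality = "both",
                              m_rivals = 1, k = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- length(models$words)
  if (is.null(grid)) {
    grid <- 2^(1:20)
    grid <- unique(c(grid[grid < V - m_rivals], V - 1L - m_rivals))
  }
  if (max(grid) + 1 + m_rivals > V)
    stop("largest grid value too large for the vocabulary")
  rows <- list()
  for (task in tasks) for (strategy in strategies) for (nk in grid) {
    log <- run_trials(models, n_trials, nk, task, strategy, modality,
                      m_rivals, k)
    rows[[length(rows) + 1L]] <-
      data.frame(n_known = nk, task = task, strategy = strategy,
                 modality = modality, n_trials = n_trials,
                 rate = mean(log$correct))
  }
  do.call(rbind, rows)
}

#' Percentile bootstrap interval for a correct rate
#'
#' Resamples any subset of three axes: `"words"` (the identities of the
#' correct words are resampled with replacement and each bootstrap rate is
#' computed over the trials of the sampled words), `"images"` (every
#' appearance set is resampled with replacement at the image level and all
#' trials are re-decided; requires `models`), and `"trials"` (trial rows
#' are resampled with replacement).
#'
#' @param log A trial log from [run_trials()].
#' @param axes Subset of `c("trials", "words", "images")`.
#' @param n_boot Number of bootstrap replicates (>= 2; default 500).
#' @param level Confidence level (default 0.95).
#' @param models The `da_models` the log was produced with (required for
#'   the images axis).
#' @param seed Optional RNG seed.
#' @return List with `lower`, `upper`, `level`, `rate` (observed) and the
#'   bootstrap `rates`.
#' @export
bootstrap_ci <- function(log, axes = c("trials", "words", "images"),
                         n_boot = 500, level = 0.95, models = NULL,
                         seed = NULL) {
  axes <- match.arg(axes, several.ok = TRUE)
  if (nrow(log) == 0) stop("empty trial log")
  if (n_boot < 2) stop("n_boot must be >= 2")
  if ("images" %in% axes && is.null(models))
    stop("the images axis needs the `models` the log was produced with")
  if (!is.null(seed)) set.seed(seed)
  uw <- unique(log$C)
  rates <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    correct <- if ("images" %in% axes)
      .redecide(log, .resample_images(models)) else log$correct
    idx <- seq_len(nrow(log))
    if ("words" %in% axes) {
      sw <- sample(uw, length(uw), replace = TRUE)
      idx <- unlist(lapply(sw, function(w) which(log$C == w)),
                    use.names = FALSE)
    }
    if ("trials" %in% axes) idx <- sample(idx, length(idx), replace = TRUE)
    rates[b] <- mean(correct[idx])
  }
  q <- stats::quantile(rates, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  list(lower = q[1], upper = q[2], level = level, rate = mean(log$correct),
       rates = rates)
}

# Resample every appearance set with replacement at the image level and
# rebuild the appearance distance matrices.
.resample_images <- function(models) {
  pick <- unlist(lapply(split(seq_along(models$img_cat), models$img_cat),
                        function(r) sample(r, length(r), replace = TRUE)),
                 use.names = FALSE)
  out <- models
  out$sqrt_colour <- models$sqrt_colour[pick, , drop = FALSE]
  out$sqrt_texton <- models$sqrt_texton[pick, , drop = FALSE]
  out$img_cat <- models$img_cat[pick]
  n <- length(models$words)
  out$D_colour <- .set_distance_matrix(out$sqrt_colour, out$img_cat, n)
  out$D_texton <- .set_distance_matrix(out$sqrt_texton, out$img_cat, n)
  dimnames(out$D_colour) <- dimnames(out$D_texton) <-
    list(models$words, models$words)
  out
}

#' Permutation baseline of the correct rate
#'
#' Repeatedly permutes the assignment between words and appearance sets
#' and re-runs the evaluation; under permutation any true word-appearance
#' coupling is destroyed, so the mean rate estimates the chance level
#' (50% for one rival).
#'
#' @param models A `da_models`.
#' @param n_perm Number of permutations (>= 2).
#' @param n_trials Trials per permutation and task.
#' @param n_known Known-set size per trial.
#' @param tasks Tasks averaged within each permutation.
#' @param strategy,modality,m_rivals,k,seed As in [run_trials()].
#' @param shuffle Set to `FALSE` to keep the identity assignment (then the
#'   unpermuted rate is recovered).
#' @return List with `mean`, `sd` (across permutations) and the
#'   per-permutation `rates`.
#' @export
permutation_baseline <- function(models, n_perm = 10, n_trials = 1000,
                                 n_known = 32,
                                 tasks = c("identification", "naming"),
                                 strategy = "mirroring", modality = "both",
                                 m_rivals = 1, k = 4, seed = NULL,
                                 shuffle = TRUE) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  V <- length(models$words)
  rates <- vapply(seq_len(n_perm), function(p) {
    perm <- if (shuffle) sample.int(V) else seq_len(V)
    mp <- permute_appearances(models, perm)
    mean(vapply(tasks, function(task)
      mean(run_trials(mp, n_trials, n_known, task, strategy, modality,
                      m_rivals, k)$correct), numeric(1)))
  }, numeric(1))
  list(mean = mean(rates), sd = stats::sd(rates), rates = rates)
}

#' Word-specific correct rates
#'
#' For every word `C`, every other word takes the rival role `R` in turn,
#' for both the identification and the naming task, with all remaining
#' words as the known set (the maximal known set).  The identification and
#' naming rates are averaged together per word.
#'
#' @param models A `da_models`.
#' @param strategy,modality,k As in [run_trials()].
#' @param seed Optional RNG seed (tie-breaks only).
#' @return Data frame with columns `word` and `rate`.
#' @export
per_word_scores <- function(models, strategy = "mirroring",
                            modality = "both", k = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- models$words
  V <- length(W)
  if (V < 4) stop("need >= 4 categories")
  mods <- if (modality == "both") c("colour", "texton") else modality
  k_use <- min(k, V - 2L)
  rate <- vapply(W, function(C) {
    hits <- 0L
    n <- 0L
    for (R in setdiff(W, C)) {
      known <- setdiff(W, c(C, R))
      for (task in c("identification", "naming")) {
        sc <- vapply(mods, function(m)
          .candidate_scores(models, task, C, R, known, strategy, k_use, m),
          numeric(2))
        dec <- if (modality == "both")
          combine_modalities(sc[, "colour"], sc[, "texton"])
        else .pick_max(sc[, 1])
        hits <- hits + (dec$chosen == 1L)
        n <- n + 1L
      }
    }
    hits / n
  }, numeric(1))
  data.frame(word = W, rate = unname(rate), stringsAsFactors = FALSE)
}

#' Stratify word-specific rates by category and semantic depth
#'
#' Computes per-category mean rates with t confidence intervals, flags
#' categories whose mean differs significantly from the grand mean
#' (two-sided t test, alpha = 0.05, no multiplicity correction), and fits
#' an ordinary least-squares regression of the word rate on semantic depth
#' (hypernymy path length), reporting the slope with its t interval.
#'
#' @param per_word Data frame from [per_word_scores()].
#' @param lexicon Data frame with columns `word`, `category`, `depth`
#'   covering all scored words.
#' @param level Confidence level (default 0.95).
#' @return List with `categories` (data frame: `category`, `n`, `mean`,
#'   `lower`, `upper`, `flag` in `c("below", "ns", "above")`),
#'   `depth_slope`, `depth_ci`, and the fitted `model`.
#' @export
stratified_summary <- function(per_word, lexicon, level = 0.95) {
  stopifnot(all(c("word", "category", "depth") %in% names(lexicon)))
  if (!all(per_word$word %in% lexicon$word))
    stop("lexicon does not cover all scored words")
  df <- merge(per_word, lexicon, by = "word")
  grand <- mean(df$rate)
  cats <- lapply(split(df, df$category), function(g) {
    n <- nrow(g)
    m <- mean(g$rate)
    if (n >= 2 && stats::sd(g$rate) > 0) {
      tt <- stats::t.test(g$rate, mu = grand, conf.level = level)
      ci <- as.numeric(tt$conf.int)
      flag <- if (tt$p.value < 0.05) (if (m > grand) "above" else "below")
              else "ns"
    } else {
      ci <- c(NA_real_, NA_real_)
      flag <- "undefined"
    }
    data.frame(category = g$category[1], n = n, mean = m,
               lower = ci[1], upper = ci[2], flag = flag,
               stringsAsFactors = FALSE)
  })
  cats <- do.call(rbind, c(cats, make.row.names = FALSE))
  fit <- stats::lm(rate ~ depth, data = df)
  ci <- stats::confint(fit, "depth", level = level)
  list(categories = cats,
       depth_slope = unname(stats::coef(fit)["depth"]),
       depth_ci = as.numeric(ci), model = fit)
}

#' Correct rate as a function of the number of rivals
#'
#' @param models A `da_models`.
#' @param rival_counts Integer vector of rival counts `m`.
#' @param n_known Known-set size per trial.
#' @param n_trials Trials per rival count.
#' @param task,strategy,modality,k,seed As in [run_trials()].
#' @return Data frame with columns `m_rivals`, `chance` (`1/(m+1)`),
#'   `rate`, `n_trials`.
#' @export
multi_rival_curve <- function(models, rival_counts, n_known,
                              n_trials = 1000, task = "identification",
                              strategy = "mirroring", modality = "both",
                              k = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(rival_counts, function(m) {
    log <- run_trials(models, n_trials, n_known, task, strategy, modality,
                      m_rivals = m, k = k)
    data.frame(m_rivals = m, chance = 1 / (m + 1), rate = mean(log$correct),
               n_trials = n_trials)
  })
  do.call(rbind, rows)
}

#' Search for the most informative quadruple of known appearances
#'
#' Samples `n_candidates` quadruples of known words at random (each
#' quadruple drawn without replacement) and evaluates the identification
#' rate for each with the remaining words as the (C, R) pool.
#'
#' @param models A `da_models`.
#' @param n_candidates Number of random quadruples (default 1000).
#' @param n_trials Trials per quadruple (default 100).
#' @param strategy,modality,k,seed As in [run_trials()].
#' @return List with `best_words`, `best_rate`, `mean_rate` (the mean over
#'   sampled quadruples) and the full `table`.
#' @export
quadruple_search <- function(models, n_candidates = 1000, n_trials = 100,
                             strategy = "mirroring", modality = "both",
                             k = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- models$words
  if (length(W) < 6) stop("need >= 6 categories")
  mods <- if (modality == "both") c("colour", "texton") else modality
  k_use <- min(k, 4L)
  res <- lapply(seq_len(n_candidates), function(i) {
    quad <- sample(W, 4L)
    pool <- setdiff(W, quad)
    hits <- 0L
    for (t in seq_len(n_trials)) {
      cr <- sample(pool, 2L)
      sc <- vapply(mods, function(m)
        .candidate_scores(models, "identification", cr[1], cr[2], quad,
                          strategy, k_use, m), numeric(2))
      dec <- if (modality == "both")
        combine_modalities(sc[, "colour"], sc[, "texton"])
      else .pick_max(sc[, 1])
      hits <- hits + (dec$chosen == 1L)
    }
    list(quad = quad, rate = hits / n_trials)
  })
  rates <- vapply(res, `[[`, numeric(1), "rate")
  best <- which.max(rates)
  tab <- data.frame(quad = vapply(res, function(r)
    paste(r$quad, collapse = " "), character(1)), rate = rates)
  list(best_words = res[[best]]$quad, best_rate = rates[best],
       mean_rate = mean(rates), table = tab)
}
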