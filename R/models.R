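#' Assemble the distance models used by the trial engine
#'
#' Precomputes the word-distance matrix and the per-modality appearance
#' distance matrices over a common set of categories, plus the stacked
#' square-rooted image histograms needed for image-level bootstrap
#' resampling.  Trials then only look distances up, which is what makes
#' large trial counts cheap.
#'
#' @param dist_model A `distributional_model` (see [coals_transform()]),
#'   or directly a symmetric word-distance matrix with dimnames (e.g. from
#'   [orthographic_distance_matrix()]).
#' @param sets Named list of [appearance_set()] objects.
#' @param lexicon Optional data frame with columns `word`, `category`,
#'   `depth` for stratified analyses.
#' @return An object of class `da_models`: list with `words`, `D_word`,
#'   `D_colour`, `D_texton`, the stacked `sqrt_colour` / `sqrt_texton`
#'   matrices, the per-image category index `img_cat`, and `lexicon`.
#' @export
build_models <- function(dist_model, sets, lexicon = NULL) {
  set_words <- vapply(sets, function(s) s$word, character(1))
  D_word <- if (inherits(dist_model, "distributional_model"))
    distributional_distance_matrix(dist_model) else dist_model
  stopifnot(is.matrix(D_word), !is.null(rownames(D_word)))
  words <- intersect(rownames(D_word), set_words)
  if (length(words) < 3) stop("need >= 3 categories with both a context ",
                              "vector and an appearance set")
  sets <- sets[match(words, set_words)]
  sq_c <- .stack_sqrt(sets, "colour")
  sq_t <- .stack_sqrt(sets, "texton")
  img_cat <- rep(seq_along(sets),
                 vapply(sets, function(s) length(s$encodings), integer(1)))
  Dc <- .set_distance_matrix(sq_c, img_cat, length(words))
  Dt <- .set_distance_matrix(sq_t, img_cat, length(words))
  dimnames(Dc) <- dimnames(Dt) <- list(words, words)
  structure(list(words = words,
                 D_word = D_word[words, words],
                 D_colour = Dc, D_texton = Dt,
                 sqrt_colour = sq_c, sqrt_texton = sq_t,
                 img_cat = img_cat, lexicon = lexicon),
            class = "da_models")
}

#' @export
print.da_models <- function(x, ...) {
  cat(sprintf("<da_models: %d categories, %d images>\n", length(x$words),
              length(x$img_cat)))
  invisible(x)
}

#' Permute the word-to-appearance assignment
#'
#' After permutation, the appearance of word `i` is the appearance set of
#' word `perm[i]`; the word-distance matrix is untouched.  Used by the
#' permutation baseline.
#'
#' @param models A `da_models`.
#' @param perm Integer permutation of `seq_along(models$words)`.
#' @return A permuted `da_models`.
#' @export
permute_appearances <- function(models, perm) {
  stopifnot(inherits(models, "da_models"),
            setequal(perm, seq_along(models$words)))
  out <- models
  W <- models$words
  out$D_colour <- models$D_colour[perm, perm]
  out$D_texton <- models$D_texton[perm, perm]
  dimnames(out$D_colour) <- dimnames(out$D_texton) <- list(W, W)
  inv <- order(perm)
  out$img_cat <- inv[models$img_cat]
  out
}

#' Build models for a synthetic world end-to-end
#'
#' Runs the whole pipeline: world, corpus, context vocabulary,
#' co-occurrence counting, COALS transform, image rendering and encoding,
#' and distance-matrix assembly.
#'
#' @param config A [world_config()].
#' @param n_occurrences Corpus occurrences per category word (default 100).
#' @param window,weighting Passed to [count_cooccurrence()].
#' @param obif An [obif_config()].
#' @param seed Optional seed governing the whole run.
#' @return A `da_models`.
#' @export
synthesize_models <- function(config, n_occurrences = 100, window = 4,
                              weighting = "flat", obif = obif_config(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  world <- make_world(config)
  stream <- generate_corpus(world, n_occurrences)
  tab <- count_cooccurrence(stream, vocab = world$context_words,
                            targets = world$categories, window = window,
                            weighting = weighting)
  dm <- coals_transform(tab)
  sets <- generate_appearance_sets(world, config = obif)
  build_models(dm, sets)
}
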