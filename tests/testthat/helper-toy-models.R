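# A hand-specified da_models object: distance matrices set directly so
# that trial decisions can be verified by hand / brute force.
toy_models <- function(words = letters[1:6], seed = 1) {
  set.seed(seed)
  n <- length(words)
  symm <- function() {
    m <- matrix(runif(n * n, 0.1, 1), n, n, dimnames = list(words, words))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  }
  structure(list(words = words, D_word = symm(), D_colour = symm(),
                 D_texton = symm(), sqrt_colour = NULL, sqrt_texton = NULL,
                 img_cat = NULL, lexicon = NULL), class = "da_models")
}

# Brute-force PROXY/FOIL scoring, straight from the definitions
naive_proxy_foil <- function(models, task, C, R, known, k, modality,
                             strategy) {
  Dw <- models$D_word
  Da <- models[[paste0("D_", modality)]]
  if (task == "identification") {
    ref_d <- Dw[C, known]
    cand <- c(C, R)
    score_of <- function(x, ref) mean(Da[x, ref])
  } else {
    ref_d <- Da[C, known]
    cand <- c(C, R)
    score_of <- function(x, ref) mean(Dw[x, ref])
  }
  ord <- known[order(ref_d)]
  ref <- if (strategy == "proxy") ord[seq_len(k)] else rev(ord)[seq_len(k)]
  m <- vapply(cand, score_of, numeric(1), ref = ref)
  if (strategy == "proxy") -unname(m) else unname(m)
}
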