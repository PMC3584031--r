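# Fixtures built in code: tiny worlds, toy encodings and brute-force
# oracles shared across test files.

# A small world with few, small images so whole-pipeline tests stay fast.
tiny_world_config <- function(n_categories = 8, rho = 1, seed = 42, ...) {
  world_config(n_categories = n_categories, rho = rho,
               images_per_category = 4, image_size = 40,
               context_vocab_size = 20, filler_vocab_size = 40,
               context_rate = 0.9, seed = seed, ...)
}

tiny_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthesize_models(tiny_world_config(n_categories = 10),
                                  n_occurrences = 80, seed = 7)
    cache
  }
})

# Hand-built unit-sum histogram of given length
rand_hist <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}

# An image_encoding with random histograms (valid shape, not from pixels)
rand_encoding <- function() {
  structure(list(colour = rand_hist(11), texton = rand_hist(529)),
            class = "image_encoding")
}

rand_set <- function(word, n_img) {
  appearance_set(word, replicate(n_img, rand_encoding(), simplify = FALSE))
}

# Flat RGB image of one colour
flat_image <- function(rgb, n = 40) {
  array(rep(rgb, each = n * n), dim = c(n, n, 3))
}

# --- independent brute-force oracles -----------------------------------

# O(n * window) re-scan co-occurrence counter over a token_stream
naive_cooccurrence <- function(stream, vocab, targets, window = 4,
                               weighting = "flat") {
  counts <- matrix(0, length(targets), length(vocab),
                   dimnames = list(targets, vocab))
  for (doc in stream) {
    for (i in seq_along(doc)) {
      a <- doc[i]
      if (!a %in% targets) next
      for (j in seq_along(doc)) {
        d <- abs(j - i)
        if (j == i || d > window) next
        b <- doc[j]
        if (!b %in% vocab) next
        w <- if (weighting == "ramped") window - d + 1 else 1
        counts[a, b] <- counts[a, b] + w
      }
    }
  }
  counts
}

# Element-by-element COALS values from a counts matrix
naive_coals <- function(counts) {
  Tt <- sum(counts)
  na <- rowSums(counts)
  nb <- colSums(counts)
  out <- counts * 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      den <- na[i] * (Tt - na[i]) * nb[j] * (Tt - nb[j])
      r <- if (den > 0) (Tt * counts[i, j] - na[i] * nb[j]) / sqrt(den) else 0
      out[i, j] <- sqrt(max(r, 0))
    }
  }
  out
}

# Exhaustive symmetric best-match mean over two appearance sets
naive_appearance_distance <- function(setA, setB, modality) {
  na <- length(setA$encodings)
  nb <- length(setB$encodings)
  d <- function(a, b) 1 - sum(sqrt(a[[modality]] * b[[modality]]))
  fwd <- sum(vapply(setA$encodings, function(a)
    min(vapply(setB$encodings, function(b) d(a, b), numeric(1))), numeric(1)))
  bwd <- sum(vapply(setB$encodings, function(b)
    min(vapply(setA$encodings, function(a) d(a, b), numeric(1))), numeric(1)))
  (fwd + bwd) / (na + nb)
}

# Brute-force global alignment score by enumerating all alignments (only
# feasible for very short words)
naive_alignment_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(a)) return(gap * (length(b) - j + 1))
    if (j > length(b)) return(gap * (length(a) - i + 1))
    max(rec(i + 1, j + 1) + (if (a[i] == b[j]) match else mismatch),
        rec(i + 1, j) + gap,
        rec(i, j + 1) + gap)
  }
  rec(1, 1)
}
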