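#' Windowed co-occurrence counts
#'
#' Counts, for every occurrence of a target word, the context-vocabulary
#' tokens falling within `window` positions before or after it.  Windows are
#' truncated at document boundaries.  With `weighting = "flat"` every
#' in-window token adds 1; with `weighting = "ramped"` a token at distance
#' `d` adds `window - d + 1` (the weighting used by the original COALS
#' implementation).
#'
#' @param stream A [token_stream()].
#' @param vocab Character vector of context words (see
#'   [select_context_vocab()]).
#' @param targets Character vector of target words whose context vectors are
#'   wanted.  Defaults to `vocab`.
#' @param window Half-width of the context window in tokens (default 4).
#' @param weighting `"flat"` or `"ramped"`.
#' @return An object of class `cooccurrence_table`: a list with the counts
#'   matrix `counts` (targets x vocab), row totals `n_target`, column totals
#'   `n_context`, and grand total `total`.
#' @export
count_cooccurrence <- function(stream, vocab, targets = vocab, window = 4,
                               weighting = c("flat", "ramped")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(stream, "token_stream"), window >= 1,
            !anyDuplicated(vocab), !anyDuplicated(targets))
  nt <- length(targets)
  nv <- length(vocab)
  counts <- matrix(0, nt, nv, dimnames = list(targets, vocab))
  for (doc in stream) {
    n <- length(doc)
    tpos <- which(doc %in% targets)
    if (!length(tpos)) next
    ti <- match(doc[tpos], targets)
    for (off in c(-(window:1), 1:window)) {
      j <- tpos + off
      ok <- j >= 1 & j <= n
      if (!any(ok)) next
      vi <- match(doc[j[ok]], vocab)
      keep <- which(!is.na(vi))
      if (!length(keep)) next
      w <- if (weighting == "ramped") window - abs(off) + 1 else 1
      lin <- (vi[keep] - 1L) * nt + ti[ok][keep]
      add <- rowsum(rep(w, length(lin)), group = lin)
      at <- as.integer(rownames(add))
      counts[at] <- counts[at] + add[, 1]
    }
  }
  structure(list(counts = counts,
                 n_target = rowSums(counts),
                 n_context = colSums(counts),
                 total = sum(counts)),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf("<cooccurrence_table: %d targets x %d context words, total weight %g>\n",
              nrow(x$counts), ncol(x$counts), x$total))
  invisible(x)
}

#' COALS transform of a co-occurrence table
#'
#' Converts raw windowed co-occurrence counts into correlation-based context
#' vectors.  For target `a` and context word `b` with count `n(a,b)`,
#' marginals `n(a)`, `n(b)` and grand total `T`, the binary correlation
#' coefficient is
#' \deqn{r = \frac{T\,n(a,b) - n(a)\,n(b)}
#'   {\sqrt{n(a)(T-n(a))\; n(b)(T-n(b))}}}
#' Negative values are attributed to noise and clipped at zero, and the rest
#' are passed through a decelerating square-root non-linearity, so the stored
#' value is `sqrt(max(r, 0))`.  Degenerate marginals (`n = 0` or `n = T`)
#' yield value 0.
#'
#' @param table A `cooccurrence_table` from [count_cooccurrence()].
#' @return A `distributional_model`: a numeric matrix (targets x context
#'   words) of transformed values, all in `[0, 1]`.
#' @export
coals_transform <- function(table) {
  stopifnot(inherits(table, "cooccurrence_table"))
  Tt <- table$total
  if (Tt <= 0) stop("co-occurrence table has zero total weight")
  na <- table$n_target
  nb <- table$n_context
  num <- Tt * table$counts - outer(na, nb)
  den2 <- outer(na * (Tt - na), nb * (Tt - nb))
  r <- matrix(0, nrow(num), ncol(num), dimnames = dimnames(table$counts))
  pos <- den2 > 0
  r[pos] <- num[pos] / sqrt(den2[pos])
  structure(sqrt(pmax(r, 0)), class = c("distributional_model", "matrix"))
}

#' @export
print.distributional_model <- function(x, ...) {
  cat(sprintf("<distributional_model: %d words x %d context dimensions>\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Distributional distance between two words
#'
#' One minus the Pearson correlation of the two words' context vectors.
#' Values lie in `[0, 2]`, smaller meaning more distributionally similar.
#' If either vector has zero variance the correlation is undefined and the
#' distance is defined as the neutral value 1.
#'
#' @param model A `distributional_model` from [coals_transform()].
#' @param w1,w2 Words (must be rows of the model).
#' @return A scalar in `[0, 2]`.
#' @export
distributional_distance <- function(model, w1, w2) {
  for (w in c(w1, w2))
    if (!w %in% rownames(model)) stop(sprintf("unknown word '%s'", w))
  v1 <- model[w1, ]
  v2 <- model[w2, ]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(1)
  1 - stats::cor(v1, v2)
}

#' All pairwise distributional distances
#'
#' @inheritParams distributional_distance
#' @param words Rows to include (default all).
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
distributional_distance_matrix <- function(model, words = rownames(model)) {
  m <- model[words, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - cc
  d[sds == 0, ] <- 1
  d[, sds == 0] <- 1
  diag(d) <- 0
  dimnames(d) <- list(words, words)
  d
}

#' Orthographic distance (global alignment score, negated)
#'
#' Scores the optimal global alignment of the two letter sequences by the
#' Needleman-Wunsch dynamic programme, with a fixed score per match and
#' penalties for mismatches and gaps.  The score is negated so that, like
#' the distributional distance, smaller values mean more similar.
#'
#' @param w1,w2 Non-empty words.
#' @param match_score Score added per aligned identical letter (default 1).
#' @param mismatch_penalty Score added per aligned differing letter
#'   (default -1).
#' @param gap_penalty Score added per insertion/deletion (default -1).
#' @return Negated optimal alignment score (a real; can be negative).
#' @examples
#' orthographic_distance("cat", "cart") # -2: score 2 for 3 matches, 1 gap
#' @export
orthographic_distance <- function(w1, w2, match_score = 1,
                                  mismatch_penalty = -1, gap_penalty = -1) {
  a <- strsplit(w1, "")[[1]]
  b <- strsplit(w2, "")[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0 && m == 0) return(0)
  f <- matrix(0, n + 1, m + 1)
  f[, 1] <- gap_penalty * (0:n)
  f[1, ] <- gap_penalty * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match_score, mismatch_penalty)
    for (j in seq_len(m)) {
      f[i + 1, j + 1] <- max(f[i, j] + sub[j],
                             f[i, j + 1] + gap_penalty,
                             f[i + 1, j] + gap_penalty)
    }
  }
  -f[n + 1, m + 1]
}

#' @rdname orthographic_distance
#' @param words Character vector of words.
#' @param ... Passed to `orthographic_distance`.
#' @return `orthographic_distance_matrix`: symmetric matrix of negated
#'   alignment scores.
#' @export
orthographic_distance_matrix <- function(words, ...) {
  n <- length(words)
  d <- matrix(0, n, n, dimnames = list(words, words))
  for (i in seq_len(n))
    for (j in seq_len(i))
      d[i, j] <- d[j, i] <- orthographic_distance(words[i], words[j], ...)
  d
}

#' Write a distributional model as long-format TSV
#' @param model A `distributional_model`.
#' @param path Output path.
#' @param drop_zero Omit zero entries (default TRUE; the matrix is sparse).
#' @export
write_distributional_model <- function(model, path, drop_zero = TRUE) {
  idx <- if (drop_zero) which(model != 0, arr.ind = TRUE) else
    as.matrix(expand.grid(seq_len(nrow(model)), seq_len(ncol(model))))
  df <- data.frame(word = rownames(model)[idx[, 1]],
                   context = colnames(model)[idx[, 2]],
                   value = model[idx])
  df <- df[order(df$word, df$context, method = "radix"), ]
  write_tsv(df, path)
}
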