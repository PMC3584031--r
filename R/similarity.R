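#' Bhattacharyya distance between two histograms
#'
#' A cosine distance on square-rooted histograms: for unit-sum histograms
#' `u` and `v`, `1 - sum(sqrt(u * v))`.  Square-rooting makes the bins
#' approximately homoscedastic so that well-populated bins do not dominate.
#' Symmetric, in `[0, 1]`, zero iff `u == v`, and 1 for histograms with
#' disjoint support.
#'
#' @param u,v Non-negative numeric vectors of equal length, each summing
#'   to 1 (tolerance 1e-6).
#' @return Scalar distance in `[0, 1]`.
#' @examples
#' bhattacharyya_distance(c(1, 0), c(0.5, 0.5)) # 1 - sqrt(0.5)
#' @export
bhattacharyya_distance <- function(u, v) {
  if (length(u) != length(v))
    stop(sprintf("histogram bin counts differ (%d vs %d)",
                 length(u), length(v)))
  if (any(u < 0) || any(v < 0)) stop("histograms must be non-negative")
  if (abs(sum(u) - 1) > 1e-6 || abs(sum(v) - 1) > 1e-6)
    stop("histograms must be normalised to unit sum")
  min(max(1 - sum(sqrt(u * v)), 0), 1)
}

#' Distance between two image encodings in one modality
#'
#' The Bhattacharyya distance between the selected histogram pair.  The
#' colour/texton combination happens at the trial level (see
#' [combine_modalities()]), never here.
#'
#' @param encA,encB `image_encoding` objects (see [encode_image()]).
#' @param modality `"colour"` or `"texton"`.
#' @return Scalar distance in `[0, 1]`.
#' @export
image_distance <- function(encA, encB, modality = c("colour", "texton")) {
  if (identical(modality, "both"))
    stop("modality 'both' is combined at the trial level, not per image; ",
         "use combine_modalities()")
  modality <- match.arg(modality)
  bhattacharyya_distance(encA[[modality]], encB[[modality]])
}

#' An appearance set: a category's bag of encoded example images
#'
#' @param word Category word the set models.
#' @param encodings List of `image_encoding` objects (>= 1).
#' @return An object of class `appearance_set`.
#' @export
appearance_set <- function(word, encodings) {
  if (length(encodings) < 1) stop("appearance set must contain >= 1 image")
  stopifnot(all(vapply(encodings, inherits, logical(1), "image_encoding")))
  structure(list(word = word, encodings = encodings),
            class = "appearance_set")
}

#' @export
print.appearance_set <- function(x, ...) {
  cat(sprintf("<appearance_set '%s': %d images>\n", x$word,
              length(x$encodings)))
  invisible(x)
}

#' Appearance distance between two categories
#'
#' The symmetric best-match mean: each image is matched to the most similar
#' image of the other set, and the match distances are averaged over both
#' directions,
#' \deqn{\frac{\sum_{a \in A} \min_b d(a,b) + \sum_{b \in B} \min_a d(a,b)}
#'            {|A| + |B|}.}
#'
#' @param setA,setB `appearance_set` objects.
#' @param modality `"colour"` or `"texton"`.
#' @return Scalar distance >= 0; zero when the sets are identical.
#' @export
appearance_distance <- function(setA, setB, modality = c("colour", "texton")) {
  modality <- match.arg(modality)
  stopifnot(inherits(setA, "appearance_set"), inherits(setB, "appearance_set"))
  na <- length(setA$encodings)
  nb <- length(setB$encodings)
  d <- matrix(0, na, nb)
  for (i in seq_len(na))
    for (j in seq_len(nb))
      d[i, j] <- image_distance(setA$encodings[[i]], setB$encodings[[j]],
                                modality)
  (sum(apply(d, 1, min)) + sum(apply(d, 2, min))) / (na + nb)
}

# Stack the square-rooted histograms of a list of appearance sets into one
# matrix per modality; used for fast batch distance computation.
.stack_sqrt <- function(sets, modality) {
  do.call(rbind, lapply(sets, function(s)
    t(vapply(s$encodings, function(e) sqrt(e[[modality]]),
             numeric(length(s$encodings[[1]][[modality]]))))))
}

# All pairwise set distances from a stacked sqrt-histogram matrix and the
# per-image category index (integer vector).  Value-identical to looping
# appearance_distance over pairs.
.set_distance_matrix <- function(sqrt_mat, img_cat, n_cat) {
  S <- tcrossprod(sqrt_mat)            # Bhattacharyya coefficients
  Dimg <- 1 - S
  Dimg[Dimg < 0] <- 0
  rows <- split(seq_len(nrow(sqrt_mat)), img_cat)
  D <- matrix(0, n_cat, n_cat)
  for (i in seq_len(n_cat)) {
    for (j in seq_len(i - 1L)) {
      blk <- Dimg[rows[[i]], rows[[j]], drop = FALSE]
      v <- (sum(do.call(pmin, asplit(blk, 2))) +
            sum(do.call(pmin, asplit(blk, 1)))) /
        (nrow(blk) + ncol(blk))
      D[i, j] <- D[j, i] <- v
    }
  }
  D
}

#' All pairwise appearance distances
#'
#' @param sets Named list of `appearance_set` objects.
#' @param modality `"colour"` or `"texton"`.
#' @return Symmetric matrix with zero diagonal, labelled by category word.
#' @export
appearance_distance_matrix <- function(sets, modality = c("colour", "texton")) {
  modality <- match.arg(modality)
  words <- vapply(sets, function(s) s$word, character(1))
  m <- .stack_sqrt(sets, modality)
  img_cat <- rep(seq_along(sets),
                 vapply(sets, function(s) length(s$encodings), integer(1)))
  D <- .set_distance_matrix(m, img_cat, length(sets))
  dimnames(D) <- list(words, words)
  D
}

#' Write a labelled distance matrix as TSV
#' @param d Square matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(word = rownames(d), as.data.frame(d, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}
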