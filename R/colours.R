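#' The eleven Basic Colour terms
#' @export
basic_colour_names <- c("black", "grey", "white", "red", "orange", "yellow",
                        "green", "blue", "purple", "pink", "brown")

#' Basic-Colour prototype table
#'
#' The colour encoding partitions the RGB cube into eleven regions, one per
#' Basic Colour term.  Here the partition is implemented as
#' nearest-prototype in the approximately perceptually uniform CIE Lab
#' space; the prototypes are an editable table shipped with the package
#' (`inst/extdata/basic_colour_prototypes.tsv`) so that alternative
#' partitions can be supplied.
#'
#' @param path Optional path to a TSV with columns `colour`, `r`, `g`, `b`
#'   (0-255).  Defaults to the shipped table.
#' @return An 11 x 3 numeric matrix of RGB values in 0-255, with row names
#'   in the canonical order of [basic_colour_names].
#' @export
basic_colour_prototypes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "basic_colour_prototypes.tsv",
                        package = "distapp", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("colour", "r", "g", "b") %in% names(df)))
  if (!setequal(df$colour, basic_colour_names))
    stop("prototype table must contain exactly the 11 Basic Colours")
  m <- as.matrix(df[match(basic_colour_names, df$colour), c("r", "g", "b")])
  rownames(m) <- basic_colour_names
  stopifnot(all(m >= 0 & m <= 255))
  m
}

# Lab coordinates of the prototypes (cached per prototype matrix)
.proto_lab <- function(prototypes) {
  grDevices::convertColor(prototypes / 255, from = "sRGB", to = "Lab")
}

#' Classify RGB values as Basic Colours
#'
#' @param rgb A length-3 vector or an n x 3 matrix of RGB values in 0-255.
#' @param prototypes Prototype matrix from [basic_colour_prototypes()].
#' @return Integer indices in 1..11 into [basic_colour_names].
#' @examples
#' basic_colour_names[classify_basic_colour(c(255, 0, 0))] # "red"
#' @export
classify_basic_colour <- function(rgb, prototypes = basic_colour_prototypes()) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  stopifnot(ncol(rgb) == 3, all(rgb >= 0 & rgb <= 255))
  lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  plab <- .proto_lab(prototypes)
  # squared Lab distance to each prototype; nearest wins, first on ties
  d2 <- outer(rowSums(lab^2), rowSums(plab^2), "+") - 2 * lab %*% t(plab)
  max.col(-d2, ties.method = "first")
}

#' Basic-Colour histogram of an image
#'
#' Every pixel is classified as one of the eleven Basic Colours and the
#' class counts are normalised to unit sum.  The histogram is a
#' bag-of-pixels encoding: it is invariant to any rearrangement of pixels.
#'
#' @param image An H x W x 3 array of RGB values in 0-255 (row-major,
#'   origin top-left).
#' @param prototypes Prototype matrix from [basic_colour_prototypes()].
#' @return Named numeric vector of length 11 summing to 1.
#' @export
colour_histogram <- function(image, prototypes = basic_colour_prototypes()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  cls <- classify_basic_colour(px, prototypes)
  h <- tabulate(cls, nbins = 11)
  stats::setNames(h / sum(h), basic_colour_names)
}
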