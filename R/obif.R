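#' oBIF configuration
#'
#' Oriented Basic Image Features are computed at a fine and a coarse
#' Gaussian scale; a pixel's texton is the ordered pair of its fine- and
#' coarse-scale oBIF classes.
#'
#' @param sigma_fine Fine filter scale in pixels (default 1).
#' @param scale_ratio Coarse/fine scale ratio (> 1; default 4).
#' @param epsilon Flat-class threshold, dimensionless (default 0.1); larger
#'   values classify more low-contrast pixels as flat.
#' @return A list of class `obif_config`.
#' @export
obif_config <- function(sigma_fine = 1, scale_ratio = 4, epsilon = 0.1) {
  stopifnot(is.finite(sigma_fine), sigma_fine > 0,
            is.finite(scale_ratio), scale_ratio > 1,
            is.finite(epsilon), epsilon > 0)
  structure(list(sigma_fine = sigma_fine, scale_ratio = scale_ratio,
                 epsilon = epsilon), class = "obif_config")
}

#' Number of oBIF classes and textons
#' @export
N_OBIF_CLASSES <- 23L

#' @rdname N_OBIF_CLASSES
#' @export
N_TEXTONS <- 529L  # 23^2 ordered (fine, coarse) class pairs

#' Convert an RGB image to luminance
#'
#' Rec. 601 luma weights; output in `[0, 1]`.
#' @param image H x W x 3 RGB array in 0-255, or an H x W matrix already in
#'   `[0, 1]` which is returned unchanged.
#' @return H x W numeric matrix.
#' @export
luminance <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  (0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]) / 255
}

# Sampled 1-D Gaussian and derivative kernels, normalised so that discrete
# correlation reproduces the analytic response exactly on constants, ramps
# and quadratics: sum(g) = 1, sum(k * d1) = 1 (and sum(d1) = 0),
# sum(k^2 * d2) = 2 (and sum(d2) = sum(k * d2) = 0).
.gauss_kernels <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k <- -r:r
  g <- exp(-k^2 / (2 * sigma^2))
  g <- g / sum(g)
  d1 <- (k / sigma^2) * g
  d1 <- d1 - mean(d1)
  d1 <- d1 / sum(k * d1)
  d2 <- ((k^2 - sigma^2) / sigma^4) * g
  d2 <- d2 - mean(d2)
  d2 <- d2 * 2 / sum(k^2 * d2)
  list(g = g, d1 = d1, d2 = d2, radius = r)
}

# Reflect (symmetric, edge included) padding of a matrix.
.pad_reflect <- function(m, ry, rx) {
  nr <- nrow(m); nc <- ncol(m)
  if (ry >= nr || rx >= nc)
    stop(sprintf("image (%d x %d) smaller than filter support (radius %d)",
                 nr, nc, max(ry, rx)))
  ri <- c(ry:1, 1:nr, nr:(nr - ry + 1))
  ci <- c(rx:1, 1:nc, nc:(nc - rx + 1))
  m[ri, ci]
}

# Separable correlation: kernel kx along x (columns), ky along y (rows),
# with reflect padding.  Kernels must have odd length.
.conv_sep <- function(m, kx, ky) {
  rx <- (length(kx) - 1L) / 2L
  ry <- (length(ky) - 1L) / 2L
  p <- .pad_reflect(m, ry, rx)
  nr <- nrow(m); nc <- ncol(m)
  # along columns (x): out[, j] = sum_k kx[k] p[, j + k - 1]
  Kx <- matrix(0, nc + 2 * rx, nc)
  for (j in seq_len(nc)) Kx[j:(j + 2 * rx), j] <- kx
  q <- p %*% Kx
  Ky <- matrix(0, nr + 2 * ry, nr)
  for (i in seq_len(nr)) Ky[i:(i + 2 * ry), i] <- ky
  t(Ky) %*% q
}

#' Gaussian derivative jet of a grayscale image
#'
#' Responses of the bank of six derivative-of-Gaussian filters up to second
#' order at scale `sigma`: the smoothed value `s` and the derivatives `sx`,
#' `sy`, `sxx`, `sxy`, `syy`.  Image coordinates are row-major with the
#' origin top-left: `x` increases along columns, `y` increases downward
#' along rows.  Borders are handled by reflect padding.
#'
#' @param gray H x W luminance matrix (see [luminance()]).
#' @param sigma Filter scale in pixels (> 0).
#' @return A list of class `jet_field` with the six response matrices and
#'   `sigma`.
#' @export
gaussian_jet <- function(gray, sigma) {
  stopifnot(is.matrix(gray), is.finite(sigma), sigma > 0)
  kk <- .gauss_kernels(sigma)
  structure(list(
    s   = .conv_sep(gray, kk$g,  kk$g),
    sx  = .conv_sep(gray, kk$d1, kk$g),
    sy  = .conv_sep(gray, kk$g,  kk$d1),
    sxx = .conv_sep(gray, kk$d2, kk$g),
    sxy = .conv_sep(gray, kk$d1, kk$d1),
    syy = .conv_sep(gray, kk$g,  kk$d2),
    sigma = sigma), class = "jet_field")
}

# Sector quantisation: angles (radians) into `nbins` equal sectors of width
# `width` centred on 0, width, 2*width, ...; boundaries go to the lower bin.
.sector_bin <- function(angle, width, nbins) {
  a <- (angle + width / 2 - 1e-9) %% (width * nbins)
  (floor(a / width) %% nbins) + 1L
}

#' Classify jet responses into oBIF classes
#'
#' Each pixel is assigned to one of 23 oriented Basic Image Feature classes
#' by the largest of seven scale-normalised competing scores:
#' flat `eps * s`; slope `2 sigma |grad s|`; and, with
#' `lambda = sigma^2 (sxx + syy)` and
#' `gamma = sigma^2 sqrt((sxx - syy)^2 + 4 sxy^2)`:
#' dark blob `lambda`, light blob `-lambda`, dark line
#' `(gamma + lambda)/sqrt(2)`, light line `(gamma - lambda)/sqrt(2)`,
#' saddle `gamma`.  Slopes are quantised into 8 sectors of the gradient
#' direction (measured from +x, counter-clockwise in image coordinates with
#' y downward); lines and saddles into 4 sectors of the feature orientation
#' (perpendicular to the principal second-derivative direction) over
#' `[0, pi)`.  Sectors are centred on the axis directions and boundaries are
#' assigned to the lower bin.
#'
#' Class indices (1-based): 1 flat; 2 light blob; 3 dark blob; 4-11 slope
#' orientations; 12-15 light line; 16-19 dark line; 20-23 saddle.
#'
#' @param jet A `jet_field` from [gaussian_jet()], or a list with scalar
#'   fields `s, sx, sy, sxx, sxy, syy, sigma` for a single pixel.
#' @param epsilon Flat threshold (see [obif_config()]).
#' @return Integer matrix (or scalar) of class indices in 1..23.
#' @export
classify_obif <- function(jet, epsilon = 0.1) {
  sg <- jet$sigma
  s <- jet$s
  scalar <- !is.matrix(s)
  as_m <- function(v) if (scalar) matrix(v, 1, 1) else v
  s <- as_m(s); sx <- as_m(jet$sx); sy <- as_m(jet$sy)
  sxx <- as_m(jet$sxx); sxy <- as_m(jet$sxy); syy <- as_m(jet$syy)

  lam <- sg^2 * (sxx + syy)
  gam <- sg^2 * sqrt((sxx - syy)^2 + 4 * sxy^2)
  sc <- cbind(flat = as.vector(epsilon * s),
              light_blob = as.vector(-lam),
              dark_blob = as.vector(lam),
              slope = as.vector(2 * sg * sqrt(sx^2 + sy^2)),
              light_line = as.vector((gam - lam) / sqrt(2)),
              dark_line = as.vector((gam + lam) / sqrt(2)),
              saddle = as.vector(gam))
  winner <- max.col(sc, ties.method = "first")  # flat wins all-zero ties

  grad_bin <- .sector_bin(atan2(as.vector(sy), as.vector(sx)), pi / 4, 8L)
  # orientation of a line/saddle feature: along the line, i.e. perpendicular
  # to the eigendirection of the Hessian eigenvalue of largest magnitude.
  # 0.5*atan2 gives the direction of the larger SIGNED eigenvalue, which is
  # across a dark line (lam > 0) but along a light one (lam < 0).
  principal <- 0.5 * atan2(2 * as.vector(sxy), as.vector(sxx - syy))
  feat_angle <- (principal + ifelse(as.vector(lam) >= 0, pi / 2, 0)) %% pi
  feat_bin <- .sector_bin(feat_angle, pi / 4, 4L)

  cls <- integer(length(winner))
  cls[winner == 1] <- 1L
  cls[winner == 2] <- 2L
  cls[winner == 3] <- 3L
  cls[winner == 4] <- 3L + grad_bin[winner == 4]
  cls[winner == 5] <- 11L + feat_bin[winner == 5]
  cls[winner == 6] <- 15L + feat_bin[winner == 6]
  cls[winner == 7] <- 19L + feat_bin[winner == 7]
  if (scalar) cls[1] else matrix(cls, nrow(s), ncol(s))
}

#' Per-pixel oBIF classes of an image at one scale
#' @param image RGB array or luminance matrix.
#' @param sigma Filter scale.
#' @param epsilon Flat threshold.
#' @return Integer matrix of class indices in 1..23.
#' @export
obif_classes <- function(image, sigma, epsilon = 0.1) {
  classify_obif(gaussian_jet(luminance(image), sigma), epsilon)
}

#' Two-scale oBIF texton histogram of an image
#'
#' Each pixel's texton is the ordered pair (fine-scale oBIF, coarse-scale
#' oBIF), giving 23^2 = 529 possible textons.  The texton index is
#' fine-major: `23 * (fine - 1) + coarse` (1-based).  Counts over all
#' pixels are normalised to unit sum.
#'
#' @param image RGB array (0-255) or luminance matrix in `[0, 1]`.
#' @param config An [obif_config()].
#' @return Numeric vector of length 529 summing to 1.
#' @export
texton_histogram <- function(image, config = obif_config()) {
  stopifnot(inherits(config, "obif_config"))
  gray <- luminance(image)
  fine <- classify_obif(gaussian_jet(gray, config$sigma_fine), config$epsilon)
  coarse <- classify_obif(gaussian_jet(gray, config$sigma_fine * config$scale_ratio),
                          config$epsilon)
  idx <- N_OBIF_CLASSES * (fine - 1L) + coarse
  h <- tabulate(idx, nbins = N_TEXTONS)
  h / sum(h)
}

#' Encode an image as colour and texton histograms
#'
#' @param image H x W x 3 RGB array in 0-255.
#' @param config An [obif_config()].
#' @param prototypes Basic-Colour prototypes (see
#'   [basic_colour_prototypes()]).
#' @return An `image_encoding`: list with unit-sum histograms `colour`
#'   (length 11) and `texton` (length 529).
#' @export
encode_image <- function(image, config = obif_config(),
                         prototypes = basic_colour_prototypes()) {
  structure(list(colour = colour_histogram(image, prototypes),
                 texton = texton_histogram(image, config)),
            class = "image_encoding")
}
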