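#' Render one synthetic image of a category
#'
#' Emulates the within-category variation of photographic example images:
#' the background colour is drawn from the category's Basic-Colour mixture;
#' foreground stripes follow the category's orientation (jittered per
#' image, sd 5 degrees) and period with a random phase; blobs of mixture
#' colours are scattered at the category's density with random positions
#' and radii; and a multiplicative lighting gain (uniform on
#' `[0.85, 1.15]`, clipped to `[0, 255]`) varies per image.  Geometry is
#' axis-aligned in pixel coordinates, origin top-left, row-major.
#'
#' @param world A `da_world`.
#' @param category A category word of the world.
#' @param seed Optional RNG seed.
#' @param prototypes Basic-Colour prototype RGB table used as the palette.
#' @return An `image_size` x `image_size` x 3 array of RGB values in 0-255.
#' @export
render_image <- function(world, category, seed = NULL,
                         prototypes = basic_colour_prototypes()) {
  stopifnot(inherits(world, "da_world"))
  ci <- match(category, world$categories)
  if (is.na(ci)) stop(sprintf("unknown category '%s'", category))
  if (!is.null(seed)) set.seed(seed)
  n <- world$config$image_size
  mix <- world$colour_mix[ci, ]

  bg <- prototypes[sample.int(11, 1, prob = mix), ]
  img <- array(rep(bg, each = n * n), dim = c(n, n, 3))

  # stripes: sinusoidal bands darkening the background
  depth <- world$stripe_depth[ci]
  if (depth > 0) {
    ang <- world$stripe_angle[ci] + stats::rnorm(1, sd = 5 * pi / 180)
    phase <- stats::runif(1, 0, 2 * pi)
    per <- world$stripe_period[ci]
    x <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    y <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    mask <- sin(2 * pi * (x * cos(ang) + y * sin(ang)) / per + phase) > 0
    fac <- ifelse(mask, 1 - depth, 1)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * fac
  }

  # blobs: filled discs in palette colours at the category's density
  n_blobs <- stats::rpois(1, world$blob_density[ci] * n * n)
  if (n_blobs > 0) {
    cx <- stats::runif(n_blobs, 1, n)
    cy <- stats::runif(n_blobs, 1, n)
    rad <- stats::runif(n_blobs, 2, 4)
    col <- prototypes[sample.int(11, n_blobs, replace = TRUE, prob = mix), ,
                      drop = FALSE]
    xs <- seq_len(n)
    for (b in seq_len(n_blobs)) {
      dx2 <- (xs - cx[b])^2
      dy2 <- (xs - cy[b])^2
      disc <- outer(dy2, dx2, "+") <= rad[b]^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[disc] <- col[b, ch]
        img[, , ch] <- plane
      }
    }
  }

  gain <- stats::runif(1, 0.85, 1.15)
  img <- img * gain
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

#' Render and encode the appearance sets of all categories
#'
#' Renders `images_per_category` images per category and encodes each as
#' colour and texton histograms.
#'
#' @param world A `da_world`.
#' @param seed Optional RNG seed.
#' @param config An [obif_config()].
#' @param prototypes Basic-Colour prototypes.
#' @param categories Subset of categories (default all).
#' @return Named list of [appearance_set()] objects.
#' @export
generate_appearance_sets <- function(world, seed = NULL,
                                     config = obif_config(),
                                     prototypes = basic_colour_prototypes(),
                                     categories = world$categories) {
  if (!is.null(seed)) set.seed(seed)
  k <- world$config$images_per_category
  sets <- lapply(categories, function(cat) {
    encs <- lapply(seq_len(k), function(i)
      encode_image(render_image(world, cat, prototypes = prototypes),
                   config = config, prototypes = prototypes))
    appearance_set(cat, encs)
  })
  stats::setNames(sets, categories)
}

#' Write an image as PNG / read a PNG image
#'
#' Thin wrappers mapping between the package's 0-255 RGB arrays and PNG
#' files.
#'
#' @param image H x W x 3 array in 0-255.
#' @param path File path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}
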