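#' Configuration of a synthetic world
#'
#' A synthetic world couples the linguistic and visual structure of a set
#' of categories through a shared latent variable.  Each category `c` has a
#' latent vector `z_c`; its context-word profile is a softmax of a linear
#' map of `rho * z_c + sqrt(1 - rho^2) * noise`, and its appearance
#' parameters (Basic-Colour mixture, stripe orientation/period, blob
#' density) come from a second, independent linear map of
#' `rho * z_c + sqrt(1 - rho^2) * noise'`.  At `rho = 1` both modalities
#' are deterministic functions of the shared latent; at `rho = 0` they are
#' independent.
#'
#' @param n_categories Number of categories (>= 1).
#' @param rho Language/appearance coupling strength in `[0, 1]`.
#' @param latent_dim Dimension of the latent vectors (default 4).
#' @param context_vocab_size Number of context words (default 60).
#' @param filler_vocab_size Number of filler words (default 200).
#' @param context_rate Probability that a window slot holds a context word
#'   rather than a filler (default 0.5).
#' @param images_per_category Images rendered per category (default 50).
#' @param image_size Side of the square rendered images in pixels
#'   (default 64).
#' @param seed Optional RNG seed recorded in the config; [make_world()]
#'   seeds from it when present.
#' @param language_scale,colour_scale Softmax concentration of the context
#'   profiles and colour mixtures (defaults 2 and 3; larger gives more
#'   peaked profiles).
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_categories, rho, latent_dim = 4,
                         context_vocab_size = 60, filler_vocab_size = 200,
                         context_rate = 0.5, images_per_category = 50,
                         image_size = 64, seed = NULL,
                         language_scale = 2, colour_scale = 3) {
  num <- c(n_categories = n_categories, rho = rho, latent_dim = latent_dim,
           context_vocab_size = context_vocab_size,
           filler_vocab_size = filler_vocab_size, context_rate = context_rate,
           images_per_category = images_per_category, image_size = image_size,
           language_scale = language_scale, colour_scale = colour_scale)
  if (any(!is.finite(num)))
    stop("non-finite world configuration value: ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  stopifnot(rho >= 0, rho <= 1, context_rate >= 0, context_rate <= 1,
            n_categories >= 1, latent_dim >= 1, context_vocab_size >= 1,
            filler_vocab_size >= 1, images_per_category >= 1,
            image_size >= 9)
  structure(c(as.list(num), list(seed = seed)), class = "world_config")
}

#' Build a synthetic world from a configuration
#'
#' Draws the per-category latents and derives the context-word profiles and
#' appearance parameters as described in [world_config()].  Deterministic
#' given `config$seed` (or the current RNG state when no seed is set).
#'
#' @param config A [world_config()].
#' @return An object of class `da_world` with elements `config`,
#'   `categories` (words), `context_words`, `filler_words`, `z` (latents,
#'   `latent_dim` x categories), `phi` (categories x context vocab, rows
#'   unit-sum), and the appearance parameters `colour_mix` (categories x
#'   11, rows unit-sum), `stripe_angle` (in `[0, pi)`), `stripe_period`
#'   (pixels), `stripe_depth` (contrast in `[0, 1]`) and `blob_density`
#'   (blobs per pixel).
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  C <- config$n_categories
  L <- config$latent_dim
  V <- config$context_vocab_size
  rho <- config$rho

  z <- matrix(stats::rnorm(L * C), L, C)
  u <- rho * z + sqrt(1 - rho^2) * matrix(stats::rnorm(L * C), L, C)
  v <- rho * z + sqrt(1 - rho^2) * matrix(stats::rnorm(L * C), L, C)

  softmax_cols <- function(m) {
    e <- exp(sweep(m, 2, apply(m, 2, max)))
    sweep(e, 2, colSums(e), "/")
  }
  A_lang <- matrix(stats::rnorm(V * L, sd = config$language_scale / sqrt(L)),
                   V, L)
  phi <- t(softmax_cols(A_lang %*% u))

  B_col <- matrix(stats::rnorm(11 * L, sd = config$colour_scale / sqrt(L)),
                  11, L)
  colour_mix <- t(softmax_cols(B_col %*% v))

  proj <- function() as.vector(stats::rnorm(L) %*% v) / sqrt(L)
  a1 <- proj(); a2 <- proj()
  structure(list(
    config = config,
    categories = sprintf("w%03d", seq_len(C)),
    context_words = sprintf("c%03d", seq_len(V)),
    filler_words = sprintf("f%03d", seq_len(config$filler_vocab_size)),
    z = z,
    phi = phi,
    colour_mix = colour_mix,
    stripe_angle = atan2(a2, a1) %% pi,
    stripe_period = 4 + 12 * stats::plogis(proj()),
    stripe_depth = 0.25 + 0.5 * stats::plogis(proj()),
    blob_density = 0.008 * stats::plogis(proj())),
    class = "da_world")
}

#' @export
print.da_world <- function(x, ...) {
  cat(sprintf("<da_world: %d categories, rho = %g, %d context words>\n",
              x$config$n_categories, x$config$rho,
              x$config$context_vocab_size))
  invisible(x)
}

#' Generate a synthetic corpus from a world
#'
#' Emits `n_occurrences_per_word` occurrences of every category word.  Each
#' occurrence is preceded by a run of filler tokens and surrounded by four
#' window slots on either side; each slot holds a draw from the category's
#' context profile with probability `context_rate`, and a uniform filler
#' word otherwise.  The filler runs guarantee that the +/-4 windows of
#' successive occurrences never overlap, so naive whole-stream counting and
#' windowed counting agree by construction.
#'
#' @param world A `da_world`.
#' @param n_occurrences_per_word Occurrences per category word (0 gives an
#'   empty stream).
#' @param seed Optional RNG seed.
#' @param sep_fillers Filler tokens inserted between occurrences
#'   (default 3; must be >= 1 to keep windows disjoint).
#' @return A [token_stream()] with a single document.
#' @export
generate_corpus <- function(world, n_occurrences_per_word, seed = NULL,
                            sep_fillers = 3) {
  stopifnot(inherits(world, "da_world"), n_occurrences_per_word >= 0,
            sep_fillers >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_occurrences_per_word
  C <- world$config$n_categories
  if (n == 0 || C == 0) return(token_stream(list()))
  rate <- world$config$context_rate

  ev_cat <- sample(rep(seq_len(C), each = n))   # shuffled occurrence order
  E <- length(ev_cat)
  n_slots <- 8L                                  # 4 before + 4 after
  is_ctx <- matrix(stats::runif(E * n_slots) < rate, E, n_slots)
  slots <- matrix("", E, n_slots)
  n_fill <- sum(!is_ctx)
  slots[!is_ctx] <- sample(world$filler_words, n_fill, replace = TRUE)
  for (c in seq_len(C)) {
    sel <- is_ctx & (ev_cat == c)
    k <- sum(sel)
    if (k > 0)
      slots[sel] <- sample(world$context_words, k, replace = TRUE,
                           prob = world$phi[c, ])
  }
  sep <- matrix(sample(world$filler_words, E * sep_fillers, replace = TRUE),
                sep_fillers, E)
  block <- rbind(sep, t(slots[, 1:4, drop = FALSE]),
                 world$categories[ev_cat], t(slots[, 5:8, drop = FALSE]))
  token_stream(list(as.vector(block)))
}

#' Serialise a world as a TSV bundle
#'
#' Writes one row per category (latent coordinates, context profile, and
#' appearance parameters) plus, when the yaml package is available, the
#' configuration as YAML alongside.
#'
#' @param world A `da_world`.
#' @param path Path of the TSV to write; the config is written to
#'   `<path>.config.yaml` (or `.json` via a plain dump when yaml is
#'   unavailable).
#' @export
write_world <- function(world, path) {
  df <- data.frame(category = world$categories,
                   t(world$z),
                   world$phi,
                   world$colour_mix,
                   stripe_angle = world$stripe_angle,
                   stripe_period = world$stripe_period,
                   stripe_depth = world$stripe_depth,
                   blob_density = world$blob_density,
                   check.names = FALSE)
  names(df) <- c("category",
                 sprintf("z%d", seq_len(nrow(world$z))),
                 sprintf("phi_%s", world$context_words),
                 sprintf("mix_%s", basic_colour_names),
                 "stripe_angle", "stripe_period", "stripe_depth",
                 "blob_density")
  write_tsv(df, path)
  cfg <- world$config
  class(cfg) <- NULL
  cfg_path <- paste0(path, ".config.yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(cfg, cfg_path)
  } else {
    writeLines(paste(names(cfg), vapply(cfg, function(x)
      paste(format(x), collapse = " "), character(1)), sep = ": "), cfg_path)
  }
  invisible(path)
}
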