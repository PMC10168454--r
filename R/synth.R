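#' Parameters of the chest-radiograph phantom generator
#'
#' The phantom emulates the gross intensity layout of a frontal chest
#' radiograph: a bright mediastinum band between two darker elliptical lung
#' fields on a soft-tissue background, rib-like sinusoidal bands across the
#' lungs, smoothed by a small Gaussian blur and corrupted by additive
#' Gaussian noise. Per-image jitter of the ellipse geometry (centres, radii,
#' rib phase) makes every phantom unique while keeping the population
#' statistics stable, so two independently seeded pools are
#' indistinguishable to any classifier — the property that makes phantom
#' cohorts a valid stand-in for finding-free radiographs.
#'
#' @param side Image side in pixels (>= 32; 64 is the working scale, 224
#'   matches full-resolution radiograph preprocessing).
#' @param lung_contrast Fractional darkening of the lung fields relative to
#'   the body background, in \[0, 1\].
#' @param rib_count Number of rib bands across each lung field (0 disables
#'   ribs).
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   intensity units.
#' @param blur_sigma Gaussian blur scale in pixels applied to the geometry
#'   before noise.
#' @param seed Integer master seed for the generator.
#' @return A `phantom_params` object.
#' @export
phantom_params <- function(side = 64, lung_contrast = 0.45, rib_count = 5,
                           noise_sigma = 6, blur_sigma = 0.8, seed = 0L) {
  side <- as.integer(side)
  if (side < 32) stop("side must be >= 32", call. = FALSE)
  if (noise_sigma < 0 || blur_sigma < 0) {
    stop("noise_sigma and blur_sigma must be >= 0", call. = FALSE)
  }
  if (lung_contrast < 0 || lung_contrast > 1) {
    stop("lung_contrast must be in [0, 1]", call. = FALSE)
  }
  structure(list(side = side, lung_contrast = lung_contrast,
                 rib_count = as.integer(rib_count),
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# base intensities of the piecewise-constant geometry (8-bit scale)
.phantom_levels <- list(body = 180, mediastinum = 215)

#' Generate one chest-radiograph-like phantom
#'
#' Deterministic given `params$seed` (and `id`): geometry jitter, rib phase
#' and noise are all drawn from a seed derived from them. With
#' `noise_sigma = 0`, `blur_sigma = 0` and `rib_count = 0` the output is the
#' bare piecewise-constant geometry.
#'
#' @param params A [phantom_params()].
#' @param id Image id (also a seeding key, so distinct ids give distinct
#'   phantoms from the same params).
#' @return An [image8()] of side `params$side`.
#' @export
#' @examples
#' img <- generate_phantom(phantom_params(side = 32, seed = 1))
#' img
generate_phantom <- function(params, id = "phantom") {
  stopifnot(inherits(params, "phantom_params"))
  S <- params$side
  withr::with_seed(fan_seed(params$seed, "phantom", id), {
    jit <- function(scale) stats::runif(1, -scale, scale)
    cx <- c(0.30 + jit(0.03), 0.70 + jit(0.03)) * S
    cy <- (0.46 + jit(0.03)) * S
    rx <- (0.155 + jit(0.015)) * S
    ry <- (0.30 + jit(0.03)) * S
    phase <- stats::runif(1, 0, 2 * pi)
    noise <- if (params$noise_sigma > 0) {
      matrix(stats::rnorm(S * S, 0, params$noise_sigma), S, S)
    } else 0
  })
  x <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # column coordinate
  y <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # row coordinate
  canvas <- matrix(.phantom_levels$body, S, S)
  med_half <- 0.09 * S
  canvas[abs(x - S / 2) <= med_half] <- .phantom_levels$mediastinum
  lung_val <- .phantom_levels$body * (1 - params$lung_contrast)
  lung <- ((x - cx[1])^2 / rx^2 + (y - cy)^2 / ry^2 <= 1) |
    ((x - cx[2])^2 / rx^2 + (y - cy)^2 / ry^2 <= 1)
  canvas[lung] <- lung_val
  if (params$rib_count > 0) {
    ribs <- 18 * sin(2 * pi * params$rib_count * (y - cy + ry) / (2 * ry) +
                       phase)
    canvas[lung] <- canvas[lung] + ribs[lung]
  }
  canvas <- gaussian_blur(canvas, params$blur_sigma) + noise
  quantize_image8(canvas, id = id)
}

#' Generate a pool of phantoms
#'
#' `n` phantoms with unique ids, each seeded by fan-out from
#' `params$seed`, so the pool is reproducible and order-independent.
#'
#' @param n Number of phantoms (>= 1).
#' @param params A [phantom_params()].
#' @param prefix Id prefix.
#' @return A list of [image8()] objects.
#' @export
generate_pool <- function(n, params, prefix = "phantom") {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  ids <- sprintf("%s-s%d-%05d", prefix, params$seed, seq_len(n))
  purrr::map(ids, ~ generate_phantom(params, id = .x))
}

#' Generate a labeled phantom cohort
#'
#' Positive and negative cohorts are drawn from the identical generator, so
#' without a shortcut the labels carry no image signal whatsoever (any
#' scorer is at chance). With `shortcut` given, the stated class is
#' perturbed via [inject_shortcut()], producing a cohort with a known,
#' quantified shortcut — the raw material of certification exams.
#'
#' @param n_pos,n_neg Cohort sizes (>= 1 each).
#' @param params A [phantom_params()].
#' @param shortcut Optional `list(spec = ada_spec(...), target =
#'   "positive"|"negative")`.
#' @param name Dataset name.
#' @return A [labeled_dataset()].
#' @export
generate_labeled_cohorts <- function(n_pos, n_neg, params, shortcut = NULL,
                                     name = "phantom-cohort") {
  if (n_pos < 1 || n_neg < 1) {
    stop("n_pos and n_neg must both be >= 1", call. = FALSE)
  }
  images <- generate_pool(n_pos + n_neg, params, prefix = "cohort")
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  ds <- labeled_dataset(images, labels, name = name)
  if (!is.null(shortcut)) {
    stopifnot(is.list(shortcut), inherits(shortcut$spec, "ada_spec"))
    ds <- inject_shortcut(ds, target = shortcut$target, spec = shortcut$spec)
  }
  ds
}
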