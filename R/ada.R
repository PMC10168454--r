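#' Acquisition-dependent-attribute (ADA) perturbation recipe
#'
#' An `ada_spec` describes how to manufacture one intrinsic shortcut: which
#' global attribute to perturb (`"S"` sharpness or `"C"` contrast), in which
#' direction, and how strong. The strength is drawn per image, uniformly
#' from `[strength_low, strength_high]`, so the detective has to learn the
#' attribute itself rather than a single fixed transform — mirroring the
#' acquisition variation (different systems, vendors, protocols) that
#' creates these attributes in real radiographs.
#'
#' Strength maps to operator parameters as:
#' * contrast, increase: gamma = 1 + s (darkens mid-tones, steepens contrast)
#' * contrast, decrease: gamma = 1 / (1 + s)
#' * sharpness, increase: unsharp-mask amount = +s at the spec's `sigma`
#' * sharpness, decrease: amount = -s (Gaussian softening)
#'
#' Default strength ranges (gamma in \[1.15, 1.5\] or its reciprocal;
#' amount in \[0.5, 1.5\] or \[-0.7, -0.3\], sigma 1.5 px) are visually
#' subtle at radiograph scale yet learnable.
#'
#' @param kind `"S"` (sharpness) or `"C"` (contrast).
#' @param direction `"increase"` or `"decrease"`.
#' @param strength_low,strength_high Bounds of the per-image uniform
#'   strength draw; `0 <= strength_low <= strength_high`.
#' @param sigma Gaussian scale in pixels for the sharpness operator
#'   (ignored for contrast).
#' @param seed Integer seed; together with each image's id it fixes the
#'   per-image strength draw, so results never depend on dataset order.
#' @return An `ada_spec` object.
#' @export
#' @examples
#' ada_spec("C", "increase")
#' ada_spec("S", "decrease", seed = 42)
ada_spec <- function(kind = c("S", "C"),
                     direction = c("increase", "decrease"),
                     strength_low = NULL, strength_high = NULL,
                     sigma = 1.5, seed = 0L) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  defaults <- list(
    S = list(increase = c(0.5, 1.5), decrease = c(0.3, 0.7)),
    C = list(increase = c(0.15, 0.5), decrease = c(0.15, 0.5))
  )
  rng <- defaults[[kind]][[direction]]
  if (is.null(strength_low)) strength_low <- rng[1]
  if (is.null(strength_high)) strength_high <- rng[2]
  if (strength_low < 0 || strength_high < strength_low) {
    stop("need 0 <= strength_low <= strength_high", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(kind = kind, direction = direction,
                 strength_low = strength_low, strength_high = strength_high,
                 sigma = sigma, seed = as.integer(seed)),
            class = "ada_spec")
}

#' @export
print.ada_spec <- function(x, ...) {
  cat(sprintf("<ada_spec kind=%s direction=%s strength=[%g, %g] sigma=%g seed=%d>\n",
              x$kind, x$direction, x$strength_low, x$strength_high,
              x$sigma, x$seed))
  invisible(x)
}

# flat key=value serialization, embedded in certification reports and
# dataset sidecars for provenance
format_ada_spec <- function(spec) {
  paste(sprintf("%s=%s", names(unclass(spec)),
                vapply(unclass(spec), format, character(1))),
        collapse = " ")
}

#' Gamma contrast adjustment
#'
#' Monotone intensity remap `v -> round(255 * (v/255)^gamma)` with
#' half-away-from-zero rounding. 0 and 255 are fixed points; `gamma = 1` is
#' the identity; `gamma > 1` steepens (increases) contrast in the bright
#' range, `gamma < 1` flattens it. Being a monotone remap of the intensity
#' scale, it never reorders two pixel values.
#'
#' @param image An [image8()].
#' @param gamma Positive exponent.
#' @return The adjusted [image8()], same dimensions and id.
#' @export
#' @examples
#' img <- image8(matrix(128L, 8, 8))
#' apply_contrast(img, gamma = 2)[1, 1]  # 64
apply_contrast <- function(image, gamma) {
  stopifnot(is_image8(image))
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma <= 0) {
    stop("`gamma` must be a single positive number", call. = FALSE)
  }
  v <- as.matrix(image)
  quantize_image8(255 * (v / 255)^gamma, id = img_id(image))
}

#' Unsharp-mask sharpness adjustment
#'
#' Adds a scaled detail band to the image:
#' `clamp(round(I + amount * (I - G_sigma(I))))`, where `G_sigma` is a
#' Gaussian blur with reflect padding. Positive `amount` sharpens (boosts
#' high spatial frequencies), negative `amount` softens; `amount = -1`
#' reduces to pure Gaussian blur, and anything below -1 would invert the
#' detail band and is rejected. `sigma = 0` or `amount = 0` is the
#' identity.
#'
#' @param image An [image8()].
#' @param sigma Gaussian scale in pixels (>= 0).
#' @param amount Detail gain (>= -1); unitless.
#' @return The adjusted [image8()], same dimensions and id.
#' @export
apply_sharpness <- function(image, sigma, amount) {
  stopifnot(is_image8(image))
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (amount < -1) {
    stop("`amount` must be >= -1 (lower would invert the detail band)",
         call. = FALSE)
  }
  if (sigma == 0 || amount == 0) return(image)
  v <- as.matrix(image)
  g <- gaussian_blur(v, sigma)
  quantize_image8(v + amount * (v - g), id = img_id(image))
}

# separable Gaussian blur with reflect (symmetric) padding on a numeric
# matrix; kernel truncated at 3 sigma
gaussian_blur <- function(m, sigma) {
  if (sigma == 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect <- function(idx, n) {
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    idx
  }
  pass <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    out <- 0 * x
    for (d in -r:r) {
      j <- reflect(seq_len(n) + d, n)
      out <- out + k[d + r + 1] * (if (along_rows) x[j, , drop = FALSE]
                                   else x[, j, drop = FALSE])
    }
    out
  }
  pass(pass(m, TRUE), FALSE)
}

#' Apply an ADA perturbation to one image
#'
#' Draws the strength uniformly from the spec's range — seeded by
#' `(spec$seed, img_id(image))`, so the same (spec, image) pair always
#' yields bit-identical output regardless of processing order — and
#' dispatches to [apply_contrast()] or [apply_sharpness()] according to the
#' spec's kind and direction.
#'
#' @param image An [image8()].
#' @param spec An [ada_spec()].
#' @return The perturbed [image8()].
#' @export
apply_ada <- function(image, spec) {
  stopifnot(is_image8(image), inherits(spec, "ada_spec"))
  s <- draw_strength(spec, img_id(image))
  if (spec$kind == "C") {
    gamma <- if (spec$direction == "increase") 1 + s else 1 / (1 + s)
    apply_contrast(image, gamma)
  } else {
    amount <- if (spec$direction == "increase") s else -s
    apply_sharpness(image, spec$sigma, amount)
  }
}

draw_strength <- function(spec, id) {
  if (spec$strength_low == spec$strength_high) return(spec$strength_low)
  withr::with_seed(
    fan_seed(spec$seed, "ada", id),
    stats::runif(1, spec$strength_low, spec$strength_high)
  )
}
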