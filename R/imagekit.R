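#' 8-bit grayscale images
#'
#' The unit every operator in the package transforms: a 2-D integer matrix of
#' intensities in \[0, 255\] (row-major, origin top-left) with an opaque `id`
#' used for provenance and per-image seeding. Radiographs follow the
#' "bright = dense" display convention.
#'
#' @param pixels Integer (or whole-number numeric) matrix with values in
#'   \[0, 255\]; at least 8 rows and 8 columns.
#' @param id Character scalar identifying the image.
#' @return An `image8` object (an integer matrix with class and `id`
#'   attributes).
#' @export
#' @examples
#' img <- image8(matrix(0L:63L, 8, 8), id = "ramp")
#' dim(img)
image8 <- function(pixels, id = "img") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    bad <- which(!is.finite(pixels))[1]
    stop(sprintf("non-finite pixel at index %d", bad), call. = FALSE)
  }
  if (any(pixels != floor(pixels))) {
    stop("pixel intensities must be integers", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  if (nrow(pixels) < 8 || ncol(pixels) < 8) {
    stop("image must be at least 8x8", call. = FALSE)
  }
  pixels <- structure(as.integer(pixels), dim = dim(pixels))
  structure(pixels, class = "image8", id = as.character(id))
}

#' @export
print.image8 <- function(x, ...) {
  cat(sprintf("<image8 %dx%d id=%s> intensity range [%d, %d]\n",
              nrow(x), ncol(x), img_id(x), min(x), max(x)))
  invisible(x)
}

#' @rdname image8
#' @param x,image An `image8` object.
#' @export
img_id <- function(x) attr(x, "id")

#' @export
as.matrix.image8 <- function(x, ...) {
  y <- unclass(x)
  attr(y, "id") <- NULL
  y
}

is_image8 <- function(x) inherits(x, "image8")

# rebuild an image8 from a double matrix after an intensity operation:
# round half-away-from-zero, clamp, keep id
quantize_image8 <- function(pix, id) {
  image8(clamp(round_half_away(pix), 0, 255), id = id)
}

#' Display-window specification
#'
#' A linear intensity window in source (detector) units: `level` is the
#' window centre (WL) and `width` the intensity span (WW) mapped onto the
#' 8-bit display range.
#'
#' @param level Window level (centre), in source units.
#' @param width Window width (span), in source units; must be positive.
#' @return A `window_spec` object.
#' @export
window_spec <- function(level, width) {
  stopifnot(is.numeric(level), length(level) == 1,
            is.numeric(width), length(width) == 1)
  if (!is.finite(width) || width <= 0) {
    stop("window width must be a positive finite number", call. = FALSE)
  }
  structure(list(level = as.numeric(level), width = as.numeric(width)),
            class = "window_spec")
}

#' Default window from the pixel data range
#'
#' When no window is recorded with an acquisition, viewers fall back to the
#' full dynamic range of the pixel data: WL = (min + max) / 2,
#' WW = max - min. Degenerate (constant) data get a width of 1 so the map
#' stays defined.
#'
#' @param raw Numeric matrix of source-unit intensities.
#' @return A [window_spec()].
#' @export
window_from_range <- function(raw) {
  rng <- range(raw)
  w <- rng[2] - rng[1]
  window_spec(level = mean(rng), width = if (w > 0) w else 1)
}

#' Window a raw intensity matrix into an 8-bit image
#'
#' Applies the standard display-window mapping
#' `round(255 * clamp((x - (WL - WW/2)) / WW, 0, 1))` with
#' half-away-from-zero rounding. Intensities at or below `WL - WW/2` map to
#' 0 and at or above `WL + WW/2` map to 255; the map is monotone
#' non-decreasing in `x`.
#'
#' @param raw Numeric matrix of source-unit intensities (e.g. decoded
#'   detector counts).
#' @param window A [window_spec()].
#' @param id Id for the resulting image.
#' @param invert If `TRUE`, invert the raw intensities before windowing
#'   (for acquisitions stored with the "bright = air" convention, e.g.
#'   MONOCHROME1), preserving "bright = dense" output.
#' @return An [image8()] with the same dimensions as `raw`.
#' @export
#' @examples
#' raw <- matrix(seq(0, 4096, length.out = 64), 8, 8)
#' window_to_8bit(raw, window_spec(2048, 4096))
window_to_8bit <- function(raw, window, id = "windowed", invert = FALSE) {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(raw))) {
    bad <- which(!is.finite(raw))[1]
    stop(sprintf("non-finite raw intensity at index %d", bad), call. = FALSE)
  }
  stopifnot(inherits(window, "window_spec"))
  if (isTRUE(invert)) raw <- max(raw) + min(raw) - raw
  lo <- window$level - window$width / 2
  frac <- clamp((raw - lo) / window$width, 0, 1)
  quantize_image8(255 * frac, id = id)
}

#' Resize an image with bilinear interpolation
#'
#' Resamples to `side` x `side` using bilinear interpolation with
#' half-pixel-centre alignment (source coordinate
#' `(t + 0.5) * scale - 0.5`), then rounds half-away-from-zero and clamps to
#' \[0, 255\]. Resizing a square image to its own side is the identity.
#'
#' @param image An [image8()].
#' @param side Target side length in pixels (>= 8).
#' @return An [image8()] of dimension `side` x `side`.
#' @export
resize_image <- function(image, side) {
  stopifnot(is_image8(image))
  side <- as.integer(side)
  if (length(side) != 1 || is.na(side) || side < 8) {
    stop("`side` must be a single integer >= 8", call. = FALSE)
  }
  m <- as.matrix(image)
  out <- bilinear_resample(m, side, side)
  quantize_image8(out, id = img_id(image))
}

# bilinear resample of a numeric matrix to nr x nc, half-pixel centres,
# edge-clamped
bilinear_resample <- function(m, nr, nc) {
  src_axis <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
    s <- clamp(s, 0, n_in - 1)
    i0 <- floor(s)
    w <- s - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    list(i0 = i0 + 1, i1 = i1 + 1, w = w)
  }
  ry <- src_axis(nr, nrow(m))
  rx <- src_axis(nc, ncol(m))
  top <- m[ry$i0, rx$i0, drop = FALSE] * rep((1 - rx$w), each = nr) +
    m[ry$i0, rx$i1, drop = FALSE] * rep(rx$w, each = nr)
  bot <- m[ry$i1, rx$i0, drop = FALSE] * rep((1 - rx$w), each = nr) +
    m[ry$i1, rx$i1, drop = FALSE] * rep(rx$w, each = nr)
  top * (1 - ry$w) + bot * ry$w
}

#' Read and write 8-bit grayscale PNG images
#'
#' `write_image_png()` persists an [image8()] as an 8-bit grayscale PNG;
#' `read_image_png()` reads one back bit-identically. Multi-channel PNGs are
#' converted to grayscale by the channel (luminance) average; 16-bit PNGs
#' are rejected.
#'
#' @param path File path.
#' @param id Id for the image read; defaults to the file name without
#'   extension.
#' @return `read_image_png()` returns an [image8()]; `write_image_png()`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path, id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  if (!is.null(info$bit.depth) && info$bit.depth > 8) {
    stop(sprintf("unsupported bit depth %d (only 8-bit PNGs are supported)",
                 info$bit.depth), call. = FALSE)
  }
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    # drop the alpha channel if present, average the colour channels
    ch <- if (nch %in% c(2, 4)) seq_len(nch - 1) else seq_len(nch)
    arr <- apply(arr[, , ch, drop = FALSE], c(1, 2), mean)
  }
  if (is.null(id)) id <- sub("\\.png$", "", basename(path), ignore.case = TRUE)
  quantize_image8(arr * 255, id = id)
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  stopifnot(is_image8(image))
  png::writePNG(as.matrix(image) / 255, target = path)
  invisible(path)
}
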