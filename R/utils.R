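# Internal numeric and seeding helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used for every intensity quantisation step in the
#' package (base R's `round()` rounds half to even, which does not port
#' across languages). `round_half_away(0.5)` is 1, `round_half_away(-0.5)`
#' is -1.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 32-bit FNV-1a over the UTF-8 bytes of a string, with the multiplication
# split into 16-bit halves so doubles stay exact. Returns a value in
# [0, 2^31 - 2] suitable for set.seed().
hash32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\r")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483646
}

# xor for doubles holding 32-bit unsigned values
bitwXor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a - a %% 65536) / 65536, (b - b %% 65536) / 65536)
  hi * 65536 + lo
}

# Deterministic seed fan-out: one master seed plus a stream label yields an
# independent 31-bit seed. Used for per-member training seeds, per-image
# perturbation draws, and pool generation.
fan_seed <- function(master, ...) {
  hash32(paste(master, ..., sep = "|"))
}

# Lightweight content fingerprint for provenance (not cryptographic):
# summarises a list of images plus an optional spec into a short hex-like tag.
fingerprint_images <- function(images, extra = NULL) {
  sums <- vapply(images, function(im) {
    p <- as.numeric(as.matrix(im))
    c(length(p), sum(p), sum(p * p) %% 1e9, p[1], p[length(p)])
  }, numeric(5))
  key <- paste(length(images),
               format(sum(sums), digits = 15),
               format(sum(sums[2, ]) %% 1e9, digits = 15),
               paste(unlist(extra), collapse = ","),
               sep = "/")
  sprintf("fp%08x", as.integer(hash32(key)))
}
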