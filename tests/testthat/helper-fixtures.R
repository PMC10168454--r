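# Shared fixtures and independent oracles for the test suite.

make_img <- function(m, id = "img") image8(m, id = id)

rand_img <- function(side = 16, seed = 1, lo = 0, hi = 255, id = NULL) {
  if (is.null(id)) id <- paste0("rand-", seed)
  withr::with_seed(seed,
    image8(matrix(sample(lo:hi, side * side, replace = TRUE), side, side),
           id = id))
}

# Independent bilinear resampler: naive double loop, half-pixel centres,
# edge clamped. Kept deliberately slow and literal.
reference_bilinear <- function(m, side) {
  out <- matrix(0, side, side)
  for (ty in seq_len(side)) {
    for (tx in seq_len(side)) {
      sy <- min(max((ty - 0.5) * nrow(m) / side - 0.5, 0), nrow(m) - 1)
      sx <- min(max((tx - 0.5) * ncol(m) / side - 0.5, 0), ncol(m) - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, nrow(m) - 1); x1 <- min(x0 + 1, ncol(m) - 1)
      wy <- sy - y0; wx <- sx - x0
      out[ty, tx] <- (1 - wy) * ((1 - wx) * m[y0 + 1, x0 + 1] +
                                   wx * m[y0 + 1, x1 + 1]) +
        wy * ((1 - wx) * m[y1 + 1, x0 + 1] + wx * m[y1 + 1, x1 + 1])
    }
  }
  out
}

# Brute-force AUC: literal loop over all (positive, negative) pairs,
# ties credited one half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Trapezoidal area under the empirical ROC curve.
trapezoid_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels == 1] >= t),
                     numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[labels == 0] >= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# A detective ensemble whose members each output a constant probability —
# for testing the ensembling rule and report plumbing without training.
constant_ensemble <- function(probs, ada_kind = "S", side = 16) {
  members <- lapply(probs, function(p) {
    w <- list(W1 = rep(0, 72), b1 = rep(0, 8),
              W2 = rep(0, 1152), b2 = rep(0, 16),
              W3 = rep(0, 4608), b3 = rep(0, 32),
              Wd = rep(0, 32), bd = stats::qlogis(p))
    list(weights = w, val_auc = NA_real_, best_epoch = NA_integer_,
         val_auc_history = numeric(0), seed = 0)
  })
  structure(list(members = members, ada_kind = ada_kind,
                 config = detective_config(ensemble_size = length(probs),
                                           image_side = side),
                 train_fingerprint = "fp-constant", certification = NULL),
            class = "detective_ensemble")
}

# Write a minimal 16-bit grayscale PNG (unsupported bit depth fixture),
# built chunk by chunk so no binary file ships with the package.
write_png16 <- function(path, w = 8L, h = 8L) {
  int_be <- function(x, n = 4) as.raw(rev((x %/% 256^(0:(n - 1))) %% 256))
  chunk <- function(type, data) {
    td <- c(charToRaw(type), data)
    crc <- digest::digest(td, algo = "crc32", serialize = FALSE)
    crc_raw <- as.raw(strtoi(substring(sprintf("%08s", crc),
                                       c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L))
    c(int_be(length(data)), td, crc_raw)
  }
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16, 0, 0, 0, 0)))
  scan <- do.call(c, lapply(seq_len(h), function(i) {
    c(as.raw(0), as.raw(rep(c(1, 0), w)))
  }))
  idat <- memCompress(scan, type = "gzip")
  writeBin(c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
             chunk("IHDR", ihdr), chunk("IDAT", idat),
             chunk("IEND", raw(0))), path)
  path
}

# Published deployment readouts used for decision-rule fidelity: five
# curated chest-radiograph datasets audited with sharpness (S) and
# contrast (C) detectives, with the verdicts the published audit reached
# (flag = shortcut present).
published_audits <- tibble::tibble(
  dataset = rep(c("COVIDx", "RoentGen-MIMIC", "UW", "BIMCV", "MIDRC"), 2),
  kind = rep(c("S", "C"), each = 5),
  auc = c(0.84, 0.37, 0.50, 0.47, 0.45,
          0.81, 0.05, 0.53, 0.56, 0.53),
  ci_low = c(0.83, 0.34, 0.48, 0.45, 0.45,
             0.80, 0.04, 0.51, 0.55, 0.52),
  ci_high = c(0.84, 0.39, 0.52, 0.48, 0.46,
              0.81, 0.06, 0.55, 0.57, 0.54),
  flagged = c(TRUE, TRUE, FALSE, FALSE, FALSE,
              TRUE, TRUE, FALSE, FALSE, FALSE)
)
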