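#' Area under the ROC curve (Mann–Whitney estimator)
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counted half:
#' `AUC = (1 / (n_pos * n_neg)) * sum over (pos, neg) pairs of
#' [s_pos > s_neg] + 0.5 * [s_pos == s_neg]`.
#' Computed via midranks in O(n log n); equals the trapezoidal area under
#' the empirical ROC curve and is invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Integer/numeric vector of 0/1 labels, same length.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' compute_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
compute_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("both labels must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUC with a stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately (each replicate preserves
#' `n_pos` and `n_neg`, so no replicate is degenerate), recomputes the AUC
#' `n_boot` times, and takes the percentile interval at
#' `(1 - level)/2` and `1 - (1 - level)/2`. Deterministic given `seed`.
#'
#' @inheritParams compute_auc
#' @param level Confidence level in (0, 1); 0.95 by default.
#' @param n_boot Number of bootstrap replicates (>= 1); 2000 by default.
#' @param seed Integer seed for the resampling.
#' @return An `auc_result` object: point estimate, `ci_low`/`ci_high`,
#'   level, replicate count, class counts and seed. `tidy()` turns it into
#'   a one-row tibble.
#' @export
#' @examples
#' set.seed(1)
#' s <- c(rnorm(20, 1), rnorm(20))
#' y <- rep(1:0, each = 20)
#' bootstrap_auc_ci(s, y, n_boot = 200, seed = 7)
bootstrap_auc_ci <- function(scores, labels, level = 0.95, n_boot = 2000,
                             seed = 0L) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  point <- compute_auc(scores, labels)  # validates labels too
  labels <- as.integer(labels)
  ipos <- which(labels == 1L)
  ineg <- which(labels == 0L)
  boots <- withr::with_seed(as.integer(seed) %% 2147483646, {
    vapply(seq_len(n_boot), function(b) {
      bp <- sample(ipos, length(ipos), replace = TRUE)
      bn <- sample(ineg, length(ineg), replace = TRUE)
      idx <- c(bp, bn)
      compute_auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  new_auc_result(auc = point, ci_low = ci[1], ci_high = ci[2],
                 level = level, n_boot = as.integer(n_boot),
                 n_pos = length(ipos), n_neg = length(ineg),
                 seed = as.integer(seed))
}

new_auc_result <- function(auc, ci_low, ci_high, level, n_boot, n_pos,
                           n_neg, seed) {
  structure(list(auc = auc, ci_low = ci_low, ci_high = ci_high,
                 level = level, n_boot = n_boot, n_pos = n_pos,
                 n_neg = n_neg, seed = seed),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.2f [%.2f, %.2f] (%d%% stratified bootstrap CI, %d reps; %d pos / %d neg)\n",
              x$auc, x$ci_low, x$ci_high, round(100 * x$level), x$n_boot,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.auc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 level = x$level, n_boot = x$n_boot, n_pos = x$n_pos,
                 n_neg = x$n_neg)
}

#' Complement an AUC under label reassignment
#'
#' An AUC of `a` under one label assignment is an AUC of `1 - a` under the
#' flipped assignment — both describe the same separation. Maps a bare
#' value, or an `auc_result` (swapping and complementing the CI bounds).
#'
#' @param x An AUC in \[0, 1\] or an `auc_result`.
#' @return Same shape as the input.
#' @export
#' @examples
#' auc_flip(0.0)   # 1
#' auc_flip(0.5)   # 0.5
auc_flip <- function(x) {
  if (inherits(x, "auc_result")) {
    new_auc_result(auc = 1 - x$auc, ci_low = 1 - x$ci_high,
                   ci_high = 1 - x$ci_low, level = x$level,
                   n_boot = x$n_boot, n_pos = x$n_pos, n_neg = x$n_neg,
                   seed = x$seed)
  } else {
    stopifnot(is.numeric(x), all(x >= 0 & x <= 1))
    1 - x
  }
}

#' @export
autoplot.auc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = "AUC", y = .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "AUC",
                  subtitle = sprintf("%d%% stratified bootstrap CI (%d replicates)",
                                     round(100 * object$level),
                                     object$n_boot)) +
    ggplot2::theme_minimal()
}

#' Serialise an AUC result to JSON
#'
#' Canonical JSON form used in reports:
#' `{"auc":..., "ci":[lo,hi], "level":0.95, "n_boot":2000, "n_pos":...,
#' "n_neg":..., "seed":...}`.
#'
#' @param x An `auc_result`.
#' @return A JSON string.
#' @export
auc_result_json <- function(x) {
  stopifnot(inherits(x, "auc_result"))
  jsonlite::toJSON(list(auc = x$auc, ci = c(x$ci_low, x$ci_high),
                        level = x$level, n_boot = x$n_boot,
                        n_pos = x$n_pos, n_neg = x$n_neg, seed = x$seed),
                   auto_unbox = TRUE, digits = NA)
}
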