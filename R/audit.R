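#' Certify a shortcut detective with the two-exam protocol
#'
#' A detective earns certification only if (Exam 1) it is at chance on a
#' dataset known to be free of its shortcut — proof that the features it
#' uses are not interwoven with the original imaging task — and (Exams
#' 2a/2b) it is near-perfect when its known perturbation is injected into
#' the positive class (AUC near 1) or the negative class (AUC near 0, the
#' label-flip mirror of the same separation). All three exam AUCs carry
#' stratified bootstrap confidence intervals.
#'
#' @param ensemble A `detective_ensemble` from [train_detective()].
#' @param shortcut_free A [labeled_dataset()] with both labels, believed
#'   free of the detective's shortcut.
#' @param spec The [ada_spec()] to inject for Exams 2a/2b; its kind must
#'   match the ensemble's.
#' @param delta_chance Exam 1 tolerance: pass requires
#'   `|AUC - 0.5| <= delta_chance` (default 0.10).
#' @param delta_perfect Exam 2 tolerance: pass requires Exam 2a
#'   `AUC >= 1 - delta_perfect` and Exam 2b `AUC <= delta_perfect`
#'   (default 0.05).
#' @param level,n_boot,seed Bootstrap CI settings passed to
#'   [bootstrap_auc_ci()].
#' @return A `certification_report` with the three exam `auc_result`s, the
#'   thresholds, the verdict `passed`, and provenance (spec serialisation,
#'   ensemble fingerprint).
#' @export
certify <- function(ensemble, shortcut_free, spec,
                    delta_chance = 0.10, delta_perfect = 0.05,
                    level = 0.95, n_boot = 2000, seed = 0L) {
  stopifnot(inherits(ensemble, "detective_ensemble"),
            inherits(shortcut_free, "labeled_dataset"),
            inherits(spec, "ada_spec"))
  assert_both_labels(shortcut_free, "shortcut-free exam dataset")
  if (!is.na(ensemble$ada_kind) && spec$kind != ensemble$ada_kind) {
    stop(sprintf("spec kind '%s' does not match the detective's kind '%s'",
                 spec$kind, ensemble$ada_kind), call. = FALSE)
  }
  exam <- function(ds, tag) {
    bootstrap_auc_ci(predict_scores(ensemble, ds), ds$label, level = level,
                     n_boot = n_boot, seed = fan_seed(seed, "exam", tag))
  }
  exam1 <- exam(shortcut_free, "1")
  exam2a <- exam(inject_shortcut(shortcut_free, "positive", spec), "2a")
  exam2b <- exam(inject_shortcut(shortcut_free, "negative", spec), "2b")
  passed <- abs(exam1$auc - 0.5) <= delta_chance &&
    exam2a$auc >= 1 - delta_perfect &&
    exam2b$auc <= delta_perfect
  structure(list(ada_kind = spec$kind, exam1 = exam1, exam2a = exam2a,
                 exam2b = exam2b,
                 thresholds = list(delta_chance = delta_chance,
                                   delta_perfect = delta_perfect),
                 passed = passed,
                 provenance = list(
                   spec = format_ada_spec(spec),
                   exam_dataset = dataset_name(shortcut_free),
                   ensemble_fingerprint = ensemble$train_fingerprint,
                   arch = ensemble$config$arch,
                   ensemble_size = length(ensemble$members))),
            class = "certification_report")
}

#' @export
print.certification_report <- function(x, ...) {
  fmt <- function(r) sprintf("%.2f [%.2f, %.2f]", r$auc, r$ci_low, r$ci_high)
  cat(sprintf("<certification_report ADA(%s): %s>\n", x$ada_kind,
              if (x$passed) "PASSED" else "FAILED"))
  cat(sprintf("  Exam 1  (shortcut-free):      %s  (need within %.2f of 0.50)\n",
              fmt(x$exam1), x$thresholds$delta_chance))
  cat(sprintf("  Exam 2a (shortcut in class 1): %s  (need >= %.2f)\n",
              fmt(x$exam2a), 1 - x$thresholds$delta_perfect))
  cat(sprintf("  Exam 2b (shortcut in class 0): %s  (need <= %.2f)\n",
              fmt(x$exam2b), x$thresholds$delta_perfect))
  invisible(x)
}

#' @export
tidy.certification_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$exam1), exam = "exam1", .before = 1),
    dplyr::mutate(tidy(x$exam2a), exam = "exam2a", .before = 1),
    dplyr::mutate(tidy(x$exam2b), exam = "exam2b", .before = 1)
  )
}

#' @export
glance.certification_report <- function(x, ...) {
  tibble::tibble(ada_kind = x$ada_kind, passed = x$passed,
                 exam1_auc = x$exam1$auc, exam2a_auc = x$exam2a$auc,
                 exam2b_auc = x$exam2b$auc,
                 delta_chance = x$thresholds$delta_chance,
                 delta_perfect = x$thresholds$delta_perfect)
}

#' @export
autoplot.certification_report <- function(object, ...) {
  d <- tidy(object)
  targets <- tibble::tibble(
    exam = c("exam1", "exam2a", "exam2b"),
    lo = c(0.5 - object$thresholds$delta_chance,
           1 - object$thresholds$delta_perfect, 0),
    hi = c(0.5 + object$thresholds$delta_chance, 1,
           object$thresholds$delta_perfect)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$exam, y = .data$auc)) +
    ggplot2::geom_rect(data = targets,
                       ggplot2::aes(x = NULL, y = NULL, xmin = as.numeric(factor(.data$exam)) - 0.35,
                                    xmax = as.numeric(factor(.data$exam)) + 0.35,
                                    ymin = .data$lo, ymax = .data$hi),
                       fill = "palegreen", alpha = 0.4) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "AUC",
                  title = sprintf("Certification exams, ADA(%s): %s",
                                  object$ada_kind,
                                  if (object$passed) "passed" else "failed")) +
    ggplot2::theme_minimal()
}

#' Attach a certification to its ensemble
#'
#' Verifies that the report was issued for this ensemble (fingerprint and
#' kind match) and records it, enabling non-advisory [detect_shortcut()]
#' flags and [audit_dataset()] deployment.
#'
#' @param ensemble A `detective_ensemble`.
#' @param report The `certification_report` from [certify()].
#' @return The ensemble with the certification recorded.
#' @export
attach_certification <- function(ensemble, report) {
  stopifnot(inherits(ensemble, "detective_ensemble"),
            inherits(report, "certification_report"))
  if (!identical(report$provenance$ensemble_fingerprint,
                 ensemble$train_fingerprint)) {
    stop("certification fingerprint does not match this ensemble",
         call. = FALSE)
  }
  ensemble$certification <- report
  ensemble
}

is_certified <- function(ensemble) {
  !is.null(ensemble$certification) && isTRUE(ensemble$certification$passed)
}

#' The shortcut-flagging decision rule
#'
#' A dataset is flagged for a shortcut when the detective's AUC deviates
#' from chance by at least `margin` in either direction (an AUC of `a` and
#' of `1 - a` describe the same separation under opposite label
#' assignments) *and* the bootstrap CI excludes 0.5. The deviation margin
#' keeps small-but-significant departures from chance (tight CIs on large
#' datasets) from being over-called.
#'
#' @param auc Point AUC estimate.
#' @param ci_low,ci_high Bootstrap CI bounds.
#' @param margin Minimum `|AUC - 0.5|` to flag (default 0.10).
#' @return Logical: flag or not.
#' @export
#' @examples
#' shortcut_flagged(0.84, 0.83, 0.84)  # TRUE
#' shortcut_flagged(0.56, 0.55, 0.57)  # FALSE: significant but small
shortcut_flagged <- function(auc, ci_low, ci_high, margin = 0.10) {
  abs(auc - 0.5) >= margin & (ci_low > 0.5 | ci_high < 0.5)
}

#' Deploy a detective on a curated dataset
#'
#' Scores the dataset, computes the AUC of the scores against the dataset's
#' own labels with a bootstrap CI, and applies the flagging rule
#' ([shortcut_flagged()]). An AUC away from 0.5 means the detective can
#' tell the classes apart — which, for a certified detective, can only be
#' because its acquisition attribute differs systematically between the
#' classes: a shortcut. Uncertified detectives produce advisory reports
#' (`flagged` stays `FALSE`, `certified = FALSE`).
#'
#' @param ensemble A `detective_ensemble` (ideally carrying a passed
#'   certification; see [attach_certification()]).
#' @param dataset The [labeled_dataset()] under audit (both labels
#'   required).
#' @param margin Deviation margin for the decision rule.
#' @param level,n_boot,seed Bootstrap CI settings.
#' @return A `detection_report`.
#' @export
detect_shortcut <- function(ensemble, dataset, margin = 0.10, level = 0.95,
                            n_boot = 2000, seed = 0L) {
  stopifnot(inherits(ensemble, "detective_ensemble"),
            inherits(dataset, "labeled_dataset"))
  assert_both_labels(dataset, "audited dataset")
  res <- bootstrap_auc_ci(predict_scores(ensemble, dataset), dataset$label,
                          level = level, n_boot = n_boot, seed = seed)
  certified <- is_certified(ensemble)
  flagged <- certified &&
    shortcut_flagged(res$auc, res$ci_low, res$ci_high, margin)
  structure(list(dataset_name = dataset_name(dataset),
                 ada_kind = ensemble$ada_kind, result = res,
                 margin = margin, flagged = flagged,
                 certified = certified),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report '%s', ADA(%s)%s>\n", x$dataset_name,
              x$ada_kind, if (x$certified) "" else " [advisory: uncertified detective]"))
  cat(sprintf("  AUC %.2f [%.2f, %.2f] -> %s (margin %.2f + CI excludes 0.5)\n",
              x$result$auc, x$result$ci_low, x$result$ci_high,
              if (x$flagged) "SHORTCUT FLAGGED" else "no shortcut flagged",
              x$margin))
  invisible(x)
}

#' @export
tidy.detection_report <- function(x, ...) {
  dplyr::mutate(tidy(x$result), dataset = x$dataset_name,
                ada_kind = x$ada_kind, margin = x$margin,
                flagged = x$flagged, certified = x$certified, .before = 1)
}

#' @export
glance.detection_report <- function(x, ...) tidy(x)

#' Audit a dataset with a panel of certified detectives
#'
#' Runs [detect_shortcut()] once per certified detective; uncertified
#' detectives are excluded with a warning. Errors if none remain.
#'
#' @param dataset The [labeled_dataset()] under audit.
#' @param detectives List of `detective_ensemble`s carrying certifications.
#' @inheritParams detect_shortcut
#' @return A list of `detection_report`s, one per certified detective;
#'   `tidy()` each (or `dplyr::bind_rows(purrr::map(reports, tidy))`) for
#'   a summary table.
#' @export
audit_dataset <- function(dataset, detectives, margin = 0.10, level = 0.95,
                          n_boot = 2000, seed = 0L) {
  stopifnot(is.list(detectives))
  ok <- vapply(detectives, is_certified, logical(1))
  if (any(!ok)) {
    warning(sprintf("excluding %d uncertified detective(s) from the audit",
                    sum(!ok)), call. = FALSE)
  }
  detectives <- detectives[ok]
  if (length(detectives) == 0) {
    stop("no certified detectives: run certify() first", call. = FALSE)
  }
  purrr::imap(detectives, function(ens, i) {
    detect_shortcut(ens, dataset, margin = margin, level = level,
                    n_boot = n_boot, seed = fan_seed(seed, "audit", i))
  })
}
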