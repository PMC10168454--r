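test_that("the decision rule reproduces every published audit verdict", {
  got <- shortcut_flagged(published_audits$auc, published_audits$ci_low,
                          published_audits$ci_high, margin = 0.10)
  expect_identical(got, published_audits$flagged)
})

test_that("the decision rule needs both the margin and CI evidence", {
  expect_true(shortcut_flagged(0.84, 0.83, 0.84))    # clear shortcut
  expect_false(shortcut_flagged(0.50, 0.48, 0.52))   # clear chance
  expect_false(shortcut_flagged(0.56, 0.55, 0.57))   # significant but small
  expect_false(shortcut_flagged(0.65, 0.45, 0.85))   # large but uncertain
  expect_true(shortcut_flagged(0.05, 0.04, 0.06))    # deviation below 0.5
})

test_that("a trained detective passes certification on phantom cohorts", {
  study <- micro_study("C")
  rep <- study$report
  expect_s3_class(rep, "certification_report")
  expect_true(rep$passed)
  expect_lte(abs(rep$exam1$auc - 0.5), rep$thresholds$delta_chance)
  expect_gte(rep$exam2a$auc, 1 - rep$thresholds$delta_perfect)
  expect_lte(rep$exam2b$auc, rep$thresholds$delta_perfect)
  # the passed flag is exactly the threshold invariant
  expect_identical(rep$passed,
                   abs(rep$exam1$auc - 0.5) <= rep$thresholds$delta_chance &&
                     rep$exam2a$auc >= 1 - rep$thresholds$delta_perfect &&
                     rep$exam2b$auc <= rep$thresholds$delta_perfect)
  d <- tidy(rep)
  expect_equal(d$exam, c("exam1", "exam2a", "exam2b"))
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("certification fails detectives that see the original task", {
  # a constant-score ensemble aces nothing: exam 2a stays at chance
  ens <- constant_ensemble(0.5, ada_kind = "S", side = 32)
  cohort <- generate_labeled_cohorts(30, 30, phantom_params(side = 32,
                                                            seed = 31))
  rep <- certify(ens, cohort, ada_spec("S", "increase", seed = 1),
                 n_boot = 100, seed = 2)
  expect_false(rep$passed)
})

test_that("certify enforces the kind contract and label presence", {
  study <- micro_study("C")
  expect_error(certify(study$ensemble, study$cohort,
                       ada_spec("S", "increase")), "kind")
  mono <- generate_labeled_cohorts(4, 4, phantom_params(side = 32, seed = 32))
  mono$label <- rep(1L, 8)
  expect_error(certify(study$ensemble, mono, ada_spec("C", "increase")),
               "both labels")
})

test_that("attach_certification verifies the fingerprint", {
  study <- micro_study("C")
  other <- constant_ensemble(0.5, ada_kind = "C", side = 32)
  expect_error(attach_certification(other, study$report), "fingerprint")
  stamped <- attach_certification(study$ensemble, study$report)
  expect_true(glance(stamped)$certified)
})

test_that("detect flags injected shortcuts and clears clean cohorts", {
  study <- micro_study("C")
  ens <- study$ensemble  # certification already attached by the study
  with_shortcut <- inject_shortcut(study$cohort, "positive", study$spec)
  hit <- detect_shortcut(ens, with_shortcut, n_boot = 200, seed = 5)
  expect_true(hit$flagged)
  expect_true(hit$certified)
  clean <- detect_shortcut(ens, study$cohort, n_boot = 200, seed = 5)
  expect_false(clean$flagged)
  d <- tidy(hit)
  expect_true(d$flagged)
  expect_equal(d$ada_kind, "C")
})

test_that("detect is symmetric under label inversion", {
  study <- micro_study("C")
  with_shortcut <- inject_shortcut(study$cohort, "positive", study$spec)
  flipped <- with_shortcut
  flipped$label <- 1L - flipped$label
  a <- detect_shortcut(study$ensemble, with_shortcut, n_boot = 200, seed = 6)
  b <- detect_shortcut(study$ensemble, flipped, n_boot = 200, seed = 6)
  expect_equal(b$result$auc, 1 - a$result$auc, tolerance = 1e-12)
  expect_identical(a$flagged, b$flagged)
})

test_that("uncertified detectives only produce advisory reports", {
  study <- micro_study("C")
  naked <- study$ensemble
  naked$certification <- NULL
  with_shortcut <- inject_shortcut(study$cohort, "positive", study$spec)
  rep <- detect_shortcut(naked, with_shortcut, n_boot = 100, seed = 7)
  expect_false(rep$certified)
  expect_false(rep$flagged)
})

test_that("audit_dataset deploys certified panels and excludes the rest", {
  study <- micro_study("C")
  uncert <- study$ensemble
  uncert$certification <- NULL
  with_shortcut <- inject_shortcut(study$cohort, "positive", study$spec)
  expect_warning(
    reports <- audit_dataset(with_shortcut,
                             list(good = study$ensemble, bad = uncert),
                             n_boot = 100),
    "uncertified")
  expect_length(reports, 1)
  expect_true(reports$good$flagged)
  expect_error(suppressWarnings(audit_dataset(with_shortcut, list(uncert))),
               "certify")
})
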