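test_that("compute_auc matches hand-checked cases", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(compute_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both labels")
  expect_error(compute_auc(1:3, c(1, 0)), "equal length")
})

test_that("compute_auc equals the pairwise and trapezoidal oracles", {
  for (s in 1:200) {
    inst <- withr::with_seed(s, {
      n <- sample(6:40, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
      list(scores = scores, labels = labels)
    })
    a <- compute_auc(inst$scores, inst$labels)
    expect_equal(a, brute_force_auc(inst$scores, inst$labels),
                 tolerance = 1e-12)
    expect_equal(a, trapezoid_auc(inst$scores, inst$labels),
                 tolerance = 1e-12)
  }
})

test_that("compute_auc agrees with pROC and is monotone-invariant", {
  for (s in 1:5) {
    inst <- withr::with_seed(s, {
      labels <- rbinom(50, 1, 0.4)
      labels[1:2] <- c(0, 1)
      scores <- rnorm(50)
      list(scores = scores, labels = labels)
    })
    expect_equal(compute_auc(inst$scores, inst$labels),
                 as.numeric(pROC::auc(pROC::roc(inst$labels, inst$scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(compute_auc(inst$scores, inst$labels),
                 compute_auc(exp(2 * inst$scores) + 5, inst$labels),
                 tolerance = 1e-12)
  }
})

test_that("label inversion complements the AUC exactly", {
  for (s in 1:200) {
    inst <- withr::with_seed(1000 + s, {
      labels <- c(0, 1, rbinom(18, 1, 0.5))
      scores <- round(runif(20), 1)
      list(scores = scores, labels = labels)
    })
    expect_equal(compute_auc(inst$scores, inst$labels),
                 1 - compute_auc(inst$scores, 1 - inst$labels),
                 tolerance = 1e-12)
  }
})

test_that("auc_flip complements values and swaps CI bounds", {
  expect_equal(auc_flip(0), 1)
  expect_equal(auc_flip(0.5), 0.5)
  expect_error(auc_flip(1.2))
  r <- bootstrap_auc_ci(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0), n_boot = 50,
                        seed = 1)
  f <- auc_flip(r)
  expect_equal(f$auc, 1 - r$auc)
  expect_equal(f$ci_low, 1 - r$ci_high)
  expect_equal(f$ci_high, 1 - r$ci_low)
  expect_lte(f$ci_low, f$ci_high)
})

test_that("perfect separation gives a degenerate [1, 1] interval", {
  scores <- c(seq(0.6, 0.9, length.out = 10), seq(0.1, 0.4, length.out = 10))
  labels <- rep(c(1, 0), each = 10)
  r <- bootstrap_auc_ci(scores, labels, n_boot = 500, seed = 3)
  expect_equal(r$auc, 1)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)
})

test_that("the stratified bootstrap matches an independent resampling oracle", {
  inst <- withr::with_seed(99, {
    labels <- rep(c(1, 0), each = 20)
    scores <- c(rnorm(20, 0.8), rnorm(20))
    list(scores = scores, labels = labels)
  })
  r <- bootstrap_auc_ci(inst$scores, inst$labels, level = 0.95,
                        n_boot = 200, seed = 7)
  # independently coded resampling path: same seeded stream, brute-force
  # pairwise AUC per replicate, explicit percentile quantiles
  ipos <- which(inst$labels == 1)
  ineg <- which(inst$labels == 0)
  boots <- withr::with_seed(7L, {
    vapply(1:200, function(b) {
      bp <- sample(ipos, length(ipos), replace = TRUE)
      bn <- sample(ineg, length(ineg), replace = TRUE)
      idx <- c(bp, bn)
      brute_force_auc(inst$scores[idx], inst$labels[idx])
    }, numeric(1))
  })
  want <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  expect_equal(r$ci_low, want[1], tolerance = 1e-12)
  expect_equal(r$ci_high, want[2], tolerance = 1e-12)
  expect_equal(r$n_pos, 20)
  expect_equal(r$n_neg, 20)
  # deterministic given the seed
  r2 <- bootstrap_auc_ci(inst$scores, inst$labels, level = 0.95,
                         n_boot = 200, seed = 7)
  expect_identical(tidy(r), tidy(r2))
})

test_that("bootstrap input validation", {
  expect_error(bootstrap_auc_ci(1:4, c(1, 1, 0, 0), n_boot = 0), "n_boot")
  expect_error(bootstrap_auc_ci(1:4, c(1, 1, 0, 0), level = 1.5), "level")
  expect_error(bootstrap_auc_ci(1:4, c(1, 1, 1, 1)), "both labels")
})

test_that("auc_result tidies to one row and plots", {
  r <- bootstrap_auc_ci(c(0.9, 0.2, 0.7, 0.4), c(1, 0, 1, 0), n_boot = 20,
                        seed = 2)
  d <- tidy(r)
  expect_s3_class(d, "tbl_df")
  expect_equal(nrow(d), 1)
  expect_named(d, c("auc", "ci_low", "ci_high", "level", "n_boot", "n_pos",
                    "n_neg"))
  expect_s3_class(autoplot(r), "ggplot")
})
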