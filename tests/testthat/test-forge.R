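test_that("build_detective_trainset splits the pool into two equal classes", {
  pool <- generate_pool(40, phantom_params(side = 32, seed = 2))
  spec <- ada_spec("C", "increase", seed = 5)
  ds <- build_detective_trainset(pool, spec, seed = 1)
  expect_equal(sum(ds$label == 1), 20)
  expect_equal(sum(ds$label == 0), 20)
  expect_identical(dataset_spec(ds)$kind, "C")
  # label-0 images are untouched pool members
  originals <- setNames(pool, vapply(pool, img_id, character(1)))
  for (i in which(ds$label == 0)) {
    expect_identical(as.matrix(ds$image[[i]]),
                     as.matrix(originals[[ds$id[i]]]))
  }
  # label-1 images carry the perturbation
  for (i in which(ds$label == 1)) {
    expect_identical(as.matrix(ds$image[[i]]),
                     as.matrix(apply_ada(originals[[ds$id[i]]], spec)))
  }
})

test_that("odd pools drop one image with a warning; tiny pools error", {
  pool <- generate_pool(41, phantom_params(side = 32, seed = 2))
  spec <- ada_spec("S", "increase", seed = 5)
  expect_warning(ds <- build_detective_trainset(pool, spec, seed = 1),
                 "odd pool")
  expect_equal(nrow(ds), 40)
  expect_error(build_detective_trainset(pool[1], spec, seed = 1),
               "at least 2")
})

test_that("trainset construction is deterministic given (pool, spec, seed)", {
  pool <- generate_pool(30, phantom_params(side = 32, seed = 3))
  spec <- ada_spec("S", "increase", seed = 9)
  a <- build_detective_trainset(pool, spec, seed = 4)
  b <- build_detective_trainset(pool, spec, seed = 4)
  expect_identical(a$label, b$label)
  expect_identical(lapply(a$image, as.matrix), lapply(b$image, as.matrix))
  c <- build_detective_trainset(pool, spec, seed = 5)
  expect_false(identical(a$label, c$label))
})

test_that("zero-strength specs leave the two classes exchangeable", {
  pool <- generate_pool(20, phantom_params(side = 32, seed = 6))
  spec <- ada_spec("C", "increase", strength_low = 0, strength_high = 0)
  ds <- build_detective_trainset(pool, spec, seed = 2)
  originals <- setNames(pool, vapply(pool, img_id, character(1)))
  for (i in seq_len(nrow(ds))) {
    expect_identical(as.matrix(ds$image[[i]]),
                     as.matrix(originals[[ds$id[i]]]))
  }
})

test_that("inject_shortcut perturbs only the targeted class", {
  cohort <- generate_labeled_cohorts(8, 8, phantom_params(side = 32, seed = 7))
  spec <- ada_spec("S", "increase", seed = 1)
  pos_in <- inject_shortcut(cohort, "positive", spec)
  expect_identical(pos_in$label, cohort$label)
  expect_identical(pos_in$id, cohort$id)
  for (i in which(cohort$label == 0)) {
    expect_identical(as.matrix(pos_in$image[[i]]),
                     as.matrix(cohort$image[[i]]))
  }
  neg_in <- inject_shortcut(cohort, "negative", spec)
  for (i in which(cohort$label == 1)) {
    expect_identical(as.matrix(neg_in$image[[i]]),
                     as.matrix(cohort$image[[i]]))
  }
  # and the targeted class did actually change
  expect_false(identical(as.matrix(pos_in$image[[1]]),
                         as.matrix(cohort$image[[1]])))
})

test_that("split_train_val stratifies, partitions, and varies with the seed", {
  ds <- generate_labeled_cohorts(50, 50, phantom_params(side = 32, seed = 8))
  parts <- split_train_val(ds, 0.2, seed = 1)
  expect_equal(nrow(parts$train) + nrow(parts$val), 100)
  expect_equal(nrow(parts$val), 20)
  expect_length(intersect(parts$train$id, parts$val$id), 0)
  expect_setequal(c(parts$train$id, parts$val$id), ds$id)
  expect_setequal(unique(parts$train$label), c(0, 1))
  expect_setequal(unique(parts$val$label), c(0, 1))
  differing <- sum(vapply(1:20, function(s) {
    a <- split_train_val(ds, 0.2, seed = s)$val$id
    b <- split_train_val(ds, 0.2, seed = s + 1000)$val$id
    !setequal(a, b)
  }, logical(1)))
  expect_gte(differing, 19)
})

test_that("split_train_val keeps a patient's images on one side", {
  pool <- generate_pool(40, phantom_params(side = 32, seed = 9))
  pid <- rep(sprintf("pt%02d", 1:10), each = 4)
  ds <- labeled_dataset(pool, rep(c(0L, 1L), 20), patient_id = pid)
  parts <- split_train_val(ds, 0.3, seed = 3)
  expect_length(intersect(parts$train$patient_id, parts$val$patient_id), 0)
})

test_that("split_train_val errors when both labels cannot reach both sides", {
  pool <- generate_pool(12, phantom_params(side = 32, seed = 10))
  labels <- c(rep(1L, 4), rep(0L, 8))
  pid <- c(rep("pt-all-pos", 4), sprintf("pt%d", 1:8))
  ds <- labeled_dataset(pool, labels, patient_id = pid)
  expect_error(split_train_val(ds, 0.3, seed = 1), "both labels")
  expect_error(split_train_val(ds, 1.2, seed = 1), "val_fraction")
})

test_that("datasets round-trip through the PNG + manifest format", {
  dir <- withr::local_tempdir()
  ds <- generate_labeled_cohorts(5, 5, phantom_params(side = 32, seed = 11),
                                 name = "rt")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(dir)
  ord <- match(ds$id, back$id)
  expect_identical(back$label[ord], ds$label)
  expect_identical(lapply(back$image[ord], as.matrix),
                   lapply(ds$image, as.matrix))
})
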