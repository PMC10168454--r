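#' Configuration of a shortcut-detective ensemble
#'
#' A detective is an ensemble of individually trained binary classifiers,
#' each trained on a different train/validation split; its score is the
#' member mean. Working-scale defaults (64 px input, `small-cnn`, 5 epochs,
#' batch 32, Adam at 1e-3) keep a full train-certify-audit cycle on a
#' single CPU; all fields are overridable, and larger architectures can be
#' registered for full-resolution runs.
#'
#' @param arch Architecture name; see [registry_get()]. Default
#'   `"small-cnn"`.
#' @param ensemble_size Number of members (>= 1; 5 matches the reference
#'   protocol, 3 is a faster working default).
#' @param image_side Input side in pixels; images are resized to this
#'   before training/scoring. Must be a multiple of 8, at least 16.
#' @param epochs Training epochs per member (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param val_fraction Fraction of the training data held out per member
#'   for validation-checkpoint selection.
#' @param seed Master seed; fans out to per-member split, initialisation
#'   and shuffle seeds.
#' @return A `detective_config` object.
#' @export
detective_config <- function(arch = "small-cnn", ensemble_size = 5,
                             image_side = 64, epochs = 5, batch_size = 32,
                             learning_rate = 1e-3, val_fraction = 0.2,
                             seed = 0L) {
  if (ensemble_size < 1) stop("ensemble_size must be >= 1", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  image_side <- as.integer(image_side)
  if (image_side < 16 || image_side %% 8 != 0) {
    stop("image_side must be a multiple of 8, at least 16", call. = FALSE)
  }
  structure(list(arch = arch, ensemble_size = as.integer(ensemble_size),
                 image_side = image_side, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "detective_config")
}

# ---- architecture registry ---------------------------------------------

.arch_registry <- new.env(parent = emptyenv())

register_arch <- function(name, constructor) {
  assign(name, constructor, envir = .arch_registry)
}

#' Look up an architecture in the registry
#'
#' The registry ships `"small-cnn"` — a compact CPU-scale convolutional
#' network (three 3x3 conv blocks of 8/16/32 channels with ReLU and 2x2
#' average pooling, global average pooling, sigmoid head) — as the default,
#' trainable architecture. The ImageNet-scale names (`"vgg-16"`,
#' `"densenet-121"`, `"efficientnet"`, `"swin-transformer"`,
#' `"convnext"`) are declared entries whose constructors describe what
#' would be needed to train them; they are not trainable in this package.
#'
#' @param arch_name Registered architecture name.
#' @return A constructor: a function of a [detective_config()] returning a
#'   list with `fit(X_train, y_train, X_val, y_val, seed)` and
#'   `predict(X, weights)` closures (pixel matrices are `side^2 x n`,
#'   intensities scaled to \[0, 1\]).
#' @export
#' @examples
#' names(registry_list())
registry_get <- function(arch_name) {
  if (!exists(arch_name, envir = .arch_registry, inherits = FALSE)) {
    stop(sprintf("unknown architecture '%s'; registered: %s", arch_name,
                 paste(sort(ls(.arch_registry)), collapse = ", ")),
         call. = FALSE)
  }
  get(arch_name, envir = .arch_registry, inherits = FALSE)
}

#' @rdname registry_get
#' @export
registry_list <- function() {
  as.list(.arch_registry)[sort(ls(.arch_registry))]
}

small_cnn_constructor <- function(config) {
  side <- config$image_side
  list(
    arch = "small-cnn",
    fit = function(X_train, y_train, X_val, y_val, seed) {
      fit <- cnn_train_cpp(X_train, as.integer(y_train), X_val,
                           as.integer(y_val), side, config$epochs,
                           config$batch_size, config$learning_rate,
                           as.integer(seed))
      fit
    },
    predict = function(X, weights) cnn_predict_cpp(X, side, weights)
  )
}

heavyweight_constructor <- function(name) {
  force(name)
  function(config) {
    stop(sprintf(paste0("architecture '%s' is registered for full-scale ",
                        "runs but has no trainable backend in this ",
                        "package; use arch = \"small-cnn\""), name),
         call. = FALSE)
  }
}

init_registry <- function() {
  register_arch("small-cnn", small_cnn_constructor)
  for (nm in c("vgg-16", "densenet-121", "efficientnet",
               "swin-transformer", "convnext")) {
    register_arch(nm, heavyweight_constructor(nm))
  }
}

# ---- training and scoring ----------------------------------------------

# stack a dataset's images into a (side^2 x n) double matrix in [0, 1],
# resizing where needed
pixel_matrix <- function(images, side) {
  cols <- purrr::map(images, function(im) {
    if (nrow(im) != side || ncol(im) != side) im <- resize_image(im, side)
    as.numeric(as.matrix(im)) / 255
  })
  matrix(unlist(cols), nrow = side * side, ncol = length(cols))
}

#' Train a shortcut-detective ensemble
#'
#' Trains `ensemble_size` members of the configured architecture, each on a
#' different train/validation split fanned out from the master seed. Each
#' member minimises binary cross-entropy; the epoch checkpoint with the
#' best validation AUC is kept. Training is deterministic given the data
#' and seed.
#'
#' @param dataset A [labeled_dataset()] with both labels present (typically
#'   from [build_detective_trainset()]).
#' @param config A [detective_config()].
#' @return A `detective_ensemble`: trained members with their validation
#'   metrics, the ADA kind it hunts (from the dataset's provenance spec, if
#'   any), the config, and a training-data fingerprint.
#' @export
train_detective <- function(dataset, config = detective_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "detective_config"))
  assert_both_labels(dataset, "training dataset")
  ctor <- registry_get(config$arch)(config)
  spec <- dataset_spec(dataset)
  members <- purrr::map(seq_len(config$ensemble_size), function(k) {
    split_seed <- fan_seed(config$seed, "member-split", k)
    parts <- split_train_val(dataset, config$val_fraction, seed = split_seed)
    Xtr <- pixel_matrix(parts$train$image, config$image_side)
    Xval <- pixel_matrix(parts$val$image, config$image_side)
    fit <- ctor$fit(Xtr, parts$train$label, Xval, parts$val$label,
                    seed = fan_seed(config$seed, "member-init", k))
    list(weights = fit$weights, val_auc = fit$best_val_auc,
         best_epoch = fit$best_epoch,
         val_auc_history = as.numeric(fit$val_auc_history),
         seed = fan_seed(config$seed, "member-init", k))
  })
  structure(list(members = members,
                 ada_kind = if (!is.null(spec)) spec$kind else NA_character_,
                 config = config,
                 train_fingerprint = fingerprint_images(
                   dataset$image,
                   extra = if (!is.null(spec)) unclass(spec) else NULL),
                 certification = NULL),
            class = "detective_ensemble")
}

#' @export
print.detective_ensemble <- function(x, ...) {
  cat(sprintf("<detective_ensemble: %d x %s @ %dpx, ADA kind %s, fingerprint %s>\n",
              length(x$members), x$config$arch, x$config$image_side,
              x$ada_kind, x$train_fingerprint))
  cat(sprintf("  member validation AUCs: %s\n",
              paste(sprintf("%.3f", vapply(x$members, `[[`, numeric(1),
                                           "val_auc")), collapse = ", ")))
  if (!is.null(x$certification)) {
    cat(sprintf("  certification: %s\n",
                if (x$certification$passed) "PASSED" else "failed"))
  }
  invisible(x)
}

#' Score images with a detective ensemble
#'
#' Each image's score is the arithmetic mean of the member probabilities
#' (of carrying the perturbed-class attribute). Order is preserved and the
#' result is invariant to how the input list is batched.
#'
#' @param ensemble A `detective_ensemble` from [train_detective()].
#' @param images A list of [image8()] objects, or a [labeled_dataset()]
#'   (whose image column is used).
#' @return Numeric vector of scores in \[0, 1\], one per image.
#' @export
predict_scores <- function(ensemble, images) {
  stopifnot(inherits(ensemble, "detective_ensemble"))
  if (inherits(images, "labeled_dataset")) images <- images$image
  if (length(images) == 0) return(numeric(0))
  ctor <- registry_get(ensemble$config$arch)(ensemble$config)
  X <- pixel_matrix(images, ensemble$config$image_side)
  member_scores <- purrr::map(ensemble$members,
                              ~ ctor$predict(X, .x$weights))
  Reduce(`+`, member_scores) / length(member_scores)
}

#' @export
tidy.detective_ensemble <- function(x, ...) {
  tibble::tibble(
    member = seq_along(x$members),
    seed = vapply(x$members, `[[`, numeric(1), "seed"),
    best_epoch = vapply(x$members, `[[`, numeric(1), "best_epoch"),
    val_auc = vapply(x$members, `[[`, numeric(1), "val_auc")
  )
}

#' @export
glance.detective_ensemble <- function(x, ...) {
  tibble::tibble(
    arch = x$config$arch,
    ensemble_size = length(x$members),
    image_side = x$config$image_side,
    ada_kind = x$ada_kind,
    mean_val_auc = mean(vapply(x$members, `[[`, numeric(1), "val_auc")),
    certified = !is.null(x$certification) && isTRUE(x$certification$passed),
    fingerprint = x$train_fingerprint
  )
}

# ---- persistence --------------------------------------------------------

#' Save / load a detective ensemble
#'
#' Each member serialises to `member_<k>.json` (its weights) next to an
#' `ensemble.json` sidecar holding the architecture, input side, ADA kind
#' and training fingerprint. Loading verifies the fingerprint recorded in
#' the sidecar against the member files.
#'
#' @param ensemble A `detective_ensemble`.
#' @param dir Checkpoint directory.
#' @return `save_ensemble()` returns `dir` invisibly; `load_ensemble()`
#'   returns the ensemble.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "detective_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(ensemble$members)) {
    jsonlite::write_json(ensemble$members[[k]],
                         file.path(dir, sprintf("member_%d.json", k)),
                         auto_unbox = TRUE, digits = NA)
  }
  meta <- list(arch = ensemble$config$arch,
               config = unclass(ensemble$config),
               ada_kind = ensemble$ada_kind,
               train_fingerprint = ensemble$train_fingerprint,
               n_members = length(ensemble$members))
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(detective_config, meta$config[names(meta$config) != "arch"])
  cfg$arch <- meta$arch
  members <- purrr::map(seq_len(meta$n_members), function(k) {
    m <- jsonlite::read_json(file.path(dir, sprintf("member_%d.json", k)),
                             simplifyVector = TRUE)
    m$weights <- purrr::map(m$weights, as.numeric)
    m
  })
  structure(list(members = members, ada_kind = meta$ada_kind, config = cfg,
                 train_fingerprint = meta$train_fingerprint,
                 certification = NULL),
            class = "detective_ensemble")
}
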