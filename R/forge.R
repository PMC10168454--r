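#' Build a shortcut-detective training set from a finding-free pool
#'
#' Randomly divides a pool of finding-free images into two equal groups:
#' one half is assigned label 1 and perturbed with the spec's attribute
#' adjustment, the other half keeps label 0 untouched. Because the pool
#' contains no findings, nothing but the manufactured global attribute
#' separates the classes — any classifier that learns to tell them apart
#' has, by construction, learned the attribute.
#'
#' @param pool List of [image8()] objects (all finding-free).
#' @param spec An [ada_spec()] describing the shortcut to manufacture.
#' @param seed Integer seed fixing the random 50/50 split.
#' @return A [labeled_dataset()] with the spec recorded as provenance.
#' @export
#' @examples
#' pool <- generate_pool(20, phantom_params(side = 32))
#' ds <- build_detective_trainset(pool, ada_spec("C", "increase"), seed = 1)
#' table(ds$label)
build_detective_trainset <- function(pool, spec, seed = 0L) {
  stopifnot(is.list(pool), inherits(spec, "ada_spec"))
  if (length(pool) < 2) {
    stop("pool must contain at least 2 images", call. = FALSE)
  }
  withr::with_seed(fan_seed(seed, "forge"), {
    if (length(pool) %% 2 == 1) {
      drop <- sample.int(length(pool), 1)
      warning(sprintf("odd pool size %d: dropping image '%s'",
                      length(pool), img_id(pool[[drop]])), call. = FALSE)
      pool <- pool[-drop]
    }
    n <- length(pool)
    pos <- sample.int(n, n / 2)
  })
  labels <- integer(n)
  labels[pos] <- 1L
  images <- purrr::map2(pool, labels, function(im, lab) {
    if (lab == 1L) apply_ada(im, spec) else im
  })
  labeled_dataset(images, labels, name = "detective-trainset",
                  ada_spec = spec)
}

#' Inject a known shortcut into one class of a labeled dataset
#'
#' Transforms every image carrying the targeted label with the spec's
#' perturbation, leaving the other class bit-identical and labels and row
#' order unchanged. Used to build the certification exam datasets: a
#' detective worth certifying must score near-perfect AUC when the shortcut
#' sits in the positive class and near-zero when it sits in the negative
#' class.
#'
#' @param dataset A [labeled_dataset()].
#' @param target `"positive"` (label 1) or `"negative"` (label 0).
#' @param spec An [ada_spec()].
#' @return The dataset with the targeted class perturbed; the spec and
#'   target are recorded as provenance.
#' @export
inject_shortcut <- function(dataset, target = c("positive", "negative"),
                            spec) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(spec, "ada_spec"))
  target <- match.arg(target)
  tlab <- if (target == "positive") 1L else 0L
  out <- dataset
  out$image <- purrr::map2(dataset$image, dataset$label, function(im, lab) {
    if (lab == tlab) apply_ada(im, spec) else im
  })
  new_labeled_dataset(out,
                      name = sprintf("%s+%s(%s)", dataset_name(dataset),
                                     spec$kind,
                                     if (target == "positive") "+" else "-"),
                      ada_spec = spec)
}

#' Split a dataset into training and validation parts
#'
#' Disjoint, exhaustive partition. When patient ids are present every image
#' of a patient lands on the same side (grouped split, preventing
#' patient-level leakage into validation); otherwise the split is stratified
#' by label. Both parts must end up with both labels, otherwise an error is
#' raised.
#'
#' @param dataset A [labeled_dataset()].
#' @param val_fraction Fraction of images for the validation side, in (0,1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `val`, both
#'   [labeled_dataset()]s.
#' @export
split_train_val <- function(dataset, val_fraction = 0.2, seed = 0L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("`val_fraction` must be in (0, 1)", call. = FALSE)
  }
  assert_both_labels(dataset)
  n <- nrow(dataset)
  has_patients <- any(!is.na(dataset$patient_id))
  ok <- function(idx) {
    length(idx) > 0 && length(idx) < n &&
      length(unique(dataset$label[idx])) == 2 &&
      length(unique(dataset$label[-idx])) == 2
  }
  val_idx <- NULL
  if (has_patients) {
    # treat NA patients as singleton groups
    grp <- ifelse(is.na(dataset$patient_id),
                  paste0(".solo.", seq_len(n)), dataset$patient_id)
    groups <- split(seq_len(n), grp)
    for (attempt in seq_len(20)) {
      cand <- withr::with_seed(fan_seed(seed, "split", attempt), {
        ord <- sample(length(groups))
        take <- integer(0)
        for (g in ord) {
          if (length(take) >= val_fraction * n) break
          take <- c(take, groups[[g]])
        }
        take
      })
      if (ok(cand)) { val_idx <- cand; break }
    }
  } else {
    for (attempt in seq_len(20)) {
      cand <- withr::with_seed(fan_seed(seed, "split", attempt), {
        unlist(lapply(split(seq_len(n), dataset$label), function(idx) {
          k <- max(1L, round(val_fraction * length(idx)))
          sample(idx, min(k, length(idx) - 1L))
        }), use.names = FALSE)
      })
      if (ok(cand)) { val_idx <- cand; break }
    }
  }
  if (is.null(val_idx)) {
    stop("cannot split: no partition puts both labels on both sides",
         call. = FALSE)
  }
  keep <- function(rows, tag) {
    new_labeled_dataset(dataset[rows, ],
                        name = paste0(dataset_name(dataset), "-", tag),
                        ada_spec = dataset_spec(dataset))
  }
  list(train = keep(setdiff(seq_len(n), val_idx), "train"),
       val = keep(sort(val_idx), "val"))
}
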