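#' Binary-labeled image datasets
#'
#' A `labeled_dataset` is a tibble with one row per image and columns
#' `id` (unique character), `image` (list-column of [image8()]), `label`
#' (integer 0/1) and `patient_id` (character, `NA` when unknown). It is both
#' the detective's training material and the audit target. Standard dplyr
#' verbs work on it; the constructor re-checks the invariants.
#'
#' @param images List of [image8()] objects.
#' @param labels Integer vector of 0/1 labels, one per image.
#' @param patient_id Optional character vector of patient identifiers
#'   (grouped train/validation splitting keeps a patient on one side).
#' @param name Dataset name, kept as an attribute for reports.
#' @param ada_spec Optional [ada_spec()] recording the perturbation that
#'   built the dataset (provenance).
#' @return A `labeled_dataset` tibble.
#' @export
labeled_dataset <- function(images, labels, patient_id = NULL,
                            name = "dataset", ada_spec = NULL) {
  stopifnot(is.list(images), length(images) == length(labels))
  if (!all(vapply(images, is_image8, logical(1)))) {
    stop("all images must be image8 objects", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  ids <- vapply(images, img_id, character(1))
  if (anyDuplicated(ids)) {
    stop("image ids must be unique within a dataset", call. = FALSE)
  }
  if (is.null(patient_id)) patient_id <- rep(NA_character_, length(images))
  out <- tibble::tibble(id = ids, image = images, label = labels,
                        patient_id = as.character(patient_id))
  new_labeled_dataset(out, name = name, ada_spec = ada_spec)
}

new_labeled_dataset <- function(tbl, name = "dataset", ada_spec = NULL) {
  structure(tbl,
            class = c("labeled_dataset", class(tibble::tibble())),
            ds_name = name, ada_spec = ada_spec)
}

#' @rdname labeled_dataset
#' @param dataset A `labeled_dataset`.
#' @export
dataset_name <- function(dataset) {
  attr(dataset, "ds_name") %||% "dataset"
}

dataset_spec <- function(dataset) attr(dataset, "ada_spec")

assert_both_labels <- function(dataset, what = "dataset") {
  if (length(unique(dataset$label)) < 2) {
    stop(sprintf("%s must contain both labels (0 and 1)", what),
         call. = FALSE)
  }
  invisible(dataset)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset '%s': %d images (%d positive, %d negative)>\n",
              dataset_name(x), nrow(x), sum(x$label == 1), sum(x$label == 0)))
  sp <- dataset_spec(x)
  if (!is.null(sp)) cat(" shortcut provenance:", format_ada_spec(sp), "\n")
  NextMethod()
}

#' Persist / load a dataset as PNG files plus a CSV manifest
#'
#' The on-disk interchange format: a directory of 8-bit grayscale PNGs and a
#' `manifest.csv` with header `path,label,patient_id` (paths relative to the
#' manifest). Any perturbation provenance is written to an
#' `ada_spec.yml`-style sidecar of `key=value` lines.
#'
#' @param dataset A [labeled_dataset()].
#' @param dir Directory to write into (created if needed).
#' @return `write_dataset()` returns the manifest path invisibly;
#'   `read_dataset()` returns a [labeled_dataset()].
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(dataset$id, ".png"))
  purrr::walk2(dataset$image, paths, write_image_png)
  manifest <- data.frame(path = basename(paths), label = dataset$label,
                         patient_id = ifelse(is.na(dataset$patient_id), "",
                                             dataset$patient_id))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  sp <- dataset_spec(dataset)
  if (!is.null(sp)) {
    writeLines(sprintf("%s=%s", names(unclass(sp)),
                       vapply(unclass(sp), format, character(1))),
               file.path(dir, "ada_spec.cfg"))
  }
  invisible(mpath)
}

#' @rdname write_dataset
#' @param name Dataset name; defaults to the directory name.
#' @export
read_dataset <- function(dir, name = basename(normalizePath(dir))) {
  mpath <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  if (!file.exists(mpath)) {
    stop(sprintf("no manifest found at %s", mpath), call. = FALSE)
  }
  manifest <- utils::read.csv(mpath, colClasses = "character")
  need <- c("path", "label", "patient_id")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns path,label,patient_id", call. = FALSE)
  }
  base <- dirname(mpath)
  images <- purrr::map(manifest$path, ~ read_image_png(file.path(base, .x)))
  pid <- ifelse(manifest$patient_id == "", NA_character_, manifest$patient_id)
  labeled_dataset(images, as.integer(manifest$label), patient_id = pid,
                  name = name)
}
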