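#' Image catalogs
#'
#' A catalog is the package's inventory of labeled, located camera-trap
#' images. Each record carries an image identifier, a file path, a species
#' (or human-activity) label, the identifier of the camera location that took
#' the image, an optional burst/sequence identifier and timestamp, and a flag
#' marking augmented supplementation copies. The ordered sets of classes and
#' locations are fixed at construction in first-appearance order; downstream
#' protocols (notably the location-blocked folds) depend on that
#' deterministic ordering.
#'
#' @param records A data frame with columns `image_id`, `path`,
#'   `class_label`, `location_id` and optionally `sequence_id`, `captured_at`
#'   and `is_augmented`.
#' @param images Optional named list of pixel arrays keyed by `image_id`,
#'   used to carry an in-memory synthetic world without touching disk.
#' @return An object of class `catalog`: a list with elements `records`
#'   (data frame), `classes` and `locations` (character vectors in
#'   first-appearance order), and `images` (possibly `NULL`).
#' @examples
#' rec <- data.frame(
#'   image_id = c("a", "b", "c"),
#'   path = NA_character_,
#'   class_label = c("Elk", "Elk", "Wolf"),
#'   location_id = c("L1", "L2", "L1")
#' )
#' cat1 <- catalog(rec)
#' cat1$classes
#' class_counts(cat1)
#' @export
catalog <- function(records, images = NULL) {
  required <- c("image_id", "path", "class_label", "location_id")
  optional <- c("sequence_id", "captured_at", "is_augmented")
  stopifnot(is.data.frame(records))
  for (col in required) {
    if (!col %in% names(records)) {
      stop(sprintf("catalog records are missing required column '%s'", col),
           call. = FALSE)
    }
  }
  for (col in setdiff(optional, names(records))) {
    records[[col]] <- if (col == "is_augmented") {
      rep(FALSE, nrow(records))
    } else {
      rep(NA_character_, nrow(records))
    }
  }
  records <- records[, c(required, optional)]
  records$image_id <- as.character(records$image_id)
  records$class_label <- as.character(records$class_label)
  records$location_id <- as.character(records$location_id)
  records$is_augmented <- as.logical(records$is_augmented)
  records$is_augmented[is.na(records$is_augmented)] <- FALSE
  rownames(records) <- NULL

  if (nrow(records) > 0) {
    bad <- which(is.na(records$class_label) | records$class_label == "")
    if (length(bad) > 0) {
      stop(sprintf("empty class label at manifest row %d", bad[1]), call. = FALSE)
    }
    bad <- which(is.na(records$location_id) | records$location_id == "")
    if (length(bad) > 0) {
      stop(sprintf("empty location id at manifest row %d", bad[1]), call. = FALSE)
    }
    if (anyDuplicated(records$image_id)) {
      dup <- records$image_id[duplicated(records$image_id)][1]
      stop(sprintf("duplicate image_id '%s' in catalog", dup), call. = FALSE)
    }
  }
  structure(
    list(
      records = records,
      classes = unique(records$class_label),
      locations = unique(records$location_id),
      images = images
    ),
    class = "catalog"
  )
}

#' @export
print.catalog <- function(x, ...) {
  cat(sprintf(
    "<catalog> %d images (%d augmented), %d classes, %d locations\n",
    nrow(x$records), sum(x$records$is_augmented),
    length(x$classes), length(x$locations)
  ))
  if (length(x$classes) > 0) {
    cc <- class_counts(x)
    shown <- head(sort(cc, decreasing = TRUE), 5)
    cat("  top classes:",
        paste(sprintf("%s (%d)", names(shown), shown), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of images in a catalog
#' @param x A `catalog`.
#' @param ... Unused.
#' @export
length.catalog <- function(x) nrow(x$records)

#' Read an image manifest into a catalog
#'
#' The manifest is a UTF-8, comma-delimited CSV with a header. Required
#' columns: `image_path`, `class_label`, `location_id`. Optional columns:
#' `image_id` (generated as `img_000001, ...` when absent), `sequence_id`,
#' `captured_at`, `is_augmented`. Row order is preserved; classes and
#' locations are deduplicated in first-appearance order.
#'
#' @param path Path to the manifest CSV.
#' @return A [catalog()].
#' @seealso [save_manifest()] for the inverse operation.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest '%s' not found", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("image_path", "class_label", "location_id")
  for (col in required) {
    if (!col %in% names(df)) {
      stop(sprintf("manifest is missing required column '%s'", col), call. = FALSE)
    }
  }
  n <- nrow(df)
  rec <- data.frame(
    image_id = if ("image_id" %in% names(df)) df$image_id else sprintf("img_%06d", seq_len(n)),
    path = df$image_path,
    class_label = df$class_label,
    location_id = df$location_id,
    stringsAsFactors = FALSE
  )
  if ("sequence_id" %in% names(df)) rec$sequence_id <- df$sequence_id
  if ("captured_at" %in% names(df)) rec$captured_at <- df$captured_at
  if ("is_augmented" %in% names(df)) {
    rec$is_augmented <- tolower(df$is_augmented) %in% c("true", "1", "t")
  }
  catalog(rec)
}

#' Write a catalog back to a manifest CSV
#'
#' Writes every record field, so `load_manifest(save_manifest(x))` returns a
#' catalog identical to `x` field-for-field (in-memory images are not
#' serialized).
#'
#' @param cat A [catalog()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(cat, path) {
  stopifnot(inherits(cat, "catalog"))
  r <- cat$records
  out <- data.frame(
    image_id = r$image_id,
    image_path = r$path,
    class_label = r$class_label,
    location_id = r$location_id,
    sequence_id = r$sequence_id,
    captured_at = r$captured_at,
    is_augmented = ifelse(r$is_augmented, "true", "false"),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-class image counts
#'
#' @param cat A [catalog()].
#' @param include_augmented Count augmented supplementation copies as well?
#' @return Named integer vector of counts in catalog class order, summing to
#'   the number of selected records.
#' @export
class_counts <- function(cat, include_augmented = TRUE) {
  stopifnot(inherits(cat, "catalog"))
  r <- cat$records
  if (!include_augmented) r <- r[!r$is_augmented, , drop = FALSE]
  if (nrow(r) == 0) return(setNames(integer(0), character(0)))
  tab <- table(factor(r$class_label, levels = cat$classes))
  setNames(as.integer(tab), cat$classes)
}

#' Per-location image counts
#' @inheritParams class_counts
#' @return Named integer vector in catalog location order.
#' @export
location_counts <- function(cat, include_augmented = TRUE) {
  stopifnot(inherits(cat, "catalog"))
  r <- cat$records
  if (!include_augmented) r <- r[!r$is_augmented, , drop = FALSE]
  if (nrow(r) == 0) return(setNames(integer(0), character(0)))
  tab <- table(factor(r$location_id, levels = cat$locations))
  setNames(as.integer(tab), cat$locations)
}

#' Load the packaged per-species recall table
#'
#' The package ships `table1_parks.csv`, a transcription of the published
#' per-species results table from a Parks Canada camera-trap study: for each
#' of 55 classes (54 species/human activities plus a "No Animal" class), the
#' number of training and testing images under the trained-location split and
#' the per-class recall of six convolutional network architectures plus their
#' voting ensemble. It is used for worked examples and to calibrate the
#' recall-versus-training-size analysis conventions.
#'
#' @param path Path to a recall-table CSV; defaults to the packaged fixture.
#' @return A data frame of class `class_recall_table` with columns
#'   `class_label`, `n_train`, `n_test` and one numeric recall column per
#'   model, plus a `models` attribute listing the model column names.
#' @examples
#' t1 <- load_table1_fixture()
#' nrow(t1)                       # 55 classes
#' sum(t1$n_train + t1$n_test)    # 47279 images
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_parks.csv", package = "camtrapeval")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("class_label", "n_train", "n_test")
  for (col in needed) {
    if (!col %in% names(df)) {
      stop(sprintf("recall table is missing required column '%s'", col), call. = FALSE)
    }
  }
  if (nrow(df) != 55) {
    stop(sprintf("fixture integrity: expected 55 classes, found %d", nrow(df)),
         call. = FALSE)
  }
  models <- setdiff(names(df), needed)
  for (m in models) {
    v <- as.numeric(df[[m]])
    if (any(is.na(v) | v < 0 | v > 1)) {
      stop(sprintf("fixture integrity: recalls for '%s' outside [0, 1]", m),
           call. = FALSE)
    }
    df[[m]] <- v
  }
  if (any(df$n_train < 0) || any(df$n_test < 0)) {
    stop("fixture integrity: negative image counts", call. = FALSE)
  }
  structure(df, models = models, class = c("class_recall_table", "data.frame"))
}
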