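#' Train/test split protocols
#'
#' Two partition protocols are implemented. The *trained-location* protocol
#' draws one seeded random permutation of all image indices and assigns the
#' leading share to training, so every camera location contributes imagery to
#' both sides - test backgrounds have been seen during training. The
#' *untrained-location* protocol blocks by camera location: a k-fold plan
#' assigns each location to exactly one contiguous test block (in the
#' catalog's deterministic location order), so no test image's background is
#' ever available at training time. The contrast between the two protocols
#' is what quantifies domain shift across camera sites.
#'
#' @name split-protocols
NULL

new_split <- function(protocol, train_ids, test_ids, seed, fold_index = NA_integer_) {
  structure(
    list(protocol = protocol, train_ids = train_ids, test_ids = test_ids,
         seed = seed, fold_index = fold_index),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split:%s> %d train / %d test%s\n", x$protocol,
              length(x$train_ids), length(x$test_ids),
              if (!is.na(x$fold_index)) sprintf(" (fold %d)", x$fold_index) else ""))
  invisible(x)
}

#' Random image-level split with trained locations
#'
#' Takes a seeded random permutation of the non-augmented record indices;
#' the first `ceiling((1 - test_fraction) * N)` permuted records train, the
#' remainder test. The split is a single global permutation - deliberately
#' not stratified by class or grouped by burst.
#'
#' @param cat A [catalog()].
#' @param test_fraction Fraction of images held out for testing, in (0, 1);
#'   default 0.10 (a 90/10 split).
#' @param seed Integer seed; the assignment is deterministic per seed.
#' @return A `split_assignment` with `protocol = "trained_location"`.
#' @export
trained_location_split <- function(cat, test_fraction = 0.10, seed = 1) {
  stopifnot(inherits(cat, "catalog"),
            test_fraction > 0, test_fraction < 1)
  ids <- cat$records$image_id[!cat$records$is_augmented]
  n <- length(ids)
  if (n < 2) stop("catalog needs at least 2 non-augmented records to split", call. = FALSE)
  perm <- with_seed(derive_seed(seed, "trained_split"), sample.int(n))
  n_train <- ceiling((1 - test_fraction) * n)
  test_idx <- if (n_train < n) perm[(n_train + 1L):n] else integer(0)
  new_split("trained_location",
            train_ids = ids[perm[seq_len(n_train)]],
            test_ids = ids[test_idx],
            seed = seed)
}

#' Location-blocked k-fold plan
#'
#' Partitions an ordered location list into k contiguous test blocks with
#' boundaries `b_i = floor(L * i / k + 0.5)` (round-half-up), so block sizes
#' differ by at most one and fold i tests the block between `b_(i-1)` and
#' `b_i`. The location order is the catalog's deterministic first-appearance
#' order; the plan depends only on that order, not on the images.
#'
#' @param locations Ordered character vector of location tokens (or a
#'   [catalog()], whose location order is used).
#' @param k Number of folds (default 5).
#' @return An object of class `fold_plan`: list with `k`, `locations`, and
#'   `folds`, an ordered list of `list(train_locations, test_locations)`.
#' @examples
#' plan <- location_kfold_plan(sprintf("L%02d", 1:36), k = 5)
#' vapply(plan$folds, function(f) length(f$test_locations), integer(1))
#' @export
location_kfold_plan <- function(locations, k = 5) {
  if (inherits(locations, "catalog")) locations <- locations$locations
  locations <- as.character(locations)
  L <- length(locations)
  stopifnot(k >= 2)
  if (L < k) {
    stop(sprintf("need at least k = %d locations, have %d", k, L), call. = FALSE)
  }
  bounds <- floor(L * seq_len(k) / k + 0.5)
  bounds[k] <- L
  lo <- c(0L, bounds[-k]) + 1L
  folds <- lapply(seq_len(k), function(i) {
    test <- locations[lo[i]:bounds[i]]
    list(train_locations = setdiff(locations, test), test_locations = test)
  })
  structure(list(k = as.integer(k), locations = locations, folds = folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test_locations), integer(1))
  cat(sprintf("<fold plan> k = %d over %d locations; test block sizes: %s\n",
              x$k, length(x$locations), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Materialize one fold of a location-blocked plan
#'
#' @param cat A [catalog()].
#' @param plan A [location_kfold_plan()].
#' @param fold_index Fold number in `1..k`.
#' @return A `split_assignment` with `protocol = "untrained_location"`:
#'   every test image comes from that fold's test locations, every training
#'   image from the remaining locations; augmented records never enter the
#'   test side.
#' @export
materialize_fold <- function(cat, plan, fold_index) {
  stopifnot(inherits(cat, "catalog"), inherits(plan, "fold_plan"))
  if (fold_index < 1 || fold_index > plan$k) {
    stop(sprintf("fold_index must be in 1..%d", plan$k), call. = FALSE)
  }
  fold <- plan$folds[[fold_index]]
  r <- cat$records[!cat$records$is_augmented, , drop = FALSE]
  in_test <- r$location_id %in% fold$test_locations
  new_split("untrained_location",
            train_ids = r$image_id[!in_test],
            test_ids = r$image_id[in_test],
            seed = NA_integer_, fold_index = as.integer(fold_index))
}

#' Check a location-blocked split for background leakage
#'
#' @param split A `split_assignment` with `protocol = "untrained_location"`
#'   (the guard is also usable diagnostically on trained-location splits).
#' @param cat The [catalog()] the split was drawn from.
#' @return `TRUE` iff the sets of locations behind the training and test
#'   images are disjoint.
#' @export
verify_no_location_leakage <- function(split, cat) {
  stopifnot(inherits(split, "split_assignment"), inherits(cat, "catalog"))
  loc <- setNames(cat$records$location_id, cat$records$image_id)
  length(intersect(unique(loc[split$train_ids]), unique(loc[split$test_ids]))) == 0
}

#' Serialize a split assignment to CSV
#'
#' Writes one row per image with columns `image_id`, `role`
#' (train/test) and `fold_index`.
#'
#' @param split A `split_assignment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_split_csv <- function(split, path) {
  stopifnot(inherits(split, "split_assignment"))
  df <- data.frame(
    image_id = c(split$train_ids, split$test_ids),
    role = rep(c("train", "test"), c(length(split$train_ids), length(split$test_ids))),
    fold_index = split$fold_index,
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
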