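#' Class-ratio table for rebalanced sampling
#'
#' For each class c with n_c training images, the ratio r_c = n_c / n_max is
#' its count relative to the largest class. The rebalancing sampler uses
#' these ratios to upweight rare classes: the smaller r_c, the more often a
#' freshly drawn image of class c is accepted for training.
#'
#' @param counts Named vector of per-class training counts, all >= 1.
#' @return An object of class `class_ratio_table`: list with `ratios` (named
#'   numeric, max exactly 1) and `n_max`.
#' @examples
#' compute_class_ratios(c(A = 90, B = 10))
#' @export
compute_class_ratios <- function(counts) {
  if (length(counts) == 0) stop("empty class counts", call. = FALSE)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector", call. = FALSE)
  }
  nm <- names(counts)
  counts <- as.numeric(counts)
  names(counts) <- nm
  if (any(counts < 1)) stop("all class counts must be >= 1", call. = FALSE)
  n_max <- max(counts)
  structure(list(ratios = counts / n_max, n_max = n_max),
            class = "class_ratio_table")
}

#' @export
print.class_ratio_table <- function(x, ...) {
  cat(sprintf("<class ratios> %d classes, n_max = %g\n",
              length(x$ratios), x$n_max))
  print(round(x$ratios, 4))
  invisible(x)
}

#' Rebalanced training-image sampler
#'
#' Implements the stochastic rejection heuristic that feeds rare classes to
#' a classifier more often than their raw share. Per emission, up to
#' `max_redraws` rounds are run: a record is drawn uniformly from the whole
#' training set (its class c has ratio r_c), and an independent uniform
#' u ~ U(0,1) is drawn; if u > r_c the round *accepts* and a uniformly chosen
#' record of the same class c is emitted, otherwise the round redraws from
#' the entire set. Since the largest class has r = 1 it can never be
#' accepted, so the loop is capped: when all `max_redraws` rounds reject, the
#' last drawn record itself is emitted. Rare classes (small r_c) are accepted
#' almost every time they are drawn, which raises their emission frequency
#' well above their raw proportion while the cap keeps the majority class
#' represented.
#'
#' Emissions are a pure function of `(seed, emission index)`: every emission
#' runs on its own derived RNG substream, so a stream can be resumed exactly
#' at any index.
#'
#' @param cat A [catalog()] of training records.
#' @param ratios A [compute_class_ratios()] table covering all catalog
#'   classes.
#' @param max_redraws Rejection-loop cap, >= 1 (default 10).
#' @param seed Integer seed.
#' @param from Index of the first emission (for exact resumption).
#' @return A function `f(n)` returning the next `n` emitted record indices
#'   (positions in `cat$records`); its `"ids"` attribute maps them to
#'   image ids.
#' @seealso [rebalanced_sample()] for a one-shot draw.
#' @export
rebalanced_stream <- function(cat, ratios, max_redraws = 10, seed = 1, from = 1L) {
  stopifnot(inherits(cat, "catalog"), inherits(ratios, "class_ratio_table"),
            max_redraws >= 1)
  missing_cls <- setdiff(cat$classes, names(ratios$ratios))
  if (length(missing_cls) > 0) {
    stop(sprintf("ratios missing for class '%s'", missing_cls[1]), call. = FALSE)
  }
  n <- nrow(cat$records)
  if (n == 0) stop("empty catalog", call. = FALSE)
  r_by_record <- ratios$ratios[cat$records$class_label]
  by_class <- split(seq_len(n), cat$records$class_label)
  counter <- as.integer(from) - 1L

  function(n_draw) {
    out <- integer(n_draw)
    for (j in seq_len(n_draw)) {
      counter <<- counter + 1L
      out[j] <- with_seed(derive_seed(seed, "emission", counter), {
        draws <- sample.int(n, max_redraws, replace = TRUE)
        u <- runif(max_redraws)
        hit <- which(u > r_by_record[draws])
        if (length(hit) > 0) {
          cls <- cat$records$class_label[draws[hit[1]]]
          pool <- by_class[[cls]]
          pool[sample.int(length(pool), 1L)]
        } else {
          draws[max_redraws]
        }
      })
    }
    out
  }
}

#' Draw n records from the rebalanced sampler
#'
#' Convenience wrapper around [rebalanced_stream()] starting at emission 1.
#'
#' @inheritParams rebalanced_stream
#' @param n_draw Number of emissions.
#' @return Integer vector of record indices into `cat$records`.
#' @export
rebalanced_sample <- function(cat, ratios, n_draw, max_redraws = 10, seed = 1) {
  rebalanced_stream(cat, ratios, max_redraws = max_redraws, seed = seed)(n_draw)
}

#' Supplement rare classes with fixed augmented copies
#'
#' Every class with fewer than `min_count` training records gains
#' deterministic augmented copies of its own images - source records cycled
#' in catalog order - until it holds exactly `min_count`. The copies are
#' flagged `is_augmented` and are treated as fixed ground-truth training
#' images; splits never place them in a test set. Intended to run *after*
#' the train/test split, on the training records only, so no augmented
#' descendant of a test image can leak into training.
#'
#' @param cat A [catalog()] of training records.
#' @param min_count Per-class floor (default 100).
#' @param augment_config An [augmentation_config()]; default configuration
#'   when `NULL`.
#' @param seed Integer seed making the copies reproducible.
#' @param classes Classes that must reach the floor; defaults to all catalog
#'   classes. A requested class with zero records is an error.
#' @return A [catalog()] with the augmented records appended.
#' @export
supplement_to_minimum <- function(cat, min_count = 100, augment_config = NULL,
                                  seed = 1, classes = cat$classes) {
  stopifnot(inherits(cat, "catalog"), min_count >= 1)
  if (is.null(augment_config)) augment_config <- augmentation_config()
  counts <- class_counts(cat)
  zero <- setdiff(classes, names(counts)[counts > 0])
  if (length(zero) > 0) {
    stop(sprintf("class '%s' has zero training records and cannot be supplemented",
                 zero[1]), call. = FALSE)
  }

  rec <- cat$records
  new_rows <- list()
  new_imgs <- list()
  write_files <- is.null(cat$images)
  for (cls in classes) {
    deficit <- min_count - counts[[cls]]
    if (deficit <= 0) next
    src_idx <- which(rec$class_label == cls & !rec$is_augmented)
    if (length(src_idx) == 0) src_idx <- which(rec$class_label == cls)
    for (j in seq_len(deficit)) {
      src <- src_idx[((j - 1L) %% length(src_idx)) + 1L]
      copy_no <- ((j - 1L) %/% length(src_idx)) + 1L
      src_id <- rec$image_id[src]
      new_id <- sprintf("%s_aug%d", src_id, copy_no)
      img <- augment(get_image(cat, src_id), augment_config,
                     seed = derive_seed(seed, "supplement", new_id))
      row <- rec[src, , drop = FALSE]
      row$image_id <- new_id
      row$is_augmented <- TRUE
      if (write_files && !is.na(row$path)) {
        p <- sub("\\.png$", sprintf("_aug%d.png", copy_no), row$path,
                 ignore.case = TRUE)
        full <- p
        root <- attr(cat, "root")
        if (!is.null(root) && !grepl("^(/|[A-Za-z]:)", p)) full <- file.path(root, p)
        write_image_png(img, full)
        row$path <- p
      } else {
        row$path <- NA_character_
        new_imgs[[new_id]] <- img
      }
      new_rows[[new_id]] <- row
    }
  }
  if (length(new_rows) == 0) return(cat)
  rec2 <- rbind(rec, do.call(rbind, new_rows))
  imgs <- cat$images
  if (length(new_imgs) > 0) imgs <- c(imgs, new_imgs)
  out <- catalog(rec2, images = imgs)
  attr(out, "root") <- attr(cat, "root")
  out
}
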