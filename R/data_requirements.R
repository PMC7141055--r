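#' Bin per-class recall by training-set size
#'
#' Groups classes into half-open training-count bins `[low, high)` (the last
#' bin is unbounded above) and reports, per bin, the number of classes and
#' the arithmetic mean and *population* standard deviation (divisor n) of
#' one model's per-class recall. The population-SD convention is fixed by
#' recomputation against the packaged fixture, whose published 1,000+ bin SD
#' (0.0137) only reproduces with divisor n.
#'
#' @param rows A `class_recall_table` (see [load_table1_fixture()]).
#' @param model_name Which recall column to summarize.
#' @param edges Strictly increasing interior bin edges; `c(500, 1000)` gives
#'   the canonical bins `[0, 500)`, `[500, 1000)`, `[1000, Inf)`.
#' @return A `recall_bin_summary` data frame with columns `bin_low`,
#'   `bin_high`, `n_classes`, `mean_recall`, `sd_recall`.
#' @examples
#' bin_recall(load_table1_fixture(), "densenet201", c(500, 1000))
#' @export
bin_recall <- function(rows, model_name, edges = c(500, 1000)) {
  stopifnot(inherits(rows, "data.frame"))
  models <- attr(rows, "models")
  if (!model_name %in% names(rows)) {
    stop(sprintf("unknown model '%s'; available: %s", model_name,
                 paste(models, collapse = ", ")), call. = FALSE)
  }
  stopifnot(length(edges) >= 1, all(diff(edges) > 0), all(edges > 0))
  lows <- c(0, edges)
  highs <- c(edges, Inf)
  recall <- rows[[model_name]]
  out <- do.call(rbind, lapply(seq_along(lows), function(i) {
    sel <- rows$n_train >= lows[i] & rows$n_train < highs[i]
    r <- recall[sel]
    n <- length(r)
    data.frame(
      bin_low = lows[i], bin_high = highs[i], n_classes = n,
      mean_recall = if (n > 0) mean(r) else NA_real_,
      sd_recall = if (n > 1) sqrt(mean((r - mean(r))^2)) else if (n == 1) 0 else NA_real_
    )
  }))
  structure(out, model = model_name,
            class = c("recall_bin_summary", "data.frame"))
}

#' Logarithmic regression of recall on training count
#'
#' Least-squares fit of `recall = a + b * ln(n_train)`, the conventional
#' summary of how per-class recognition improves with training-set size.
#'
#' @param points Data frame with columns `n_train` (>= 1) and `recall`, or
#'   two equally long vectors via `n_train` and `recall`.
#' @param n_train,recall Alternative vector interface.
#' @return An object of class `log_fit`: list with `a` (intercept), `b`
#'   (slope), `r_squared`, `n_points` and the underlying [lm()] fit.
#' @export
fit_log_regression <- function(points = NULL, n_train = points$n_train,
                               recall = points$recall) {
  n_train <- as.numeric(n_train)
  recall <- as.numeric(recall)
  stopifnot(length(n_train) == length(recall))
  if (length(n_train) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(n_train < 1)) stop("all n_train must be >= 1", call. = FALSE)
  if (length(unique(n_train)) == 1) {
    stop("degenerate design: all n_train equal", call. = FALSE)
  }
  fit <- lm(recall ~ log(n_train))
  ss_tot <- sum((recall - mean(recall))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
         r_squared = r2, n_points = length(n_train), fit = fit),
    class = "log_fit"
  )
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("<log fit> recall = %.4f + %.4f ln(n); r^2 = %.3f (%d points)\n",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Recall-versus-training-size trend from a recall table
#'
#' Convenience analysis: bins classes into contiguous `bin_width`-wide
#' training-count bins, drops empty bins, takes each bin's mean recall
#' against the mean training count of its classes, and fits
#' [fit_log_regression()] through the bin means. This is the smoothed
#' learning-curve view used to judge how many images per class a deployment
#' needs.
#'
#' @param rows A `class_recall_table`.
#' @param model_name Recall column to analyze.
#' @param bin_width Bin width in training images (default 500).
#' @return A `log_fit` with an extra `bins` element (the per-bin means).
#' @export
recall_curve_fit <- function(rows, model_name, bin_width = 500) {
  stopifnot(bin_width >= 1)
  idx <- floor(rows$n_train / bin_width)
  recall <- rows[[model_name]]
  if (is.null(recall)) {
    stop(sprintf("unknown model '%s'", model_name), call. = FALSE)
  }
  bins <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    data.frame(bin_low = b * bin_width, n_classes = sum(sel),
               mean_n_train = mean(rows$n_train[sel]),
               mean_recall = mean(recall[sel]))
  }))
  out <- fit_log_regression(n_train = bins$mean_n_train, recall = bins$mean_recall)
  out$bins <- bins
  out
}

#' Minimum training-count guideline for a target recall
#'
#' @param summaries A [bin_recall()] summary.
#' @param target_recall Desired mean recall.
#' @return The smallest `bin_low` whose bin mean recall meets the target, or
#'   `NA` if no bin does.
#' @examples
#' threshold_guideline(bin_recall(load_table1_fixture(), "densenet201"), 0.95)
#' @export
threshold_guideline <- function(summaries, target_recall) {
  stopifnot(inherits(summaries, "data.frame"), nrow(summaries) > 0)
  ok <- !is.na(summaries$mean_recall) & summaries$mean_recall >= target_recall
  if (!any(ok)) return(NA_real_)
  min(summaries$bin_low[ok])
}
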