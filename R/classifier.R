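#' Pixel features for the reference classifier
#'
#' Concatenates a `size x size` grayscale thumbnail (spatial layout: where
#' things are, including the background structure that identifies a camera
#' location) with per-channel color histograms (`color_bins` bins per
#' channel, position-invariant: what colors are present, which is how a
#' linear model recognizes an animal regardless of where it stands in the
#' frame). Both parts live in `[0, 1]`-scale units; the histogram block is
#' upweighted by a factor 4 so the few histogram dimensions are not drowned
#' out by the many thumbnail pixels. Deliberately simple: the reference
#' backend must train in seconds while remaining sensitive to both animal
#' appearance and background, which is exactly what the domain-shift
#' experiments need. `color_bins = 0` gives a pure grayscale-thumbnail
#' feature.
#'
#' @param img Height x width x 3 array in `[0, 255]`.
#' @param size Thumbnail side length (default 12).
#' @param color_bins Histogram bins per color channel (default 12).
#' @return Numeric vector of length `size^2 + 3 * color_bins`.
#' @export
image_features <- function(img, size = 12, color_bins = 12) {
  assert_rgb(img)
  g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  small <- EBImage::imageData(EBImage::resize(EBImage::Image(g / 255), size, size))
  if (color_bins == 0) return(as.numeric(small))
  npx <- dim(img)[1] * dim(img)[2]
  hs <- unlist(lapply(1:3, function(ch) {
    tabulate(pmin(color_bins, floor(img[, , ch] / 256 * color_bins) + 1L),
             color_bins) / npx
  }), use.names = FALSE)
  c(as.numeric(small), 4 * hs)
}

n_image_features <- function(size, color_bins) size^2 + 3L * color_bins

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit the reference multinomial logistic classifier
#'
#' A desk-scale classification backend: multinomial logistic regression on
#' thumbnail-plus-color-histogram features ([image_features()]), trained by
#' minibatch Adam. Each
#' minibatch is drawn through the rebalancing sampler (when supplied) so
#' rare classes are seen more often than their raw share, and each drawn
#' image is passed through the stochastic augmenter (when supplied) before
#' feature extraction - the same data diet a heavyweight convolutional
#' backend would receive through this pipeline. Without sampler and
#' augmenter, features are cached and minibatches are drawn uniformly.
#'
#' Training is deterministic per seed: refitting with identical data and
#' seed reproduces the parameters exactly.
#'
#' @param cat A [catalog()] of training records (>= 2 classes).
#' @param ratios Optional [compute_class_ratios()] table activating
#'   rebalanced sampling.
#' @param augment_cfg Optional [augmentation_config()] applied to every
#'   sampled training image.
#' @param steps Number of Adam steps (default 300).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size.
#' @param l2 L2 penalty on the weights.
#' @param feature_size Thumbnail side length for [image_features()].
#' @param color_bins Color-histogram bins per channel for
#'   [image_features()].
#' @param max_redraws Rejection cap of the rebalancing sampler.
#' @param seed Integer seed governing sampling, augmentation and
#'   initialization.
#' @param name Backend name used in reports.
#' @return An object of class `softmax_classifier` with components `W`
#'   (feature x class weight matrix incl. intercept row), `class_labels`,
#'   `feature_size`, `loss_trace`, and the call settings. Supports
#'   [predict()], [coef()] and [print()].
#' @examples
#' cfg <- synthetic_world_config(n_locations = 2, n_species = 2,
#'                               abundance = c(12, 12), no_animal_fraction = 0,
#'                               noise_level = 2, seed = 7)
#' w <- generate_world(cfg)
#' fit <- softmax_classifier(w, steps = 60, seed = 7)
#' mean(predict(fit, w) == w$records$class_label)
#' @export
softmax_classifier <- function(cat, ratios = NULL, augment_cfg = NULL,
                               steps = 300, batch_size = 32,
                               learning_rate = 0.05, l2 = 1e-4,
                               feature_size = 12, color_bins = 12,
                               max_redraws = 10,
                               seed = 1, name = "softmax_ref") {
  stopifnot(inherits(cat, "catalog"))
  labels <- cat$records$class_label
  class_labels <- cat$classes
  if (length(class_labels) < 2) {
    stop("training requires at least 2 classes", call. = FALSE)
  }
  n <- nrow(cat$records)
  k <- length(class_labels)
  y <- match(labels, class_labels)
  d <- n_image_features(feature_size, color_bins)

  # feature cache of the raw (unaugmented) images
  X0 <- matrix(0, n, d)
  for (i in seq_len(n)) {
    X0[i, ] <- image_features(get_image(cat, cat$records$image_id[i]),
                              feature_size, color_bins)
  }

  draw_batch <- if (is.null(ratios)) {
    counter <- 0L
    function(m) {
      counter <<- counter + 1L
      with_seed(derive_seed(seed, "uniform_batch", counter),
                sample.int(n, m, replace = TRUE))
    }
  } else {
    stream <- rebalanced_stream(cat, ratios, max_redraws = max_redraws,
                                seed = derive_seed(seed, "sampler"))
    function(m) stream(m)
  }

  W <- with_seed(derive_seed(seed, "init"), {
    matrix(stats::rnorm((d + 1) * k, 0, 0.01), d + 1, k)
  })
  mW <- vW <- matrix(0, d + 1, k)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(steps)

  for (t in seq_len(steps)) {
    idx <- draw_batch(batch_size)
    if (is.null(augment_cfg)) {
      Xb <- X0[idx, , drop = FALSE]
    } else {
      Xb <- matrix(0, length(idx), d)
      for (j in seq_along(idx)) {
        img <- get_image(cat, cat$records$image_id[idx[j]])
        img <- augment(img, augment_cfg,
                       seed = derive_seed(seed, "train_aug", t, j))
        Xb[j, ] <- image_features(img, feature_size, color_bins)
      }
    }
    Xb <- cbind(1, Xb)
    P <- softmax(Xb %*% W)
    Y <- matrix(0, length(idx), k)
    Y[cbind(seq_along(idx), y[idx])] <- 1
    loss_trace[t] <- -mean(log(pmax(P[Y == 1], 1e-12))) + l2 * sum(W[-1, ]^2) / 2
    G <- crossprod(Xb, P - Y) / length(idx)
    G[-1, ] <- G[-1, ] + l2 * W[-1, ]
    mW <- b1 * mW + (1 - b1) * G
    vW <- b2 * vW + (1 - b2) * G^2
    W <- W - learning_rate * (mW / (1 - b1^t)) / (sqrt(vW / (1 - b2^t)) + eps)
  }

  structure(
    list(W = W, class_labels = class_labels, feature_size = feature_size,
         color_bins = color_bins, steps = steps, batch_size = batch_size, learning_rate = learning_rate,
         l2 = l2, seed = seed, name = name, loss_trace = loss_trace,
         rebalanced = !is.null(ratios), augmented = !is.null(augment_cfg)),
    class = "softmax_classifier"
  )
}

#' @export
print.softmax_classifier <- function(x, ...) {
  cat(sprintf(
    "<softmax classifier '%s'> %d classes, %d features, %d steps (final loss %.4f)\n",
    x$name, length(x$class_labels), nrow(x$W) - 1, x$steps,
    x$loss_trace[length(x$loss_trace)]
  ))
  invisible(x)
}

#' @export
coef.softmax_classifier <- function(object, ...) object$W

collect_features <- function(object, newdata) {
  d <- n_image_features(object$feature_size, object$color_bins)
  if (inherits(newdata, "catalog")) {
    ids <- newdata$records$image_id
    X <- t(vapply(ids, function(id) {
      image_features(get_image(newdata, id), object$feature_size, object$color_bins)
    }, numeric(d)))
  } else if (is.list(newdata)) {
    X <- t(vapply(newdata, image_features, numeric(d),
                  size = object$feature_size, color_bins = object$color_bins))
  } else if (is.array(newdata) && length(dim(newdata)) == 3) {
    X <- matrix(image_features(newdata, object$feature_size, object$color_bins),
                nrow = 1)
  } else {
    stop("newdata must be a catalog, a list of images, or one RGB array",
         call. = FALSE)
  }
  X
}

#' Predict from the reference classifier
#'
#' @param object A fitted [softmax_classifier()].
#' @param newdata A [catalog()], a list of RGB arrays, or a single array.
#' @param type `"class"` for top-1 labels, `"prob"` for the full probability
#'   matrix (columns in `object$class_labels` order).
#' @param ... Unused.
#' @return Character vector of labels, or an N x K probability matrix whose
#'   rows sum to 1.
#' @export
predict.softmax_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$W)) stop("classifier is not fitted", call. = FALSE)
  P <- softmax(cbind(1, collect_features(object, newdata)) %*% object$W)
  colnames(P) <- object$class_labels
  if (type == "prob") return(P)
  predict_top1_from_proba(P, object$class_labels)
}

predict_top1_from_proba <- function(P, labels) {
  # ties resolved toward the lowest class index (which.max convention)
  labels[apply(P, 1, which.max)]
}

#' Top-1 labels from a fitted backend
#'
#' @param object A fitted backend supporting probability predictions.
#' @param newdata Images (see [predict.softmax_classifier()]).
#' @return Character vector of predicted labels, order-preserving. Exact
#'   probability ties resolve to the earliest class in label order.
#' @export
predict_top1 <- function(object, newdata) {
  predict(object, newdata, type = "class")
}

#' Serialize / restore a fitted reference classifier
#'
#' The parameter matrix and metadata are stored as JSON, so fitted desk-scale
#' backends can be exchanged as plain text.
#'
#' @param object A fitted [softmax_classifier()].
#' @param path JSON file path.
#' @return `save_classifier()`: `path` invisibly; `load_classifier()`: the
#'   restored `softmax_classifier`.
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "softmax_classifier"))
  payload <- unclass(object)
  payload$W <- list(dim = dim(object$W), values = as.numeric(object$W))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @param path JSON file path.
#' @export
load_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$W <- matrix(payload$W$values, payload$W$dim[1], payload$W$dim[2])
  payload$class_labels <- as.character(payload$class_labels)
  structure(payload, class = "softmax_classifier")
}

#' Ensemble voting across classification backends
#'
#' Each model casts its top-1 label as one vote per image; the plurality
#' label wins. Ties on the vote count are broken by the highest mean
#' predicted probability among the tied labels across models (and, should
#' that also tie, by earliest label order); the `tie_broken` flag records
#' whether the maximal vote count was shared.
#'
#' @param per_model_probas Named list (>= 2 models) of N x K probability
#'   matrices sharing the same column (label) order.
#' @param class_labels Label order; defaults to the first matrix's column
#'   names.
#' @return An object of class `ensemble_result`: list with `winner`
#'   (character, length N), `tie_broken` (logical, length N), `vote_counts`
#'   (N x K matrix) and `per_model_top1` (N x M character matrix).
#' @export
ensemble_vote <- function(per_model_probas, class_labels = NULL) {
  stopifnot(is.list(per_model_probas), length(per_model_probas) >= 2)
  per_model_probas <- lapply(per_model_probas, function(P) {
    if (is.null(dim(P))) matrix(P, nrow = 1, dimnames = list(NULL, names(P))) else P
  })
  if (is.null(class_labels)) class_labels <- colnames(per_model_probas[[1]])
  if (is.null(class_labels)) stop("class labels are required", call. = FALSE)
  k <- length(class_labels)
  for (P in per_model_probas) {
    cn <- colnames(P)
    if (ncol(P) != k || (!is.null(cn) && !identical(cn, class_labels))) {
      stop("all models must share one class-label order", call. = FALSE)
    }
  }
  n <- nrow(per_model_probas[[1]])
  m <- length(per_model_probas)
  top1 <- vapply(per_model_probas, function(P) {
    class_labels[apply(P, 1, which.max)]
  }, character(n))
  top1 <- matrix(top1, nrow = n,
                 dimnames = list(NULL, names(per_model_probas)))
  mean_proba <- Reduce(`+`, per_model_probas) / m

  votes <- matrix(0L, n, k, dimnames = list(NULL, class_labels))
  for (j in seq_len(m)) {
    hit <- cbind(seq_len(n), match(top1[, j], class_labels))
    votes[hit] <- votes[hit] + 1L
  }
  winner <- character(n)
  tie_broken <- logical(n)
  for (i in seq_len(n)) {
    v <- votes[i, ]
    top <- which(v == max(v))
    tie_broken[i] <- length(top) > 1
    winner[i] <- if (length(top) == 1) {
      class_labels[top]
    } else {
      class_labels[top[which.max(mean_proba[i, top])]]
    }
  }
  structure(
    list(winner = winner, tie_broken = tie_broken, vote_counts = votes,
         per_model_top1 = top1),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble vote> %d images, %d models; %d tie(s) broken\n",
              length(x$winner), ncol(x$per_model_top1), sum(x$tie_broken)))
  invisible(x)
}
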