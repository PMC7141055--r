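# Independent oracles, written against the documented behaviour only -
# none of these call the implementation paths they check.

# Analytic enumeration of the rebalancing sampler's emission distribution.
# Per round: draw a record uniformly (class c, ratio r_c), draw u ~ U(0,1);
# accept with probability (1 - r_c) and emit a uniform record of class c.
# After M rejected rounds the last drawn record is emitted, whose class
# distribution conditional on rejection is proportional to n_c * r_c.
oracle_emission_probs <- function(counts, max_redraws) {
  n <- sum(counts)
  r <- counts / max(counts)
  p_accept_c <- (counts / n) * (1 - r)   # per-round accept-and-emit-class-c
  p_acc <- sum(p_accept_c)
  p_reject_c <- (counts / n) * r         # per-round reject while holding class c
  M <- max_redraws
  accept_mass <- if (p_acc == 0) rep(0, length(counts)) else {
    p_accept_c * sum((1 - p_acc)^(0:(M - 1)))
  }
  cap_mass <- (1 - p_acc)^(M - 1) * p_reject_c
  probs <- accept_mass + cap_mass
  names(probs) <- names(counts)
  probs
}

# Brute-force precision/recall/F1 by direct counting over label pairs.
oracle_prf <- function(truth, pred, label) {
  tp <- sum(truth == label & pred == label)
  fp <- sum(truth != label & pred == label)
  fn <- sum(truth == label & pred != label)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

# Normal-equations least squares for recall = a + b ln(n).
oracle_log_fit <- function(n_train, recall) {
  X <- cbind(1, log(n_train))
  beta <- solve(t(X) %*% X, t(X) %*% recall)
  resid <- recall - X %*% beta
  ss_tot <- sum((recall - mean(recall))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(resid^2) / ss_tot
  list(a = beta[1], b = beta[2], r_squared = r2)
}

# Index-arithmetic 90-degree counterclockwise rotation of an H x W x 3 array
# (square input): out[i, j] = in[j, n + 1 - i].
oracle_rotate90_ccw <- function(img) {
  n <- dim(img)[1]
  stopifnot(n == dim(img)[2])
  out <- img
  for (ch in 1:3) out[, , ch] <- t(img[, n:1, ch])
  out
}

# Small in-memory catalog with arbitrary labels/locations and flat images.
make_toy_catalog <- function(labels, locations = rep("L1", length(labels)),
                             with_images = FALSE, image_side = 32) {
  n <- length(labels)
  ids <- sprintf("t%03d", seq_len(n))
  rec <- data.frame(
    image_id = ids, path = NA_character_,
    class_label = labels, location_id = locations,
    stringsAsFactors = FALSE
  )
  imgs <- NULL
  if (with_images) {
    imgs <- lapply(seq_len(n), function(i) {
      array((i * 37) %% 256, c(image_side, image_side, 3))
    })
    names(imgs) <- ids
  }
  catalog(rec, images = imgs)
}
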