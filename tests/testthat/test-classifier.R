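# Two visually trivial classes: bright uniform vs dark uniform images.
separable_catalog <- function(n_per = 10, side = 32) {
  n <- 2 * n_per
  ids <- sprintf("s%03d", seq_len(n))
  labels <- rep(c("bright", "dark"), each = n_per)
  imgs <- lapply(seq_len(n), function(i) {
    base <- if (labels[i] == "bright") 210 else 40
    set.seed(i)
    array(pmin(pmax(base + rnorm(side * side * 3, 0, 5), 0), 255),
          c(side, side, 3))
  })
  names(imgs) <- ids
  catalog(
    data.frame(image_id = ids, path = NA_character_, class_label = labels,
               location_id = "L1", stringsAsFactors = FALSE),
    images = imgs
  )
}

test_that("a linearly separable toy reaches perfect training accuracy quickly", {
  cat_ <- separable_catalog(10)
  fit <- softmax_classifier(cat_, steps = 200, batch_size = 10,
                            learning_rate = 0.1, seed = 1)
  expect_equal(mean(predict(fit, cat_) == cat_$records$class_label), 1)
})

test_that("fits are bitwise deterministic per seed and expose the contract", {
  cfg <- synthetic_world_config(n_locations = 2, n_species = 3,
                                abundance = c(8, 6, 4), no_animal_fraction = 0,
                                seed = 3)
  w <- generate_world(cfg)
  f1 <- softmax_classifier(w, steps = 40, seed = 11)
  f2 <- softmax_classifier(w, steps = 40, seed = 11)
  expect_identical(f1$W, f2$W)

  P <- predict(f1, w, type = "prob")
  expect_equal(ncol(P), 3)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(P >= 0))
  expect_identical(colnames(P), w$classes)

  # top-1 equals the argmax, order preserved, ties to the lowest index
  labels <- c("a", "b", "c")
  fake <- structure(list(W = NULL), class = "softmax_classifier")
  expect_error(predict(fake, w), "not fitted")
  expect_equal(
    camtrapeval:::predict_top1_from_proba(
      rbind(c(0.7, 0.2, 0.1), c(0.5, 0.5, 0)), labels),
    c("a", "a")
  )

  expect_error(
    softmax_classifier(make_toy_catalog(rep("only", 4), with_images = TRUE)),
    "at least 2 classes"
  )
})

test_that("fitted classifiers survive a JSON round trip", {
  cat_ <- separable_catalog(6)
  fit <- softmax_classifier(cat_, steps = 50, batch_size = 8, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(fit, path)
  back <- load_classifier(path)
  expect_equal(back$W, fit$W)
  expect_equal(back$class_labels, fit$class_labels)
  expect_equal(predict(back, cat_), predict(fit, cat_))
})

test_that("ensemble voting follows plurality with mean-confidence tie-breaks", {
  labs <- c("A", "B", "C")
  P <- function(...) {
    m <- rbind(c(...))
    colnames(m) <- labs
    m
  }
  # unanimity
  r <- ensemble_vote(list(m1 = P(0.8, 0.1, 0.1), m2 = P(0.6, 0.3, 0.1),
                          m3 = P(0.9, 0.05, 0.05)))
  expect_equal(r$winner, "A")
  expect_false(r$tie_broken)

  # plurality 2 vs 1
  r <- ensemble_vote(list(m1 = P(0.8, 0.1, 0.1), m2 = P(0.7, 0.2, 0.1),
                          m3 = P(0.1, 0.8, 0.1)))
  expect_equal(r$winner, "A")
  expect_equal(unname(r$vote_counts[1, ]), c(2L, 1L, 0L))

  # 1-1 tie broken by higher mean probability
  r <- ensemble_vote(list(m1 = P(0.60, 0.35, 0.05), m2 = P(0.35, 0.55, 0.10)))
  expect_equal(r$winner, "A")   # mean A = 0.475 > mean B = 0.45
  expect_true(r$tie_broken)

  # inconsistent label orders are rejected
  Q <- P(0.2, 0.3, 0.5)
  colnames(Q) <- c("B", "A", "C")
  expect_error(ensemble_vote(list(m1 = P(1, 0, 0), m2 = Q)), "label order")
})

test_that("an ensemble of identical models equals the single model", {
  cat_ <- separable_catalog(8)
  fit <- softmax_classifier(cat_, steps = 60, batch_size = 8, seed = 4)
  P <- predict(fit, cat_, type = "prob")
  r <- ensemble_vote(list(a = P, b = P, c = P))
  expect_equal(r$winner, predict(fit, cat_))
  expect_false(any(r$tie_broken))
})

test_that("ensembles tend to match or beat the median single model", {
  wins <- 0L
  n_runs <- 10
  for (s in seq_len(n_runs)) {
    cfg <- synthetic_world_config(n_locations = 3, n_species = 3,
                                  abundance = c(20, 15, 10),
                                  night_fraction = 0, noise_level = 4,
                                  no_animal_fraction = 0.15, seed = 100 + s)
    w <- generate_world(cfg)
    sp <- trained_location_split(w, 0.25, seed = s)
    tr <- subset_catalog(w, sp$train_ids)
    te <- subset_catalog(w, sp$test_ids)
    truth <- te$records$class_label
    probas <- lapply(c(1, 2, 3), function(ms) {
      fit <- softmax_classifier(tr, steps = 120, batch_size = 16,
                                learning_rate = 0.1, seed = ms * 13)
      predict(fit, te, type = "prob")
    })
    accs <- vapply(probas, function(P) {
      mean(camtrapeval:::predict_top1_from_proba(P, tr$classes) == truth)
    }, numeric(1))
    names(probas) <- paste0("m", 1:3)
    ens_acc <- mean(ensemble_vote(probas)$winner == truth)
    if (ens_acc >= median(accs)) wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * n_runs)
})
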