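test_that("trained-location split obeys the permutation rule and determinism", {
  cat_ <- make_toy_catalog(rep(c("A", "B"), 5), locations = rep(c("L1", "L2"), 5))
  sp <- trained_location_split(cat_, 0.1, seed = 3)
  expect_length(sp$train_ids, 9)
  expect_length(sp$test_ids, 1)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), cat_$records$image_id)

  expect_identical(trained_location_split(cat_, 0.1, seed = 3), sp)

  big <- make_toy_catalog(rep("A", 100))
  s1 <- trained_location_split(big, 0.3, seed = 1)
  s2 <- trained_location_split(big, 0.3, seed = 2)
  expect_false(setequal(s1$test_ids, s2$test_ids))

  expect_error(trained_location_split(make_toy_catalog("A"), 0.1), "at least 2")
})

test_that("test membership is uniform across records over many seeds", {
  cat_ <- make_toy_catalog(rep("A", 20))
  n_seeds <- 2000
  hits <- setNames(numeric(20), cat_$records$image_id)
  for (s in seq_len(n_seeds)) {
    sp <- trained_location_split(cat_, 0.5, seed = s)
    hits[sp$test_ids] <- hits[sp$test_ids] + 1
  }
  freq <- hits / n_seeds
  # binomial 3-sigma band around 0.5
  sigma <- sqrt(0.5 * 0.5 / n_seeds)
  expect_true(all(abs(freq - 0.5) < 3 * sigma + 1e-9))
})

test_that("fold boundaries follow the contiguous percentile rule", {
  plan5 <- location_kfold_plan(sprintf("L%02d", 1:5), k = 5)
  expect_equal(lapply(plan5$folds, `[[`, "test_locations"),
               as.list(sprintf("L%02d", 1:5)))

  plan36 <- location_kfold_plan(sprintf("L%02d", 1:36), k = 5)
  sizes <- vapply(plan36$folds, function(f) length(f$test_locations), integer(1))
  expect_equal(sizes, c(7, 7, 8, 7, 7))
  expect_equal(plan36$folds[[1]]$test_locations, sprintf("L%02d", 1:7))
  expect_equal(plan36$folds[[3]]$test_locations, sprintf("L%02d", 15:22))

  # middle-block pattern: fold 2 of L=10, k=5 tests positions 3-4
  plan10 <- location_kfold_plan(sprintf("L%02d", 1:10), k = 5)
  expect_equal(plan10$folds[[2]]$test_locations, c("L03", "L04"))
  expect_equal(plan10$folds[[2]]$train_locations,
               sprintf("L%02d", c(1:2, 5:10)))

  expect_error(location_kfold_plan(c("a", "b"), k = 5), "at least k")

  # block sizes stay within 1 of each other across many (L, k)
  for (L in 5:20) {
    for (k in 2:min(L, 7)) {
      s <- vapply(location_kfold_plan(as.character(seq_len(L)), k)$folds,
                  function(f) length(f$test_locations), integer(1))
      expect_lte(max(s) - min(s), 1)
      expect_equal(sum(s), L)
    }
  }
})

test_that("materialized folds partition images with zero location leakage", {
  cfg <- synthetic_world_config(n_locations = 10, n_species = 4,
                                abundance = c(20, 14, 9, 6), seed = 31)
  w <- generate_world(cfg)
  plan <- location_kfold_plan(w, k = 5)
  seen <- character(0)
  for (i in 1:5) {
    sp <- materialize_fold(w, plan, i)
    expect_true(verify_no_location_leakage(sp, w))
    loc <- setNames(w$records$location_id, w$records$image_id)
    expect_true(all(loc[sp$test_ids] %in% plan$folds[[i]]$test_locations))
    expect_true(all(loc[sp$train_ids] %in% plan$folds[[i]]$train_locations))
    expect_length(intersect(seen, sp$test_ids), 0)
    seen <- c(seen, sp$test_ids)
  }
  expect_setequal(seen, w$records$image_id)
})

test_that("species confined to a test block vanish from that fold's training labels", {
  sp <- list(
    species_descriptor("Common", "ellipse", c(200, 180, 160), texture_seed = 1),
    species_descriptor("Rare", "compound", c(60, 40, 30), texture_seed = 2)
  )
  occ <- rbind(Common = rep(1L, 4),
               Rare = c(1L, 0L, 0L, 0L))  # only at the first location
  cfg <- synthetic_world_config(n_locations = 4, species = sp,
                                abundance = c(20, 6), occupancy = occ,
                                no_animal_fraction = 0, seed = 8)
  w <- generate_world(cfg)
  plan <- location_kfold_plan(w, k = 4)
  hit <- which(vapply(plan$folds, function(f) "L01" %in% f$test_locations, logical(1)))
  sp <- materialize_fold(w, plan, hit)
  train_labels <- w$records$class_label[w$records$image_id %in% sp$train_ids]
  expect_false("Rare" %in% train_labels)
  test_labels <- w$records$class_label[w$records$image_id %in% sp$test_ids]
  expect_true("Rare" %in% test_labels)
})

test_that("leakage detector flags trained-location splits and hand-built leaks", {
  cat_ <- make_toy_catalog(rep("A", 12), locations = rep(c("L1", "L2", "L3"), 4))
  sp <- trained_location_split(cat_, 0.25, seed = 2)
  expect_false(verify_no_location_leakage(sp, cat_))

  ids <- cat_$records$image_id
  leaky <- structure(
    list(protocol = "untrained_location", train_ids = ids[1:6],
         test_ids = ids[c(7, 2)], seed = 1, fold_index = 1L),
    class = "split_assignment"
  )
  expect_false(verify_no_location_leakage(leaky, cat_))
})

test_that("split invariants hold over a 100-seed sweep", {
  cat_ <- make_toy_catalog(rep(c("A", "B", "C"), 10),
                           locations = rep(sprintf("L%d", 1:5), 6))
  all_ids <- cat_$records$image_id
  for (s in 1:100) {
    sp <- trained_location_split(cat_, 0.2, seed = s)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$test_ids), all_ids)
  }
})

test_that("fold plans ignore image-level shuffles that keep location order", {
  cfg <- synthetic_world_config(n_locations = 6, n_species = 3,
                                abundance = c(8, 6, 4), seed = 13)
  w <- generate_world(cfg)
  plan1 <- location_kfold_plan(w, k = 3)
  # shuffle records within the blocks that preserve first-appearance order
  rec <- w$records
  first_idx <- match(w$locations, rec$location_id)
  rest <- setdiff(seq_len(nrow(rec)), first_idx)
  rec2 <- rbind(rec[first_idx, ], rec[rev(rest), ])
  w2 <- catalog(rec2, images = w$images[rec2$image_id])
  expect_equal(w2$locations, w$locations)
  plan2 <- location_kfold_plan(w2, k = 3)
  expect_equal(plan2$folds, plan1$folds)
})
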