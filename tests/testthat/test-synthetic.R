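cfg3 <- synthetic_world_config(n_locations = 3, n_species = 4,
                               abundance = c(10, 7, 5, 3), seed = 21)

test_that("backgrounds are deterministic, location-specific, and darker at night", {
  b1 <- render_background(cfg3, "L01", seed = 5)
  b2 <- render_background(cfg3, "L01", seed = 5)
  expect_identical(b1, b2)

  night <- render_background(cfg3, "L01", night = TRUE, seed = 5)
  expect_lt(mean_luminance(night), mean_luminance(b1))

  # structural between-location difference exceeds the within-location
  # sensor-noise level
  locs <- cfg3$locations
  between <- outer(seq_along(locs), seq_along(locs), Vectorize(function(i, j) {
    mean(abs(render_background(cfg3, locs[i], seed = 1) -
             render_background(cfg3, locs[j], seed = 1)))
  }))
  off_diag <- between[upper.tri(between)]
  expect_true(all(off_diag > cfg3$noise_level))

  expect_error(render_background(cfg3, "nowhere"), "unknown location")
})

test_that("within-location image distance is smaller than between-location", {
  sample_imgs <- function(loc, n) {
    lapply(seq_len(n), function(s) render_background(cfg3, loc, seed = s))
  }
  per_loc <- lapply(cfg3$locations, sample_imgs, n = 10)
  dist_mean <- function(a, b) mean(abs(a - b))
  within <- unlist(lapply(per_loc, function(imgs) {
    vapply(2:length(imgs), function(i) dist_mean(imgs[[1]], imgs[[i]]), numeric(1))
  }))
  between <- unlist(lapply(1:2, function(i) {
    vapply((i + 1):3, function(j) dist_mean(per_loc[[i]][[1]], per_loc[[j]][[1]]),
           numeric(1))
  }))
  expect_lt(mean(within), mean(between))
})

test_that("render_image composites sprites per occupancy, pose and crop rules", {
  occ <- cfg3$occupancy
  sp_ok <- rownames(occ)[which(occ[, "L01"] == 1)[1]]
  sp_bad_row <- which(occ[, "L01"] == 0)
  # background-only image equals the rendered background exactly
  none <- render_image(cfg3, "L01", species = NULL, seed = 3)
  expect_identical(none$image, render_background(cfg3, "L01", seed = 3))
  expect_false(any(none$mask))

  ri <- render_image(cfg3, "L01", species = sp_ok,
                     pose = list(scale = 0.6), seed = 3)
  expect_true(any(ri$mask))
  expect_equal(dim(ri$image), c(64, 64, 3))

  if (length(sp_bad_row) > 0) {
    expect_error(
      render_image(cfg3, "L01", species = rownames(occ)[sp_bad_row[1]], seed = 3),
      "occupancy violation"
    )
  }

  # fully cropped-out animal leaves an empty mask
  cropped <- render_image(cfg3, "L01", species = sp_ok,
                          pose = list(scale = 0.5, crop_fraction = 1), seed = 3)
  expect_false(any(cropped$mask))
})

test_that("mask area scales quadratically with sprite scale", {
  occ_sp <- rownames(cfg3$occupancy)[which(cfg3$occupancy[, "L02"] == 1)[1]]
  base <- render_image(cfg3, "L02", species = occ_sp,
                       pose = list(scale = 1, position = c(0.5, 0.5)), seed = 9)
  for (s in c(0.5, 0.75)) {
    scaled <- render_image(cfg3, "L02", species = occ_sp,
                           pose = list(scale = s, position = c(0.5, 0.5)), seed = 9)
    expect_equal(sum(scaled$mask), s^2 * sum(base$mask),
                 tolerance = 0.1)
  }
})

test_that("generated worlds honor abundance, occupancy and determinism", {
  w <- generate_world(cfg3)
  cc <- class_counts(w)
  expect_equal(unname(cc[cfg3$species_names]), cfg3$abundance)
  expect_equal(sum(cc), nrow(w$records))

  # occupancy: no (species, location) pair outside the matrix support
  r <- w$records[w$records$class_label != "No Animal", ]
  for (i in seq_len(nrow(r))) {
    expect_equal(cfg3$occupancy[r$class_label[i], r$location_id[i]], 1L,
                 ignore_attr = TRUE)
  }

  # full-run determinism, including files on disk
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_world(cfg3, output_dir = d1)
  generate_world(cfg3, output_dir = d2)
  m1 <- readLines(file.path(d1, "manifest.csv"))
  m2 <- readLines(file.path(d2, "manifest.csv"))
  expect_identical(m1, m2)
  f1 <- list.files(file.path(d1, "images"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "images"), full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  pick <- round(seq(1, length(f1), length.out = 5))
  for (i in pick) {
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  }
})

test_that("infeasible occupancy is rejected before generation", {
  occ <- matrix(1L, 2, 2)
  occ[2, ] <- 0L
  expect_error(
    synthetic_world_config(n_locations = 2, n_species = 2,
                           abundance = c(5, 5), occupancy = occ, seed = 1),
    "occupies no location"
  )
})

test_that("burst mode emits 5-image sequences at a shared location", {
  cfg <- synthetic_world_config(n_locations = 3, n_species = 2,
                                abundance = c(11, 7), sequence_mode = TRUE,
                                no_animal_fraction = 0, seed = 4)
  w <- generate_world(cfg)
  expect_true(all(!is.na(w$records$sequence_id)))
  per_seq <- split(w$records, w$records$sequence_id)
  sizes <- vapply(per_seq, nrow, integer(1))
  expect_true(all(sizes <= 5))
  expect_true(any(sizes == 5))
  for (s in per_seq) {
    expect_length(unique(s$location_id), 1)
    expect_length(unique(s$class_label), 1)
  }
})
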