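#' Generate a synthetic camera-trap world
#'
#' Produces a full labeled image collection from a
#' [synthetic_world_config()]: exactly the configured number of images per
#' species (plus a "No Animal" share), placed only at locations the species
#' occupies, with jittered pose/scale/illumination, optional occlusion and
#' crop-out, day/night conditions, and optional 5-image bursts. The whole
#' run, including any files written, is a pure function of the config (which
#' houses the seed): rerunning gives byte-identical manifests and images.
#'
#' @param config A [synthetic_world_config()].
#' @param output_dir Directory to write `manifest.csv` and `images/*.png`
#'   into, or `NULL` (default) to keep all pixel data in memory on the
#'   returned catalog - the cheap mode used throughout the test-scale
#'   experiments.
#' @return A [catalog()]; when `output_dir` is `NULL` its `images` element
#'   holds the pixel arrays, otherwise `attr(, "root")` points at
#'   `output_dir` and paths are relative to it.
#' @examples
#' cfg <- synthetic_world_config(n_locations = 3, n_species = 3,
#'                               abundance = c(8, 5, 3), seed = 42)
#' w <- generate_world(cfg)
#' class_counts(w)
#' @export
generate_world <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "synthetic_world_config"))
  n_sp <- length(config$species)
  n_animal <- sum(config$abundance)
  n_none <- as.integer(round(
    config$no_animal_fraction / (1 - config$no_animal_fraction) * n_animal
  ))

  labels <- c(rep(config$species_names, times = config$abundance),
              rep(config$no_animal_label, n_none))
  n_total <- length(labels)
  if (n_total == 0) stop("configured world has zero images", call. = FALSE)

  plan <- with_seed(derive_seed(config$seed, "plan"), {
    burst <- config$sequence_mode
    loc <- character(n_total)
    seq_id <- rep(NA_character_, n_total)
    pos <- 1L
    seq_counter <- 0L
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      allowed <- if (lab == config$no_animal_label) {
        config$locations
      } else {
        config$locations[config$occupancy[lab, ] == 1]
      }
      if (burst) {
        # bursts of 5 frames share one location draw and one sequence id
        n_bursts <- ceiling(length(idx) / 5)
        bl <- allowed[sample.int(length(allowed), n_bursts, replace = TRUE)]
        for (b in seq_len(n_bursts)) {
          seq_counter <- seq_counter + 1L
          members <- idx[((b - 1L) * 5L + 1L):min(b * 5L, length(idx))]
          loc[members] <- bl[b]
          seq_id[members] <- sprintf("seq_%05d", seq_counter)
        }
      } else {
        loc[idx] <- allowed[sample.int(length(allowed), length(idx), replace = TRUE)]
      }
    }
    night <- runif(n_total) < config$night_fraction
    list(loc = loc, seq_id = seq_id, night = night)
  })

  ids <- sprintf("img_%06d", seq_len(n_total))
  write_files <- !is.null(output_dir)
  if (write_files) {
    dir.create(file.path(output_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  }
  images <- if (write_files) NULL else vector("list", n_total)

  for (i in seq_len(n_total)) {
    sp <- if (labels[i] == config$no_animal_label) NULL else labels[i]
    img_seed <- derive_seed(config$seed, "image", i)
    pose <- with_seed(derive_seed(img_seed, "posepars"), {
      list(
        scale = runif(1, config$scale_range[1], config$scale_range[2]),
        position = c(runif(1, 0.35, 0.75), runif(1, 0.2, 0.8)),
        occlusion_fraction = if (runif(1) < config$occlusion_prob) runif(1, 0.1, 0.35) else 0,
        crop_fraction = if (runif(1) < config$crop_prob) runif(1, 0.2, 0.6) else 0
      )
    })
    rendered <- render_image(config, plan$loc[i], species = sp, pose = pose,
                             night = plan$night[i], seed = img_seed)
    if (write_files) {
      write_image_png(rendered$image,
                      file.path(output_dir, "images", paste0(ids[i], ".png")))
    } else {
      images[[i]] <- rendered$image
    }
  }

  rec <- data.frame(
    image_id = ids,
    path = if (write_files) file.path("images", paste0(ids, ".png")) else NA_character_,
    class_label = labels,
    location_id = plan$loc,
    sequence_id = plan$seq_id,
    captured_at = NA_character_,
    is_augmented = FALSE,
    stringsAsFactors = FALSE
  )
  if (!write_files) names(images) <- ids
  out <- catalog(rec, images = images)
  if (write_files) {
    attr(out, "root") <- output_dir
    save_manifest(out, file.path(output_dir, "manifest.csv"))
  }
  out
}

#' Restrict a catalog to a subset of records
#'
#' @param cat A [catalog()].
#' @param image_ids Identifiers to keep; order follows the original catalog.
#' @return A [catalog()] containing only the selected records (classes and
#'   locations recomputed in first-appearance order).
#' @export
subset_catalog <- function(cat, image_ids) {
  stopifnot(inherits(cat, "catalog"))
  keep <- cat$records$image_id %in% image_ids
  rec <- cat$records[keep, , drop = FALSE]
  imgs <- if (!is.null(cat$images)) cat$images[rec$image_id] else NULL
  out <- catalog(rec, images = imgs)
  attr(out, "root") <- attr(cat, "root")
  out
}
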