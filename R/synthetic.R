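#' Species descriptors for the synthetic world
#'
#' A species in the synthetic world is a colored, textured sprite: an
#' ellipse, a polygon, or a compound body-head-legs silhouette. Distinct
#' species should differ in at least one of shape, color, or texture seed so
#' that a classifier has signal to separate them.
#'
#' @param name Species label.
#' @param base_shape One of `"ellipse"`, `"polygon"`, `"compound"`.
#' @param base_color RGB triple in `0..255`.
#' @param texture_seed Integer seed for the species' fixed texture pattern.
#' @param n_sides Polygon side count (polygon shape only).
#' @return An object of class `species_descriptor`.
#' @export
species_descriptor <- function(name, base_shape = c("ellipse", "polygon", "compound"),
                               base_color = c(120, 90, 60), texture_seed = 1,
                               n_sides = 5) {
  base_shape <- match.arg(base_shape)
  stopifnot(length(base_color) == 3, all(base_color >= 0 & base_color <= 255))
  structure(
    list(name = name, base_shape = base_shape, base_color = as.numeric(base_color),
         texture_seed = as.integer(texture_seed), n_sides = as.integer(n_sides)),
    class = "species_descriptor"
  )
}

default_species_set <- function(n_species, seed) {
  shapes <- c("ellipse", "polygon", "compound")
  # fixed, well-separated palette; recycled hues get a different shape/texture
  palette <- list(
    c(235, 225, 210), c(40, 35, 30), c(180, 60, 50), c(70, 130, 70),
    c(200, 160, 40), c(90, 70, 160), c(230, 120, 30), c(120, 120, 120),
    c(60, 150, 160), c(170, 40, 120)
  )
  lapply(seq_len(n_species), function(i) {
    species_descriptor(
      name = sprintf("Species%02d", i),
      base_shape = shapes[((i - 1L) %% 3L) + 1L],
      base_color = palette[[((i - 1L) %% length(palette)) + 1L]],
      texture_seed = derive_seed(seed, "texture", i),
      n_sides = 3L + (i %% 4L)
    )
  })
}

#' Configuration of a synthetic camera-trap world
#'
#' Describes a small artificial study area: a set of camera locations with
#' location-specific static procedural backgrounds, a species pool with a
#' long-tailed abundance profile, a species-by-location occupancy structure
#' (not every species occurs everywhere), a background-only "No Animal"
#' class, day/night conditions, and optional 5-image motion-trigger bursts.
#' The generated imagery has the statistical structure the evaluation
#' protocols probe - notably backgrounds that identify locations, which is
#' what makes location-blocked testing harder than random splitting.
#'
#' @param n_locations Number of camera locations.
#' @param species List of [species_descriptor()] objects, or `NULL` to
#'   generate `n_species` default descriptors.
#' @param n_species Number of species when `species` is `NULL`.
#' @param abundance Integer vector of per-species image counts. Default: a
#'   long-tailed geometric decay `round(abundance_max * decay^(i-1))`
#'   (minimum 2), mimicking the heavy class imbalance of real camera-trap
#'   inventories at reduced scale.
#' @param abundance_max Largest per-species count for the default profile.
#' @param decay Geometric decay ratio of the default abundance profile.
#' @param occupancy Binary species x locations matrix (1 = species occurs
#'   there), or `NULL` for the default in which each species occupies a
#'   seeded random 60% of locations (at least one).
#' @param occupancy_fraction Fraction of locations each species occupies
#'   under the default occupancy.
#' @param no_animal_fraction Fraction of the final catalog that is
#'   background-only "No Animal" imagery. Default 0.19, the share observed in
#'   a typical motion-triggered deployment.
#' @param night_fraction Fraction of images taken at night (darkened).
#' @param sequence_mode Emit motion-trigger bursts of 5 images sharing a
#'   sequence id, location, species and conditions?
#' @param image_size `c(height, width)` in pixels; 64 x 64 by default.
#' @param noise_level Per-image Gaussian sensor noise SD in intensity levels.
#' @param scale_range Range of the sprite scale (fraction of the shorter
#'   image side) drawn per image; the low end controls how small and hard
#'   the hardest animals are.
#' @param occlusion_prob Probability that an image has its animal partly
#'   hidden behind foreground (messy case).
#' @param crop_prob Probability that an image has its animal partly cropped
#'   out of frame (messy case).
#' @param shared_background Use the same background at every location
#'   (ablation switch that removes the location-identifying signal)?
#' @param seed Integer seed; the whole world is a pure function of
#'   (config, seed).
#' @return An object of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(n_locations = 6,
                                   species = NULL,
                                   n_species = 8,
                                   abundance = NULL,
                                   abundance_max = 60,
                                   decay = 0.85,
                                   occupancy = NULL,
                                   occupancy_fraction = 0.6,
                                   no_animal_fraction = 0.19,
                                   night_fraction = 0.25,
                                   sequence_mode = FALSE,
                                   image_size = c(64, 64),
                                   noise_level = 8,
                                   scale_range = c(0.3, 0.8),
                                   occlusion_prob = 0.10,
                                   crop_prob = 0.05,
                                   shared_background = FALSE,
                                   seed = 1) {
  stopifnot(n_locations >= 1,
            no_animal_fraction >= 0, no_animal_fraction < 1,
            night_fraction >= 0, night_fraction < 1,
            length(image_size) == 2, all(image_size >= 16),
            noise_level >= 0, length(scale_range) == 2,
            scale_range[1] > 0, scale_range[2] <= 1,
            occlusion_prob >= 0, occlusion_prob <= 1,
            crop_prob >= 0, crop_prob <= 1)
  if (is.null(species)) species <- default_species_set(n_species, seed)
  stopifnot(length(species) >= 1)
  n_species <- length(species)
  sp_names <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(sp_names)) stop("duplicate species names", call. = FALSE)

  if (is.null(abundance)) {
    abundance <- pmax(2L, as.integer(round(abundance_max * decay^(seq_len(n_species) - 1))))
  }
  stopifnot(length(abundance) == n_species, all(abundance >= 0))

  locations <- sprintf("L%02d", seq_len(n_locations))
  if (is.null(occupancy)) {
    n_occ <- max(1L, as.integer(round(occupancy_fraction * n_locations)))
    occupancy <- matrix(0L, n_species, n_locations,
                        dimnames = list(sp_names, locations))
    with_seed(derive_seed(seed, "occupancy"), {
      for (i in seq_len(n_species)) {
        occupancy[i, sample(n_locations, n_occ)] <- 1L
      }
    })
  } else {
    occupancy <- as.matrix(occupancy)
    if (is.null(rownames(occupancy))) rownames(occupancy) <- sp_names
    if (is.null(colnames(occupancy))) colnames(occupancy) <- locations
    stopifnot(nrow(occupancy) == n_species, ncol(occupancy) == n_locations)
  }
  bad <- rowSums(occupancy) == 0 & abundance > 0
  if (any(bad)) {
    stop(sprintf("species '%s' has positive abundance but occupies no location",
                 sp_names[which(bad)[1]]), call. = FALSE)
  }

  structure(
    list(
      n_locations = n_locations, locations = locations,
      species = species, species_names = sp_names,
      abundance = as.integer(abundance),
      occupancy = occupancy,
      no_animal_fraction = no_animal_fraction,
      no_animal_label = "No Animal",
      night_fraction = night_fraction,
      sequence_mode = isTRUE(sequence_mode),
      image_size = as.integer(image_size),
      noise_level = noise_level,
      scale_range = as.numeric(scale_range),
      occlusion_prob = occlusion_prob,
      crop_prob = crop_prob,
      shared_background = isTRUE(shared_background),
      seed = as.integer(seed)
    ),
    class = "synthetic_world_config"
  )
}

#' @export
print.synthetic_world_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic world> %d locations, %d species (+ '%s'), %dx%d px, seed %d\n",
    x$n_locations, length(x$species), x$no_animal_label,
    x$image_size[1], x$image_size[2], x$seed
  ))
  cat("  abundance:", paste(x$abundance, collapse = " "), "\n")
  invisible(x)
}

# Noiseless daytime background structure for one location: a vertical
# sky-to-ground gradient plus a handful of fixed-position "rocks/logs".
# Pure function of (config, location_id); every image at a location shares it.
background_structure <- function(config, location_id) {
  if (!location_id %in% config$locations) {
    stop(sprintf("unknown location '%s'", location_id), call. = FALSE)
  }
  bg_key <- if (config$shared_background) "SHARED" else location_id
  h <- config$image_size[1]; w <- config$image_size[2]
  with_seed(derive_seed(config$seed, "background", bg_key), {
    sky <- runif(3, 120, 230)
    ground <- runif(3, 40, 150)
    horizon <- runif(1, 0.35, 0.65)
    t <- pmin(pmax((seq_len(h) / h - horizon) / 0.25 + 0.5, 0), 1)
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      img[, , ch] <- matrix((1 - t) * sky[ch] + t * ground[ch], h, w)
    }
    n_obj <- sample(3:6, 1)
    for (o in seq_len(n_obj)) {
      cy <- runif(1, horizon, 1) * h
      cx <- runif(1, 0, 1) * w
      ry <- runif(1, 0.03, 0.10) * h
      rx <- runif(1, 0.05, 0.22) * w
      col <- runif(3, 20, 110)
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      inside <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inside] <- col[ch]
        img[, , ch] <- plane
      }
    }
    img
  })
}

night_factor <- 0.35

apply_night <- function(img, night) {
  if (!night) return(img)
  # darken and shift toward a cold monochrome cast
  g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  out <- img
  for (ch in 1:3) out[, , ch] <- night_factor * (0.7 * g + 0.3 * img[, , ch])
  out
}

add_sensor_noise <- function(img, noise_level, seed) {
  if (noise_level <= 0) return(round(clip255(img)))
  with_seed(seed, {
    round(clip255(img + array(stats::rnorm(length(img), 0, noise_level), dim(img))))
  })
}

#' Render the background of one synthetic location
#'
#' Deterministic in all arguments: two calls with identical
#' `(location_id, conditions, seed)` give bit-identical arrays. Different
#' locations get structurally different backgrounds (unless the world is
#' configured with `shared_background = TRUE`); per-image sensor noise is the
#' only within-location variation.
#'
#' @param config A [synthetic_world_config()].
#' @param location_id Location token from `config$locations`.
#' @param night Darken for night conditions?
#' @param noise_level Sensor noise SD; defaults to the config value.
#' @param seed Integer seed for the per-image noise.
#' @return Height x width x 3 array in `0..255`.
#' @export
render_background <- function(config, location_id, night = FALSE,
                              noise_level = config$noise_level, seed = 1) {
  img <- apply_night(background_structure(config, location_id), night)
  add_sensor_noise(img, noise_level, derive_seed(seed, "noise", location_id, night))
}

# Rasterize a species sprite into a size_px bounding box.
# Returns list(color = array, mask = logical matrix).
render_sprite <- function(sp, size_px, jitter_seed = 1) {
  size_px <- max(3L, as.integer(size_px))
  yy <- matrix(seq_len(size_px), size_px, size_px)
  xx <- matrix(seq_len(size_px), size_px, size_px, byrow = TRUE)
  c0 <- (size_px + 1) / 2
  u <- (xx - c0) / (size_px / 2)
  v <- (yy - c0) / (size_px / 2)
  mask <- switch(sp$base_shape,
    ellipse = (u / 0.95)^2 + (v / 0.62)^2 <= 1,
    polygon = {
      k <- max(3L, sp$n_sides)
      ang <- atan2(v, u)
      r <- sqrt(u^2 + v^2)
      # regular k-gon inradius formula in polar coordinates
      rmax <- 0.92 * cos(pi / k) / cos(((ang %% (2 * pi / k)) - pi / k))
      r <= rmax
    },
    compound = {
      body <- (u / 0.72)^2 + ((v - 0.05) / 0.42)^2 <= 1
      head <- ((u - 0.62) / 0.28)^2 + ((v + 0.38) / 0.28)^2 <= 1
      leg1 <- abs(u + 0.42) <= 0.09 & v > 0.2 & v < 0.95
      leg2 <- abs(u - 0.30) <= 0.09 & v > 0.2 & v < 0.95
      body | head | leg1 | leg2
    }
  )
  col <- array(0, c(size_px, size_px, 3))
  # fixed per-species texture plus mild per-image jitter
  tex <- with_seed(sp$texture_seed, {
    matrix(stats::rnorm(size_px^2, 0, 18), size_px, size_px)
  })
  jit <- with_seed(derive_seed(jitter_seed, "sprite_jitter"), {
    stats::rnorm(3, 0, 8)
  })
  shade <- 1 - 0.25 * (v + 1) / 2  # simple top-lit shading
  for (ch in 1:3) {
    col[, , ch] <- clip255((sp$base_color[ch] + jit[ch]) * shade + tex)
  }
  list(color = col, mask = mask)
}

#' Render one synthetic camera-trap image
#'
#' Composites a species sprite (or nothing) onto a location's static
#' background, applies pose (scale, position, occlusion, crop), day/night
#' conditions, and sensor noise. With `species = NULL` the result equals
#' [render_background()] for the same arguments and the mask is empty.
#'
#' @param config A [synthetic_world_config()].
#' @param location_id Location token.
#' @param species Species name, or `NULL` for a background-only image.
#' @param pose List with `scale` (sprite box as a fraction of the shorter
#'   image side, 1 = full side), `position` (fractional `c(y, x)` center),
#'   `occlusion_fraction` (fraction of sprite rows hidden behind foreground,
#'   removed from the mask bottom-up), `crop_fraction` (fraction of the
#'   sprite shifted out of frame; 1 = fully cropped out).
#' @param night Night conditions?
#' @param noise_level Sensor noise SD; defaults to the config value.
#' @param seed Integer seed.
#' @return List with elements `image` (H x W x 3 array) and `mask` (H x W
#'   logical matrix of sprite pixels).
#' @export
render_image <- function(config, location_id, species = NULL,
                         pose = list(), night = FALSE,
                         noise_level = config$noise_level, seed = 1) {
  pose <- utils::modifyList(
    list(scale = 0.5, position = c(0.55, 0.5),
         occlusion_fraction = 0, crop_fraction = 0),
    pose
  )
  h <- config$image_size[1]; w <- config$image_size[2]
  canvas <- background_structure(config, location_id)
  mask_full <- matrix(FALSE, h, w)

  if (!is.null(species)) {
    i <- match(species, config$species_names)
    if (is.na(i)) stop(sprintf("unknown species '%s'", species), call. = FALSE)
    if (config$occupancy[species, location_id] != 1) {
      stop(sprintf("occupancy violation: species '%s' does not occur at location '%s'",
                   species, location_id), call. = FALSE)
    }
    size_px <- max(3L, round(pose$scale * min(h, w)))
    spr <- render_sprite(config$species[[i]], size_px,
                         jitter_seed = derive_seed(seed, "pose", location_id, species))
    m <- spr$mask
    # occlusion: foreground hides the lower part of the animal
    if (pose$occlusion_fraction > 0) {
      hide <- round(pose$occlusion_fraction * size_px)
      if (hide > 0) m[(size_px - hide + 1):size_px, ] <- FALSE
    }
    cy <- round(pose$position[1] * h - size_px / 2)
    cy <- min(max(cy, 1L), max(1L, h - size_px + 1L))
    if (pose$crop_fraction > 0) {
      # crop: anchor at the right edge and shift part of the sprite out of frame
      shift <- round(pose$crop_fraction * size_px)
      cx <- w - size_px + 1L + shift
    } else {
      cx <- round(pose$position[2] * w - size_px / 2)
      cx <- min(max(cx, 1L), max(1L, w - size_px + 1L))
    }
    sy <- which(cy + seq_len(size_px) - 1L >= 1L & cy + seq_len(size_px) - 1L <= h)
    sx <- which(cx + seq_len(size_px) - 1L >= 1L & cx + seq_len(size_px) - 1L <= w)
    if (length(sy) > 0 && length(sx) > 0) {
      tyr <- cy + sy - 1L
      txr <- cx + sx - 1L
      m_sub <- m[sy, sx, drop = FALSE]
      block <- mask_full[tyr, txr, drop = FALSE]
      block[m_sub] <- TRUE
      mask_full[tyr, txr] <- block
      for (ch in 1:3) {
        cplane <- canvas[tyr, txr, ch, drop = TRUE]
        splane <- spr$color[sy, sx, ch, drop = TRUE]
        cplane[m_sub] <- splane[m_sub]
        canvas[tyr, txr, ch] <- cplane
      }
    }
  }

  canvas <- apply_night(canvas, night)
  img <- add_sensor_noise(canvas, noise_level,
                          derive_seed(seed, "noise", location_id, night))
  list(image = img, mask = mask_full)
}
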