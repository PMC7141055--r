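#' Augmentation configuration
#'
#' Controls the stochastic image augmentation pipeline. Eight operators are
#' available - mirroring, color-channel shifts, Gaussian blurring, grayscale
#' conversion, rotation, pixel dropout, local contrast normalization, and
#' small local affine warps - each with an application probability and a
#' magnitude range. Operators are applied in a fixed order (geometry first,
#' then photometry, then dropout), each consuming its own random draws, so a
#' given `(image, config, seed)` always yields the same output. All default
#' magnitudes are label-preserving for small sprites: rotation up to +/-25
#' degrees, blur radius up to 2 px, dropout up to 5% of pixels, channel
#' shifts up to +/-20 intensity levels, affine displacement up to 3 px.
#'
#' @param enabled_ops Character subset of
#'   `c("mirror", "rotate", "local_affine", "blur", "color_channel_shift",
#'   "grayscale", "contrast_normalize", "pixel_dropout")`.
#' @param probs Named numeric vector of per-op application probabilities in
#'   `[0, 1]`; unnamed ops keep the default 0.5.
#' @param rotate_deg Rotation range: scalar m for uniform(-m, m) degrees, or
#'   a length-2 range.
#' @param blur_sigma_max Maximum Gaussian blur sigma in pixels.
#' @param dropout_fraction Probability that an individual pixel is zeroed
#'   when dropout fires.
#' @param channel_shift Maximum per-channel additive shift in intensity
#'   levels (applied symmetrically).
#' @param affine_displacement Maximum corner displacement of the local
#'   affine warp, in pixels.
#' @param contrast_gain Gain of the local contrast normalization residual.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(enabled_ops = c("mirror", "rotate", "local_affine",
                                                "blur", "color_channel_shift",
                                                "grayscale", "contrast_normalize",
                                                "pixel_dropout"),
                                probs = NULL,
                                rotate_deg = 25,
                                blur_sigma_max = 2,
                                dropout_fraction = 0.05,
                                channel_shift = 20,
                                affine_displacement = 3,
                                contrast_gain = 1.5) {
  all_ops <- c("mirror", "rotate", "local_affine", "blur", "color_channel_shift",
               "grayscale", "contrast_normalize", "pixel_dropout")
  enabled_ops <- if (length(enabled_ops) == 0) character(0) else {
    match.arg(enabled_ops, all_ops, several.ok = TRUE)
  }
  p <- setNames(rep(0.5, length(all_ops)), all_ops)
  if (!is.null(probs)) {
    stopifnot(!is.null(names(probs)), all(names(probs) %in% all_ops),
              all(probs >= 0 & probs <= 1))
    p[names(probs)] <- probs
  }
  if (length(rotate_deg) == 1) rotate_deg <- c(-abs(rotate_deg), abs(rotate_deg))
  stopifnot(length(rotate_deg) == 2, blur_sigma_max > 0,
            dropout_fraction >= 0, dropout_fraction <= 1,
            channel_shift >= 0, affine_displacement >= 0)
  structure(
    list(enabled_ops = enabled_ops, probs = p, rotate_deg = sort(rotate_deg),
         blur_sigma_max = blur_sigma_max, dropout_fraction = dropout_fraction,
         channel_shift = channel_shift, affine_displacement = affine_displacement,
         contrast_gain = contrast_gain),
    class = "augmentation_config"
  )
}

#' @export
print.augmentation_config <- function(x, ...) {
  cat("<augmentation>", if (length(x$enabled_ops) == 0) "(all ops disabled)"
      else paste(x$enabled_ops, collapse = ", "), "\n")
  invisible(x)
}

as_ebimage <- function(img) EBImage::Image(img / 255, colormode = "Color")
from_ebimage <- function(x) clip255(EBImage::imageData(x) * 255)

#' Augment one image
#'
#' Applies the configured stochastic operators to an 8-bit RGB array.
#' Deterministic per `(image, config, seed)`; with all operators disabled
#' the input is returned bit-identically. Output dimensions and the
#' `[0, 255]` range are always preserved, and no operator changes the class
#' label semantics of the image.
#'
#' Rotation follows the convention that positive angles rotate the image
#' content counterclockwise (in row/column coordinates); uncovered corners
#' are filled with the image's mean color. "Pixel cluster normalization" is
#' implemented as local contrast normalization: the residual of the image
#' against a Gaussian-smoothed local mean is re-amplified.
#'
#' @param img Height x width x 3 numeric array in `[0, 255]`.
#' @param config An [augmentation_config()].
#' @param seed Integer seed.
#' @return Augmented array of the same shape, integer-valued in `0..255`.
#' @export
augment <- function(img, config, seed = 1) {
  assert_rgb(img)
  stopifnot(inherits(config, "augmentation_config"))
  if (length(config$enabled_ops) == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  on_ops <- config$enabled_ops
  p <- config$probs

  with_seed(derive_seed(seed, "augment"), {
    x <- img
    fire <- function(op) op %in% on_ops && runif(1) < p[[op]]

    if (fire("mirror")) x <- x[, w:1, , drop = FALSE]

    if (fire("rotate")) {
      ang <- runif(1, config$rotate_deg[1], config$rotate_deg[2])
      bg <- mean(x) / 255
      x <- from_ebimage(EBImage::rotate(as_ebimage(x), ang,
                                        output.dim = c(h, w),
                                        bg.col = grDevices::rgb(bg, bg, bg)))
    }

    if (fire("local_affine")) {
      d <- config$affine_displacement
      A <- diag(2) + matrix(runif(4, -d / max(h, w), d / max(h, w)), 2, 2)
      tr <- runif(2, -d, d)
      m <- rbind(A, tr)
      x <- from_ebimage(EBImage::affine(as_ebimage(x), m, output.dim = c(h, w)))
    }

    if (fire("blur")) {
      sigma <- runif(1, 0.3, config$blur_sigma_max)
      x <- from_ebimage(EBImage::gblur(as_ebimage(x), sigma = sigma))
    }

    if (fire("color_channel_shift")) {
      shift <- runif(3, -config$channel_shift, config$channel_shift)
      for (ch in 1:3) x[, , ch] <- x[, , ch] + shift[ch]
      x <- clip255(x)
    }

    if (fire("grayscale")) {
      g <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
      for (ch in 1:3) x[, , ch] <- g
    }

    if (fire("contrast_normalize")) {
      smooth <- from_ebimage(EBImage::gblur(as_ebimage(x), sigma = 3))
      x <- clip255(smooth + config$contrast_gain * (x - smooth))
    }

    if (fire("pixel_dropout")) {
      drop <- matrix(runif(h * w) < config$dropout_fraction, h, w)
      for (ch in 1:3) {
        plane <- x[, , ch]
        plane[drop] <- 0
        x[, , ch] <- plane
      }
    }

    round(clip255(x))
  })
}
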