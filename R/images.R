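#' Pixel array helpers
#'
#' Images are represented throughout the package as numeric arrays of shape
#' height x width x 3 holding 8-bit RGB intensities in `[0, 255]`. PNG files
#' are read and written through the png package; EBImage provides the
#' geometric and filtering primitives used by augmentation.
#'
#' @name pixel-arrays
#' @keywords internal
NULL

assert_rgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      !is.numeric(img)) {
    stop(sprintf("%s must be a height x width x 3 numeric RGB array", what),
         call. = FALSE)
  }
  invisible(img)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Write an 8-bit RGB array to a PNG file
#' @param img Height x width x 3 array with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  assert_rgb(img)
  png::writePNG(round(clip255(img)) / 255, path)
  invisible(path)
}

#' Read a PNG file as an 8-bit RGB array
#' @param path PNG path.
#' @return Height x width x 3 array with values in `0..255`.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Mean luminance of an RGB array
#' @param img Height x width x 3 array.
#' @return Scalar mean of the per-pixel channel means, in `[0, 255]`.
#' @export
mean_luminance <- function(img) {
  assert_rgb(img)
  mean(img)
}

#' Retrieve the pixel array for one catalog record
#'
#' Resolves in-memory images first (synthetic worlds generated without an
#' output directory), then falls back to reading the record's PNG path,
#' relative paths being resolved against the catalog root.
#'
#' @param cat A [catalog()].
#' @param image_id Record identifier.
#' @return Height x width x 3 array in `0..255`.
#' @export
get_image <- function(cat, image_id) {
  stopifnot(inherits(cat, "catalog"))
  if (!is.null(cat$images) && image_id %in% names(cat$images)) {
    return(cat$images[[image_id]])
  }
  i <- match(image_id, cat$records$image_id)
  if (is.na(i)) stop(sprintf("unknown image_id '%s'", image_id), call. = FALSE)
  p <- cat$records$path[i]
  if (is.na(p)) stop(sprintf("no pixels available for '%s'", image_id), call. = FALSE)
  root <- attr(cat, "root")
  if (!is.null(root) && !file.exists(p)) p <- file.path(root, p)
  read_image_png(p)
}
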