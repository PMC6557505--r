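# Reading and writing images and region masks. PNG and TIFF only; RAW
# decoding is out of scope (photographs are expected to arrive already
# decoded). 8- and 16-bit integer images are normalized to [0, 1] on load by
# the readers (division by the type maximum).

#' Read a photograph from disk
#'
#' Supports 8- and 16-bit PNG and TIFF. An alpha channel is dropped;
#' single-channel (grayscale) images are replicated to three channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An [rgb_image] (sRGB-encoded, values in `[0, 1]`).
#' @export
read_image <- function(path) {
  px <- .read_raster(path)
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (dim(px)[3] == 4L) {
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3] == 2L) {
    px <- array(rep(px[, , 1], 3L), dim = c(dim(px)[1:2], 3L))
  }
  rgb_image(px, encoding = "srgb")
}

.read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  )
}

#' Write an image to disk
#'
#' @param img An [rgb_image]; linear-encoded images are re-encoded to sRGB
#'   before writing.
#' @param path Output path; format chosen from the extension (`.png`,
#'   `.tif`/`.tiff`).
#' @param bits Bit depth for TIFF output (8 or 16); PNG is written at 8 bit.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 8L) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  if (identical(attr(img, "encoding"), "linear")) {
    img <- rgb_image(array(linear_to_srgb(img), dim = dim(img)), "srgb")
  }
  ext <- tolower(tools::file_ext(path))
  px <- unclass(img)
  attributes(px) <- list(dim = dim(px))
  switch(ext,
    png = png::writePNG(px, target = path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits)),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Load a measurement-area mask
#'
#' Masks are single-channel 8-bit PNG images: any nonzero pixel is inside
#' the measurement area. The mask must have the same height and width as the
#' photograph it belongs to.
#'
#' @param path Path to the mask PNG.
#' @param image_shape Integer vector `c(H, W)` (or the dimensions of an
#'   [rgb_image]/[lab_image]) to validate against.
#' @param label Area label, e.g. `"irradiated"` or `"control"`.
#' @return A [measurement_area].
#' @export
load_mask <- function(path, image_shape, label = "other") {
  px <- .read_raster(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  if (length(image_shape) > 2L) image_shape <- image_shape[1:2]
  if (!identical(as.integer(dim(px)), as.integer(image_shape))) {
    stop(sprintf("mask dimensions (%d x %d) do not match image (%d x %d)",
                 nrow(px), ncol(px), image_shape[1], image_shape[2]),
         call. = FALSE)
  }
  measurement_area(px != 0, label = label)
}
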