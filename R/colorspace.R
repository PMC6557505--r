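# sRGB <-> CIELAB conversion (D65 white point, 2-degree standard observer).
#
# The forward chain is sRGB -> linear RGB -> XYZ -> CIELAB; every step is
# exactly invertible for in-gamut colors. All images are stored as H x W x 3
# double arrays with channel values in [0, 1] (RGB) or on the native CIELAB
# scales (L* in [0, 100], a*/b* unbounded).

# IEC 61966-2-1 sRGB primaries -> XYZ (D65). The reference white is taken as
# the row sums of this matrix so that exactly neutral inputs (r = g = b) map
# to a* = b* = 0 with no rounding residue.
.rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3L, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)
.white_xyz <- rowSums(.rgb2xyz)

#' Construct an RGB image
#'
#' An RGB image is an `H x W x 3` double array with all channel values in
#' `[0, 1]`. The `encoding` attribute records whether the values are
#' sRGB-encoded (the usual state of a decoded photograph) or linear-light.
#'
#' @param pixels An `H x W x 3` numeric array with values in `[0, 1]`.
#' @param encoding `"srgb"` (gamma-encoded, the default for photographs) or
#'   `"linear"` (linear-light).
#' @return An object of class `rgb_image` (the validated array).
#' @export
rgb_image <- function(pixels, encoding = c("srgb", "linear")) {
  encoding <- match.arg(encoding)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) {
    stop("image dimensions must be at least 1 x 1", call. = FALSE)
  }
  if (anyNA(pixels) || !all(is.finite(pixels))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 1)) {
    stop("channel values must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, class = "rgb_image", encoding = encoding)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, %s-encoded\n",
              d[1], d[2], attr(x, "encoding")))
  invisible(x)
}

#' Construct a CIELAB image
#'
#' @param L,a,b Numeric `H x W` matrices holding the lightness L* (in
#'   `[0, 100]`), the red-green component a*, and the blue-yellow component
#'   b* of every pixel.
#' @return An object of class `lab_image`: an `H x W x 3` array with the
#'   channels L*, a*, b*.
#' @export
lab_image <- function(L, a, b) {
  if (!is.matrix(L) || !identical(dim(L), dim(a)) || !identical(dim(L), dim(b))) {
    stop("`L`, `a`, `b` must be matrices of identical dimensions", call. = FALSE)
  }
  if (anyNA(L) || !all(is.finite(L), is.finite(a), is.finite(b))) {
    stop("CIELAB channels contain non-finite values", call. = FALSE)
  }
  if (any(L < 0) || any(L > 100)) {
    stop("L* must lie in [0, 100]", call. = FALSE)
  }
  structure(array(c(L, a, b), dim = c(dim(L), 3L),
                  dimnames = list(NULL, NULL, c("L", "a", "b"))),
            class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lab_image> %d x %d pixels (L*, a*, b*)\n", d[1], d[2]))
  invisible(x)
}

#' sRGB transfer function
#'
#' Decode sRGB-encoded values to linear-light, or re-encode linear values
#' to sRGB. Both functions implement the standard piecewise sRGB transfer
#' curve (linear segment below 0.04045 / 0.0031308, exponent 2.4 above) and
#' are exact inverses of each other on `[0, 1]`.
#'
#' @param v Numeric vector, matrix or array with values in `[0, 1]`.
#' @return Object of the same shape as `v`.
#' @export
srgb_to_linear <- function(v) {
  if (anyNA(v) || any(v < 0) || any(v > 1)) {
    stop("sRGB values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' @rdname srgb_to_linear
#' @export
linear_to_srgb <- function(v) {
  if (anyNA(v) || any(v < 0) || any(v > 1)) {
    stop("linear values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

# CIE lightness function and inverse; delta = 6/29.
.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

# Flatten an H x W x 3 array to an N x 3 matrix (pixels in column-major
# order) and back.
.flatten <- function(img) matrix(img, ncol = 3L)
.unflatten <- function(m, d) array(m, dim = c(d[1], d[2], 3L))

#' Convert an RGB image to CIELAB
#'
#' Pixels are decoded from sRGB to linear-light (when the image is flagged
#' `srgb`), mapped to CIE XYZ using the sRGB primaries with D65 white, and
#' converted to CIELAB with the standard cube-root lightness function. The
#' conversion is vectorized over the whole image.
#'
#' @param img An [rgb_image].
#' @return A [lab_image] of the same dimensions.
#' @export
#' @examples
#' img <- rgb_image(array(0.5, dim = c(2, 2, 3)))
#' lab <- rgb_to_lab(img)
#' lab[1, 1, ] # neutral mid gray: L* ~ 53.39, a* = b* = 0
rgb_to_lab <- function(img) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  m <- .flatten(img)
  if (identical(attr(img, "encoding"), "srgb")) m <- srgb_to_linear(m)
  xyz <- m %*% t(.rgb2xyz)
  fxyz <- .lab_f(sweep(xyz, 2L, .white_xyz, "/"))
  L <- 116 * fxyz[, 2] - 16
  a <- 500 * (fxyz[, 1] - fxyz[, 2])
  b <- 200 * (fxyz[, 2] - fxyz[, 3])
  d <- dim(img)
  lab_image(matrix(L, d[1], d[2]), matrix(a, d[1], d[2]), matrix(b, d[1], d[2]))
}

#' Convert a CIELAB image to sRGB
#'
#' Exact inverse of [rgb_to_lab()] for in-gamut colors. Out-of-gamut pixels
#' are clipped to `[0, 1]` in linear RGB; the number of clipped pixels is
#' recorded in the `n_clipped` attribute of the result (clipping is reported,
#' never fatal).
#'
#' @param lab A [lab_image].
#' @param encoding Encoding of the returned image, `"srgb"` or `"linear"`.
#' @return An [rgb_image] with attribute `n_clipped`.
#' @export
lab_to_rgb <- function(lab, encoding = c("srgb", "linear")) {
  encoding <- match.arg(encoding)
  if (!inherits(lab, "lab_image")) {
    stop("`lab` must be a lab_image", call. = FALSE)
  }
  m <- .flatten(lab)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.lab_finv(fx), .lab_finv(fy), .lab_finv(fz))
  xyz <- sweep(xyz, 2L, .white_xyz, "*")
  lin <- xyz %*% t(.xyz2rgb)
  # count only genuinely out-of-gamut pixels, not rounding dust at 0/1
  clipped <- lin < -1e-9 | lin > 1 + 1e-9
  n_clipped <- sum(rowSums(clipped) > 0)
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  out <- if (encoding == "srgb") linear_to_srgb(lin) else lin
  res <- rgb_image(.unflatten(out, dim(lab)), encoding = encoding)
  attr(res, "n_clipped") <- n_clipped
  res
}
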