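# Color calibration from a photographed reference card.
#
# The correction model is affine in linear RGB: a 3 x 3 matrix plus an
# offset, fitted by ordinary least squares over the card patches. Affine in
# linear light absorbs both a global color cast and an exposure shift and
# has a closed-form fit; patch locations come from a layout config rather
# than automatic card detection.

# ColorChecker Classic nominal sRGB coordinates (8-bit), row-major from the
# dark-skin patch; widely published nominal values for the 24-patch chart.
.colorchecker_srgb <- matrix(c(
  115,  82,  68,   194, 150, 130,    98, 122, 157,    87, 108,  67,
  133, 128, 177,   103, 189, 170,   214, 126,  44,    80,  91, 166,
  193,  90,  99,    94,  60, 108,   157, 188,  64,   224, 163,  46,
   56,  61, 150,    70, 148,  73,   175,  54,  60,   231, 199,  31,
  187,  86, 149,     8, 133, 161,   243, 243, 242,   200, 200, 200,
  160, 160, 160,   122, 122, 121,    85,  85,  85,    52,  52,  52
), ncol = 3L, byrow = TRUE) / 255

.colorchecker_ids <- c(
  "dark_skin", "light_skin", "blue_sky", "foliage", "blue_flower",
  "bluish_green", "orange", "purplish_blue", "moderate_red", "purple",
  "yellow_green", "orange_yellow", "blue", "green", "red", "yellow",
  "magenta", "cyan", "white", "neutral_8", "neutral_65", "neutral_5",
  "neutral_35", "black"
)

#' Describe the patch layout of a reference card
#'
#' A card layout lists, for every patch, its pixel rectangle in the
#' photograph and its known reference color. Rectangles use 0-based,
#' half-open coordinates `(x0, y0, x1, y1)` with `x` along image columns and
#' `y` along rows, origin at the top-left pixel.
#'
#' @param patches A data frame with columns `patch_id`, `x0`, `y0`, `x1`,
#'   `y1`, `ref_r`, `ref_g`, `ref_b` (reference sRGB in `[0, 1]`).
#' @return A `card_layout` tibble.
#' @export
card_layout <- function(patches) {
  patches <- tibble::as_tibble(patches)
  need <- c("patch_id", "x0", "y0", "x1", "y1", "ref_r", "ref_g", "ref_b")
  if (!all(need %in% names(patches))) {
    stop("layout must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(patches$x1 <= patches$x0) || any(patches$y1 <= patches$y0)) {
    stop("patch rectangles must satisfy x1 > x0 and y1 > y0", call. = FALSE)
  }
  refs <- as.matrix(patches[, c("ref_r", "ref_g", "ref_b")])
  if (any(refs < 0) || any(refs > 1)) {
    stop("reference sRGB values must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(patches)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (patches$x0[i] < patches$x1[j] && patches$x0[j] < patches$x1[i] &&
          patches$y0[i] < patches$y1[j] && patches$y0[j] < patches$y1[i]) {
        stop(sprintf("patch regions '%s' and '%s' overlap",
                     patches$patch_id[i], patches$patch_id[j]), call. = FALSE)
      }
    }
  }
  class(patches) <- c("card_layout", class(patches))
  patches
}

#' Read a card layout from a JSON or YAML config file
#'
#' The config is a list of patches, each with fields `id`, `rect`
#' (`[x0, y0, x1, y1]`, 0-based half-open) and `ref` (sRGB triple in
#' `[0, 1]`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [card_layout].
#' @export
read_card_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported layout format: .", ext, call. = FALSE)
  )
  if (!is.null(raw$patches)) raw <- raw$patches
  card_layout(purrr::map_dfr(raw, function(p) {
    tibble::tibble(
      patch_id = as.character(p$id),
      x0 = p$rect[[1]], y0 = p$rect[[2]], x1 = p$rect[[3]], y1 = p$rect[[4]],
      ref_r = p$ref[[1]], ref_g = p$ref[[2]], ref_b = p$ref[[3]]
    )
  }))
}

#' Default 24-patch reference card layout
#'
#' Builds a layout for a ColorChecker-style 24-patch card rendered as a
#' `nrow_card x 6` grid of square patches.
#'
#' @param origin `c(x0, y0)` pixel position of the top-left corner of the
#'   first patch (0-based).
#' @param patch_px Side length of each patch in pixels.
#' @param gap_px Gap between neighboring patches in pixels.
#' @param nrow_card Number of patch rows (the 24 patches are laid out
#'   row-major).
#' @return A [card_layout] with the 24 classic reference colors.
#' @export
colorchecker_layout <- function(origin = c(0, 0), patch_px = 20L,
                                gap_px = 4L, nrow_card = 4L) {
  ncol_card <- ceiling(24L / nrow_card)
  idx <- seq_len(24L) - 1L
  row <- idx %/% ncol_card
  col <- idx %% ncol_card
  x0 <- origin[1] + col * (patch_px + gap_px)
  y0 <- origin[2] + row * (patch_px + gap_px)
  card_layout(tibble::tibble(
    patch_id = .colorchecker_ids,
    x0 = x0, y0 = y0, x1 = x0 + patch_px, y1 = y0 + patch_px,
    ref_r = .colorchecker_srgb[, 1],
    ref_g = .colorchecker_srgb[, 2],
    ref_b = .colorchecker_srgb[, 3]
  ))
}

#' Measure the observed card-patch colors in a photograph
#'
#' Computes the per-patch channel means in linear RGB (pixels are decoded
#' from sRGB first), in the order the layout lists the patches.
#'
#' @param img An [rgb_image] containing the photographed card.
#' @param layout A [card_layout]; every patch rectangle must lie inside the
#'   image and contain at least 25 pixels.
#' @return A tibble with columns `patch_id`, `r`, `g`, `b` (observed linear
#'   RGB means).
#' @export
extract_patch_colors <- function(img, layout) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  d <- dim(img)
  if (any(layout$x0 < 0) || any(layout$y0 < 0) ||
      any(layout$x1 > d[2]) || any(layout$y1 > d[1])) {
    stop("patch region lies outside the image bounds", call. = FALSE)
  }
  npx <- (layout$x1 - layout$x0) * (layout$y1 - layout$y0)
  if (any(npx < 25)) {
    stop("patch regions must contain at least 25 pixels", call. = FALSE)
  }
  lin <- if (identical(attr(img, "encoding"), "srgb")) {
    array(srgb_to_linear(img), dim = d)
  } else {
    unclass(img)
  }
  purrr::pmap_dfr(layout[, c("patch_id", "x0", "y0", "x1", "y1")],
    function(patch_id, x0, y0, x1, y1) {
      rows <- (y0 + 1L):y1
      cols <- (x0 + 1L):x1
      tibble::tibble(
        patch_id = patch_id,
        r = mean(lin[rows, cols, 1]),
        g = mean(lin[rows, cols, 2]),
        b = mean(lin[rows, cols, 3])
      )
    })
}

.patch_matrix <- function(x, ref = FALSE) {
  if (is.matrix(x)) return(x)
  cols <- if (ref) c("ref_r", "ref_g", "ref_b") else c("r", "g", "b")
  if (is.data.frame(x)) {
    if (!all(cols %in% names(x))) cols <- c("r", "g", "b")
    if (!all(cols %in% names(x))) {
      stop("patch table must have columns r, g, b (or ref_r, ref_g, ref_b)",
           call. = FALSE)
    }
    return(as.matrix(x[, cols]))
  }
  stop("patch colors must be a matrix or data frame", call. = FALSE)
}

#' Fit an affine color correction from card patches
#'
#' Fits, by ordinary least squares, the affine map `A x + c` in linear RGB
#' that best sends the observed patch colors to their reference values.
#' Requires at least 4 chromatically independent patches; an all-gray card
#' (or any rank-deficient patch set) is rejected.
#'
#' @param observed Observed patch colors in linear RGB: a matrix with 3
#'   columns or the tibble returned by [extract_patch_colors()].
#' @param reference Reference patch colors in linear RGB, same length and
#'   order. A [card_layout] may be given: its sRGB references are decoded
#'   to linear automatically.
#' @return A `color_correction` object with elements `matrix` (3 x 3),
#'   `offset` (length 3) and `fit_residual` (root-mean-square
#'   post-correction patch error over all patch-channel entries, linear-RGB
#'   units).
#' @export
fit_color_correction <- function(observed, reference) {
  obs <- .patch_matrix(observed)
  ref <- if (inherits(reference, "card_layout")) {
    srgb_to_linear(.patch_matrix(reference, ref = TRUE))
  } else {
    .patch_matrix(reference, ref = TRUE)
  }
  if (nrow(obs) != nrow(ref)) {
    stop("observed and reference patch sets differ in length", call. = FALSE)
  }
  if (nrow(obs) < 4L) {
    stop("at least 4 patches are required to fit an affine correction",
         call. = FALSE)
  }
  X <- cbind(obs, 1)
  qrx <- qr(X)
  if (qrx$rank < 4L) {
    stop(paste0(
      "patch set is rank-deficient (rank ", qrx$rank, " < 4): the observed ",
      "colors span too small a subspace (e.g. an all-gray card) to ",
      "determine an affine correction"), call. = FALSE)
  }
  B <- qr.coef(qrx, ref)              # 4 x 3: rows = (r, g, b, intercept)
  pred <- X %*% B
  res <- sqrt(mean((pred - ref)^2))
  structure(
    list(matrix = t(B[1:3, , drop = FALSE]), offset = as.numeric(B[4, ]),
         fit_residual = res, n_patches = nrow(obs)),
    class = "color_correction"
  )
}

#' Identity color correction
#' @return A `color_correction` that leaves images unchanged.
#' @export
identity_correction <- function() {
  structure(list(matrix = diag(3), offset = c(0, 0, 0),
                 fit_residual = 0, n_patches = NA_integer_),
            class = "color_correction")
}

#' @export
print.color_correction <- function(x, ...) {
  cat("<color_correction> affine map in linear RGB\n")
  cat("  matrix:\n")
  print(round(x$matrix, 5))
  cat("  offset:", paste(round(x$offset, 5), collapse = ", "), "\n")
  cat(sprintf("  fit residual (RMS, linear RGB): %.3g over %s patches\n",
              x$fit_residual, x$n_patches))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted color correction
#'
#' @param x A `color_correction`.
#' @param ... Unused.
#' @return One row per affine coefficient (`term`, `estimate`).
#' @method tidy color_correction
#' @export
tidy.color_correction <- function(x, ...) {
  terms <- c(outer(c("r", "g", "b"), c("r", "g", "b"),
                   function(i, j) paste0(i, "~", j)),
             paste0(c("r", "g", "b"), "~1"))
  tibble::tibble(term = terms, estimate = c(x$matrix, x$offset))
}

#' @rdname tidy.color_correction
#' @method glance color_correction
#' @export
glance.color_correction <- function(x, ...) {
  tibble::tibble(fit_residual = x$fit_residual, n_patches = x$n_patches)
}

#' Apply a color correction to an image
#'
#' The affine map is applied per pixel in linear RGB; results are clipped to
#' `[0, 1]` (the clipped-pixel count is reported in the `n_clipped`
#' attribute) and re-encoded to sRGB.
#'
#' @param img An [rgb_image].
#' @param correction A `color_correction` from [fit_color_correction()].
#' @return A corrected [rgb_image] (sRGB-encoded) with attribute
#'   `n_clipped`.
#' @export
apply_correction <- function(img, correction) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  if (!inherits(correction, "color_correction")) {
    stop("`correction` must be a color_correction", call. = FALSE)
  }
  d <- dim(img)
  m <- .flatten(img)
  if (identical(attr(img, "encoding"), "srgb")) m <- srgb_to_linear(m)
  out <- m %*% t(correction$matrix)
  out <- sweep(out, 2L, correction$offset, "+")
  clipped <- out < -1e-9 | out > 1 + 1e-9
  n_clipped <- sum(rowSums(clipped) > 0)
  out[out < 0] <- 0
  out[out > 1] <- 1
  res <- rgb_image(.unflatten(linear_to_srgb(out), d), encoding = "srgb")
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Save / load a color correction as JSON
#'
#' @param correction A `color_correction`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `read_color_correction()` returns the object.
#' @export
write_color_correction <- function(correction, path) {
  jsonlite::write_json(
    list(matrix = correction$matrix, offset = correction$offset,
         fit_residual = correction$fit_residual,
         n_patches = correction$n_patches),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_color_correction
#' @export
read_color_correction <- function(path) {
  raw <- jsonlite::fromJSON(path)
  structure(list(matrix = matrix(as.numeric(t(raw$matrix)), 3, 3, byrow = TRUE),
                 offset = as.numeric(raw$offset),
                 fit_residual = as.numeric(raw$fit_residual),
                 n_patches = raw$n_patches),
            class = "color_correction")
}
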