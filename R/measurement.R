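# Measurement areas and their CIELAB color summaries. An area is a binary
# pixel mask over the photograph (typically "irradiated" and the
# contralateral "control" region); its summary is the per-channel mean and
# SD of L*, a*, b* over the masked pixels.

#' Define a measurement area
#'
#' @param mask Logical `H x W` matrix, `TRUE` inside the area. Masks are
#'   strictly binary; no feathering or partial-pixel weighting.
#' @param label Area label: `"irradiated"`, `"control"`, or any other name.
#' @return A `measurement_area` with elements `mask`, `label`,
#'   `pixel_count`.
#' @export
measurement_area <- function(mask, label = "other") {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  if (anyNA(mask)) stop("mask contains missing values", call. = FALSE)
  n <- sum(mask)
  if (n == 0L) stop("empty measurement area", call. = FALSE)
  structure(list(mask = mask, label = as.character(label), pixel_count = n),
            class = "measurement_area")
}

#' @export
print.measurement_area <- function(x, ...) {
  cat(sprintf("<measurement_area> '%s': %d of %d pixels (%d x %d)\n",
              x$label, x$pixel_count, length(x$mask),
              nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Check an area against the recommended minimum pixel count
#'
#' Clinical-scale measurement areas should contain at least one megapixel of
#' data; smaller areas yield noisier color summaries. The check warns but
#' never fails, so that small bench-scale images remain usable.
#'
#' @param area A [measurement_area].
#' @param minimum Minimum recommended pixel count (default `1e6`).
#' @return `TRUE` (meets the minimum) or `FALSE` (warned), invisibly.
#' @export
check_minimum_area <- function(area, minimum = 1e6) {
  if (area$pixel_count < minimum) {
    warning(sprintf(
      "measurement area '%s' has %d pixels, below the recommended minimum of %s",
      area$label, area$pixel_count, format(minimum, scientific = FALSE)),
      call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

# Population SD (denominator n): area summaries are descriptive statistics
# of a fixed pixel population, not sample estimates.
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize the CIELAB color of a measurement area
#'
#' Computes the arithmetic mean and SD of L*, a*, b* over the masked pixels.
#' SDs use the population denominator `n` (the masked pixels are the whole
#' population of interest, not a sample).
#'
#' @param lab A [lab_image].
#' @param area A [measurement_area] of matching dimensions.
#' @return A one-row tibble: `label`, `n_pixels`, `mean_L`, `sd_L`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
summarize_area <- function(lab, area) {
  if (!inherits(lab, "lab_image")) stop("`lab` must be a lab_image", call. = FALSE)
  if (!inherits(area, "measurement_area")) {
    stop("`area` must be a measurement_area", call. = FALSE)
  }
  if (!identical(dim(lab)[1:2], dim(area$mask))) {
    stop("mask dimensions do not match the image", call. = FALSE)
  }
  L <- lab[, , 1][area$mask]
  a <- lab[, , 2][area$mask]
  b <- lab[, , 3][area$mask]
  tibble::tibble(
    label = area$label, n_pixels = area$pixel_count,
    mean_L = mean(L), sd_L = .pop_sd(L),
    mean_a = mean(a), sd_a = .pop_sd(a),
    mean_b = mean(b), sd_b = .pop_sd(b)
  )
}

#' Summarize several measurement areas at once
#'
#' @param lab A [lab_image].
#' @param areas A list of [measurement_area] objects.
#' @return A tibble with one row per area (see [summarize_area()]).
#' @export
summarize_areas <- function(lab, areas) {
  purrr::map_dfr(areas, summarize_area, lab = lab)
}
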