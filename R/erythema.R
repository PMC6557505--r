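# Standard Erythema Value (SEV) and its baseline-subtracted form.
#
# SEV combines lightness and redness into one signal: per pixel,
# SEV = (L*max - L*) x a*, with L*max = 100 (the top of the CIELAB lightness
# scale). The product compensates the suppression of a* by pigmentation
# (darker skin lowers both L* and a*), so equally red lesions on lighter and
# darker skin score alike. Delta-SEV subtracts the SEV of the patient's own
# non-irradiated baseline skin, removing inter-patient baseline tone scatter.

#' Per-pixel SEV map over a measurement area
#'
#' Computes `sev = (l_max - L*) * a*` for every masked pixel, and the
#' arithmetic mean and SD of those per-pixel values. The per-pixel mean is
#' the canonical area SEV; see [sev_of_mean_color()] for the alternative
#' aggregation from the area's mean color.
#'
#' @param lab A [lab_image].
#' @param area A [measurement_area] of matching dimensions.
#' @param l_max Lightness ceiling of the SEV formula; 100 is the top of the
#'   CIELAB scale and the default. Masked pixels with `L* > l_max` raise an
#'   error, since they signal a broken upstream conversion.
#' @return A `sev_result`: `sev_map` (`H x W`, `NA` outside the area),
#'   `mean_sev`, `sd_sev` (population denominator), `l_max`, `n_pixels`,
#'   `label`.
#' @export
#' @examples
#' lab <- lab_image(matrix(66.66, 4, 4), matrix(6.91, 4, 4), matrix(16.53, 4, 4))
#' area <- measurement_area(matrix(TRUE, 4, 4), "control")
#' sev_map(lab, area)$mean_sev # (100 - 66.66) * 6.91 = 230.4
sev_map <- function(lab, area, l_max = 100) {
  if (!inherits(lab, "lab_image")) stop("`lab` must be a lab_image", call. = FALSE)
  if (!inherits(area, "measurement_area")) {
    stop("`area` must be a measurement_area", call. = FALSE)
  }
  if (!identical(dim(lab)[1:2], dim(area$mask))) {
    stop("mask dimensions do not match the image", call. = FALSE)
  }
  d <- dim(lab)
  L <- matrix(lab[, , 1], d[1], d[2])
  a <- matrix(lab[, , 2], d[1], d[2])
  if (any(L[area$mask] > l_max)) {
    stop(sprintf(
      "L* exceeds l_max = %g on %d masked pixels; this indicates a broken conversion",
      l_max, sum(L[area$mask] > l_max)), call. = FALSE)
  }
  smap <- matrix(NA_real_, nrow(L), ncol(L))
  smap[area$mask] <- (l_max - L[area$mask]) * a[area$mask]
  vals <- smap[area$mask]
  structure(
    list(sev_map = smap, mean_sev = mean(vals), sd_sev = .pop_sd(vals),
         l_max = l_max, n_pixels = area$pixel_count, label = area$label),
    class = "sev_result"
  )
}

#' @export
print.sev_result <- function(x, ...) {
  cat(sprintf("<sev_result> '%s': mean SEV %.2f (SD %.2f) over %d pixels (L*max = %g)\n",
              x$label, x$mean_sev, x$sd_sev, x$n_pixels, x$l_max))
  invisible(x)
}

#' @method tidy sev_result
#' @export
tidy.sev_result <- function(x, ...) {
  tibble::tibble(label = x$label, n_pixels = x$n_pixels,
                 mean_sev = x$mean_sev, sd_sev = x$sd_sev, l_max = x$l_max)
}

#' Baseline-subtracted SEV
#'
#' `delta_sev = mean SEV of the measured (irradiated) area - mean SEV of the
#' baseline (contralateral control) area`. Both inputs must use the same
#' `l_max`.
#'
#' @param measured,baseline `sev_result` objects from [sev_map()].
#' @return A `delta_sev` object: `value`, `sev_measured`, `sev_baseline`,
#'   `l_max`.
#' @export
delta_sev <- function(measured, baseline) {
  if (!inherits(measured, "sev_result") || !inherits(baseline, "sev_result")) {
    stop("`measured` and `baseline` must be sev_result objects", call. = FALSE)
  }
  if (!isTRUE(all.equal(measured$l_max, baseline$l_max))) {
    stop(sprintf("l_max mismatch: measured %g vs baseline %g",
                 measured$l_max, baseline$l_max), call. = FALSE)
  }
  structure(
    list(value = measured$mean_sev - baseline$mean_sev,
         sev_measured = measured$mean_sev,
         sev_baseline = baseline$mean_sev,
         l_max = measured$l_max),
    class = "delta_sev"
  )
}

#' @export
print.delta_sev <- function(x, ...) {
  cat(sprintf("<delta_sev> %.2f (measured %.2f - baseline %.2f)\n",
              x$value, x$sev_measured, x$sev_baseline))
  invisible(x)
}

#' @method tidy delta_sev
#' @export
tidy.delta_sev <- function(x, ...) {
  tibble::tibble(delta_sev = x$value, sev_measured = x$sev_measured,
                 sev_baseline = x$sev_baseline, l_max = x$l_max)
}

#' SEV of an area's mean color
#'
#' The alternative aggregation `(l_max - mean_L) * mean_a`, computed from a
#' color summary rather than per pixel. For a uniform area it equals the
#' per-pixel mean SEV exactly; for inhomogeneous areas the two differ by the
#' covariance term `cov(-L*, a*)`, which is why the per-pixel mean is the
#' canonical statistic and this one is provided for sensitivity comparison.
#'
#' @param summary A color-summary tibble (see [summarize_area()]); vectorized
#'   over rows.
#' @param l_max Lightness ceiling, default 100.
#' @return Numeric vector, one value per summary row.
#' @export
sev_of_mean_color <- function(summary, l_max = 100) {
  if (!all(c("mean_L", "mean_a") %in% names(summary))) {
    stop("`summary` must have columns mean_L and mean_a", call. = FALSE)
  }
  (l_max - summary$mean_L) * summary$mean_a
}
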