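# End-to-end convenience wrapper: photograph + masks (+ optional card
# calibration) -> color summaries, per-area SEV, Delta-SEV.

#' Analyze a photographed pair of measurement areas
#'
#' Runs the full measurement chain on one patient's photograph: optional
#' color correction, conversion to CIELAB, color summaries of the measured
#' (irradiated) and baseline (control) areas, per-pixel SEV maps, and the
#' baseline-subtracted Delta-SEV.
#'
#' @param img An [rgb_image] (e.g. from [read_image()]).
#' @param measured,baseline [measurement_area]s for the irradiated region
#'   and the contralateral control region.
#' @param correction Optional `color_correction` to apply first.
#' @param l_max SEV lightness ceiling (default 100).
#' @param check_area Warn when an area is below the recommended megapixel
#'   minimum (default `FALSE`; bench-scale images are routinely smaller).
#' @return A list of class `erythema_analysis`: `summaries` (two-row
#'   tibble), `sev_measured`, `sev_baseline` (`sev_result`s), `delta_sev`
#'   (`delta_sev` object).
#' @export
analyze_image <- function(img, measured, baseline, correction = NULL,
                          l_max = 100, check_area = FALSE) {
  if (!is.null(correction)) img <- apply_correction(img, correction)
  lab <- rgb_to_lab(img)
  if (check_area) {
    check_minimum_area(measured)
    check_minimum_area(baseline)
  }
  sev_m <- sev_map(lab, measured, l_max = l_max)
  sev_b <- sev_map(lab, baseline, l_max = l_max)
  structure(
    list(summaries = summarize_areas(lab, list(measured, baseline)),
         sev_measured = sev_m, sev_baseline = sev_b,
         delta_sev = delta_sev(sev_m, sev_b)),
    class = "erythema_analysis"
  )
}

#' @export
print.erythema_analysis <- function(x, ...) {
  cat("<erythema_analysis>\n")
  print(as.data.frame(x$summaries), digits = 4)
  cat(sprintf("  mean SEV: measured %.2f, baseline %.2f; Delta-SEV = %.2f\n",
              x$sev_measured$mean_sev, x$sev_baseline$mean_sev,
              x$delta_sev$value))
  invisible(x)
}

#' @method tidy erythema_analysis
#' @export
tidy.erythema_analysis <- function(x, ...) {
  dplyr::mutate(x$summaries,
                mean_sev = c(x$sev_measured$mean_sev, x$sev_baseline$mean_sev),
                sd_sev = c(x$sev_measured$sd_sev, x$sev_baseline$sd_sev),
                delta_sev = x$delta_sev$value)
}

#' @rdname tidy.erythema_analysis
#' @method glance erythema_analysis
#' @export
glance.erythema_analysis <- function(x, ...) {
  tibble::tibble(delta_sev = x$delta_sev$value,
                 sev_measured = x$sev_measured$mean_sev,
                 sev_baseline = x$sev_baseline$mean_sev,
                 l_max = x$delta_sev$l_max)
}
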