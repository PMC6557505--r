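# ggplot2 visualizations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a SEV heat map
#'
#' @param object A `sev_result` from [sev_map()].
#' @param ... Unused.
#' @return A ggplot raster of the per-pixel SEV over the measurement area.
#' @method autoplot sev_result
#' @export
autoplot.sev_result <- function(object, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object$sev_map)),
                           x = seq_len(ncol(object$sev_map)))
  df$sev <- as.vector(t(object$sev_map))
  df <- df[!is.na(df$sev), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$sev)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "SEV") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("SEV map ('%s')", object$label),
      subtitle = sprintf("mean %.1f (SD %.1f), L*max = %g",
                         object$mean_sev, object$sd_sev, object$l_max),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Display an RGB image
#'
#' @param object An [rgb_image].
#' @param ... Unused.
#' @return A ggplot showing the image.
#' @method autoplot rgb_image
#' @export
autoplot.rgb_image <- function(object, ...) {
  if (identical(attr(object, "encoding"), "linear")) {
    object <- rgb_image(array(linear_to_srgb(object), dim = dim(object)), "srgb")
  }
  d <- dim(object)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(as.raster(unclass(object)),
                               xmin = 0, xmax = d[2], ymin = 0, ymax = d[1]) +
    ggplot2::xlim(0, d[2]) + ggplot2::ylim(0, d[1]) +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::theme_void()
}

#' @method autoplot synthetic_skin_image
#' @export
autoplot.synthetic_skin_image <- function(object, ...) {
  autoplot(object$image, ...)
}

#' Compare Delta-SEV between treatment arms
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or any data frame
#'   with `arm` and `delta_sev` columns).
#' @return A ggplot boxplot of Delta-SEV by arm with patient points.
#' @export
plot_delta_sev <- function(cohort) {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$arm, y = .data$delta_sev,
                                       fill = .data$arm)) +
    ggplot2::geom_boxplot(alpha = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = "treatment arm", y = expression(Delta * "SEV")) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
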