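#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_hline facet_wrap labs scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a cross-section velocity series
#'
#' Mean streamwise velocity (cm s^-1) and wall displacement (% occlusion)
#' against time, one panel per slice, mirroring the standard presentation
#' of peristaltic-flow runs.
#'
#' @param object A [cross_section_series()] result (or several bound
#'   together with a `segment` column).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcm_series <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$time, y = 100 * .data$mean_vx)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line(colour = "#2166ac") +
    labs(x = "time (s)", y = "mean streamwise velocity (cm/s)") +
    theme_minimal()
  if ("segment" %in% names(object))
    p <- p + facet_wrap(~segment, labeller = ggplot2::label_both)
  p
}

#' Plot a bottom-wall shear-rate series
#'
#' @param object A [bottom_wall_shear_series()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shear_series <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("mean_shear", "max_shear"),
                              names_to = "metric", values_to = "shear")
  p <- ggplot(long, aes(x = .data$time, y = .data$shear,
                        colour = .data$metric)) +
    geom_line() +
    labs(x = "time (s)", y = "bottom-wall shear rate (1/s)", colour = NULL) +
    theme_minimal()
  if (!all(is.na(object$segment)))
    p <- p + facet_wrap(~segment, labeller = ggplot2::label_both)
  p
}

#' Plot a pixel grid (velocity or shear map)
#'
#' @param object A [rasterize_slice()] / [pixel_shear_map()] result.
#' @param field Column to map (`"vx"`, `"gamma_norm"`, ...).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pixel_grid <- function(object, field = "vx", ...) {
  d <- object[!object$masked, ]
  ggplot(d, aes(x = .data$y, y = .data$z, fill = .data[[field]])) +
    geom_tile(width = attr(object, "L"), height = attr(object, "L")) +
    scale_fill_viridis_c() +
    labs(x = "y (m)", y = "z (m)", fill = field,
         title = sprintf("slice at x = %.3f m", attr(object, "x_plane"))) +
    theme_minimal()
}

#' Main-effects plot
#'
#' Mean response at the low and high level of each factor, the standard
#' design-of-experiments visualisation.
#'
#' @param object A [main_effects()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.main_effects <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(unclass(object)),
                           c("low_mean", "high_mean"),
                           names_to = "level", values_to = "mean")
  d$level <- ifelse(d$level == "low_mean", "low", "high")
  d$level <- factor(d$level, levels = c("low", "high"))
  ggplot(d, aes(x = .data$level, y = .data$mean, group = .data$factor)) +
    geom_line() + geom_point() +
    facet_wrap(~factor, scales = "free_x") +
    labs(x = NULL, y = attr(object, "response")) +
    theme_minimal()
}
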