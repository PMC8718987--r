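# "fire" pseudocolor ramp used for intensity surfaces
fire_colors <- function() c("#000000", "#3A0088", "#C2185B", "#FF6F00",
                            "#FFD600", "#FFFFFF")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a membrane image as a fire-LUT heat map
#'
#' @param object A `membrane_image`.
#' @param ... Unused.
#' @return A ggplot. Rows increase downward, matching image orientation.
#' @export
autoplot.membrane_image <- function(object, ...) {
  df <- export_surface(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = fire_colors(), limits = c(0, 1),
                                  name = if (object$is_reductive_scale)
                                    "reductive\nintensity" else "luminance") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a calibration series with its fitted line, colored by level CV
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot of replicate densities vs. nominal concentration with
#'   the calibration line; points colored by their level's CV percent.
#' @export
autoplot.validation_report <- function(object, ...) {
  series <- object$model$lm$model
  lv <- object$levels
  series$cv_percent <- lv$cv_percent[match(series$nominal, lv$nominal)]
  ggplot2::ggplot(series, ggplot2::aes(x = .data$nominal,
                                       y = .data$integrated_density)) +
    ggplot2::geom_abline(slope = object$model$slope,
                         intercept = object$model$intercept,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cv_percent), size = 2) +
    ggplot2::scale_colour_gradientn(colours = c("#1A9850", "#FEE08B", "#D73027"),
                                    name = "CV %") +
    ggplot2::labs(x = "nominal concentration (mol/L)",
                  y = "integrated density (intensity · px)") +
    ggplot2::theme_minimal()
}

#' Plot bilateral sum/difference maps
#'
#' @param object A `bilateral_map`.
#' @param which `"diff"` (default) or `"sum"`.
#' @param ... Unused.
#' @return A ggplot heat map over the overlap region; x is the offset from
#'   the midline in px.
#' @export
autoplot.bilateral_map <- function(object, which = c("diff", "sum"), ...) {
  which <- match.arg(which)
  df <- export_surface(object, which = which)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "offset from midline (px)", y = "row") +
    ggplot2::theme_minimal()
  if (which == "diff") {
    p + ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                      high = "#B2182B",
                                      name = "ipsi − contra")
  } else {
    p + ggplot2::scale_fill_gradientn(colours = fire_colors(),
                                      name = "ipsi + contra")
  }
}

#' Plot paired dorsoventral line profiles
#'
#' @param profile Tibble from [line_profile()].
#' @return A ggplot of ipsilateral and contralateral intensity vs. row.
#' @export
plot_line_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, c("ipsi", "contra"),
                              names_to = "side", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$row, y = .data$intensity,
                                     colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "row (dorsoventral)", y = "reductive intensity") +
    ggplot2::theme_minimal()
}

#' Plot per-region intensity densities sorted by distance to the trauma site
#'
#' @param comparisons Tibble from [compare_regions()] or [rank_regions()].
#' @return A ggplot with one facet per region (ordered by distance), each
#'   showing the ipsilateral and contralateral kernel densities.
#' @export
plot_region_densities <- function(comparisons) {
  ranked <- if (is.null(attr(comparisons, "spearman_rho"))) {
    rank_regions(comparisons)
  } else comparisons
  df <- ranked |>
    dplyr::mutate(panel = sprintf("%s (%.0f px)", .data$name,
                                  .data$distance_px)) |>
    dplyr::select("panel", "density") |>
    tidyr::unnest("density") |>
    tidyr::pivot_longer(c("ipsi_density", "contra_density"),
                        names_to = "side", values_to = "density") |>
    dplyr::mutate(side = sub("_density", "", .data$side))
  df$panel <- factor(df$panel, levels = unique(df$panel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$density,
                                   colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "reductive intensity", y = "density") +
    ggplot2::theme_minimal()
}
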