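#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_col
#'   geom_hline geom_vline scale_fill_gradient2 scale_fill_viridis_c
#'   scale_y_log10 labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Plot a dose plane
#'
#' @param object A [dose_plane()].
#' @param ... Unused.
#' @return A ggplot raster of the dose with mm axes.
#' @exportS3Method ggplot2::autoplot
autoplot.dose_plane <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$x_mm, y = .data$y_mm, fill = .data$dose_cgy)) +
    geom_raster() +
    scale_fill_viridis_c(name = "dose\n[cGy(RBE)]") +
    coord_equal() +
    labs(title = object$label, x = "x [mm]", y = "y [mm]") +
    theme_minimal()
}

#' DDM heat map with optional gamma-failure overlay
#'
#' Signed per-pixel dose deviation on the measured grid, diverging palette
#' (direction and magnitude), axes in mm. When a gamma map is supplied,
#' pixels failing the binary gamma test (gamma > 1) are marked with an
#' asterisk so the two tests can be read side by side.
#'
#' @param map A `ddmqa_ddm`.
#' @param gamma_map Optional `ddmqa_gamma` on the same measured grid.
#' @param limit_pct Symmetric color limit, percent (default: data range).
#' @return A ggplot object.
#' @export
ddm_heatmap <- function(map, gamma_map = NULL, limit_pct = NULL) {
  stopifnot(inherits(map, "ddmqa_ddm"))
  df <- map$pixels[map$pixels$evaluated, ]
  lim <- limit_pct %||% max(abs(df$ddm_pct), 1e-6)
  p <- ggplot(df, aes(x = .data$x_mm, y = .data$y_mm)) +
    geom_raster(aes(fill = .data$ddm_pct)) +
    scale_fill_gradient2(name = expression(Delta * D[min] ~ "[%]"),
                         low = "#313695", mid = "white", high = "#a50026",
                         limits = c(-lim, lim)) +
    coord_equal() +
    labs(x = "x [mm]", y = "y [mm]",
         title = sprintf("DDM heat map (r = %.3g mm)", map$r_mm)) +
    theme_minimal()
  if (!is.null(gamma_map)) {
    stopifnot(inherits(gamma_map, "ddmqa_gamma"))
    if (!identical(gamma_map$dim, map$dim)) {
      abort_ddmqa("gamma map and DDM map have different shapes.",
                  "ddmqa_comparison_error")
    }
    fails <- gamma_map$pixels[gamma_map$pixels$evaluated &
                                !is.na(gamma_map$pixels$gamma) &
                                gamma_map$pixels$gamma > 1, ]
    if (nrow(fails)) {
      p <- p + geom_point(data = fails, shape = 8, size = 2, stroke = 0.8)
    }
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.ddmqa_ddm <- function(object, gamma_map = NULL, ...) {
  ddm_heatmap(object, gamma_map = gamma_map)
}

#' Plot a gamma map
#'
#' @param object A `ddmqa_gamma`.
#' @param ... Unused.
#' @return A ggplot raster of per-pixel gamma.
#' @exportS3Method ggplot2::autoplot
autoplot.ddmqa_gamma <- function(object, ...) {
  df <- object$pixels[object$pixels$evaluated, ]
  ggplot(df, aes(x = .data$x_mm, y = .data$y_mm, fill = .data$gamma)) +
    geom_raster() +
    scale_fill_viridis_c(name = expression(gamma)) +
    coord_equal() +
    labs(x = "x [mm]", y = "y [mm]",
         title = sprintf("gamma map (%.3g%%/%.3g mm)",
                         object$criteria$dose_pct,
                         object$criteria$distance_mm)) +
    theme_minimal()
}

#' Plot a DDM dose-deviation histogram
#'
#' Logarithmic count axis (so single failing pixels stay visible against
#' the mass of agreeing ones), red tolerance lines at plus/minus the
#' tolerance, and dashed horizontal guides at 1% and 10% of the evaluated
#' pixel count. Mu and sigma are reported in the subtitle.
#'
#' @param object A `ddmqa_histogram`.
#' @param ... Unused.
#' @return A ggplot object (y axis log10; flagged in the plot's label
#'   metadata).
#' @exportS3Method ggplot2::autoplot
autoplot.ddmqa_histogram <- function(object, ...) {
  bins <- object$bins[object$bins$count > 0, ]
  tol <- object$tolerance_pct
  p <- ggplot(bins, aes(x = .data$bin_center, y = .data$count)) +
    geom_col(width = object$bin_width_pct, fill = "#4d9221") +
    geom_vline(xintercept = c(-tol, tol), color = "red") +
    geom_hline(yintercept = c(0.01, 0.10) * object$n, linetype = "dashed",
               color = "grey40") +
    scale_y_log10() +
    labs(x = "dose deviation [% of max dose]", y = "pixels (log)",
         title = "DDM dose-deviation histogram",
         subtitle = sprintf("mu = %+.2f%%, sigma = %.2f%%, n = %d",
                            object$mu,
                            if (is.na(object$sigma)) 0 else object$sigma,
                            object$n)) +
    theme_minimal()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.ddmqa_deviation_histogram <- function(object, ...) {
  ggplot(object, aes(x = .data$bin_center, y = .data$density)) +
    geom_col(width = object$bin_high[1] - object$bin_low[1],
             fill = "#2166ac") +
    labs(x = "radial deviation [mm]", y = "probability density [1/mm]",
         title = "Probability-weighted beamlet radial deviations") +
    theme_minimal()
}

#' Composite comparison figure
#'
#' The standard two-row QA report layout: measured and calculated planes on
#' top; DDM heat map with gamma-failure asterisks and the log-scale
#' deviation histogram below. Requires the patchwork package.
#'
#' @param report A `ddmqa_comparison`.
#' @param measured,calculated The input [dose_plane()]s (for the top row).
#' @return A patchwork object.
#' @export
plot_comparison <- function(report, measured, calculated) {
  stopifnot(inherits(report, "ddmqa_comparison"))
  if (!requireNamespace("patchwork", quietly = TRUE)) {
    abort_ddmqa("plot_comparison() needs the patchwork package.",
                "ddmqa_config_error")
  }
  top <- patchwork::wrap_plots(autoplot(measured), autoplot(calculated))
  bottom <- patchwork::wrap_plots(
    ddm_heatmap(report$ddm, report$gamma),
    autoplot(report$histogram)
  )
  top / bottom
}

#' @importFrom rlang .data
NULL
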