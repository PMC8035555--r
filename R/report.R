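#' Full measured-vs-calculated plane comparison
#'
#' The end-to-end QA pipeline: (optional) two-stage registration of the
#' measured plane to the calculation, resampling of the calculated plane to
#' the fine search grid, the instrumented gamma test, the DDM analysis, the
#' dose-deviation histogram and both pass rates, bundled into a single
#' deterministic report.
#'
#' @inheritParams compute_gamma
#' @param register Run [register_planes()] and apply the recovered shift to
#'   the measured plane before comparing (default `TRUE`).
#' @param ddm_tolerance_pct DDM pass tolerance, percent (default
#'   `criteria$dose_pct`).
#' @param histogram_bin_pct Histogram bin width, percent (default 0.5).
#' @param mask_pct Coarse-registration mask, percent of maximum (default 20).
#' @return A `ddmqa_comparison` object bundling `registration`, `gamma`,
#'   `ddm`, `histogram`, `criteria` and the headline rates. [glance()] gives
#'   the one-row summary; [report_json()] serializes it.
#' @examples
#' pair <- synth_pair("region-error", magnitude_pct = 5, field_size_mm = 60)
#' cmp <- compare_planes(pair$measured, pair$calculated,
#'                       criteria(), search_spacing_mm = 0.5,
#'                       register = FALSE)
#' glance(cmp)
#' @export
compare_planes <- function(measured, calculated, criteria = ddmqa::criteria(),
                           register = TRUE, search_spacing_mm = 0.1,
                           normalize_to = c("calculated", "measured"),
                           ddm_tolerance_pct = criteria$dose_pct,
                           histogram_bin_pct = 0.5, mask_pct = 20) {
  stopifnot(inherits(measured, "dose_plane"), inherits(calculated, "dose_plane"))
  normalize_to <- match.arg(normalize_to)
  reg <- NULL
  aligned <- measured
  if (register) {
    reg <- register_planes(measured, calculated, mask_pct = mask_pct)
    aligned <- apply_shift(measured, reg)
  }
  fine <- prepare_search_plane(calculated, search_spacing_mm)
  gm <- compute_gamma(aligned, fine, criteria,
                      search_spacing_mm = search_spacing_mm,
                      normalize_to = normalize_to)
  dm <- compute_ddm(aligned, fine, criteria,
                    search_spacing_mm = search_spacing_mm,
                    normalize_to = normalize_to)
  hist <- ddm_histogram(dm, bin_width_pct = histogram_bin_pct,
                        tolerance_pct = ddm_tolerance_pct)
  structure(
    list(
      registration = reg,
      gamma = gm,
      ddm = dm,
      histogram = hist,
      criteria = criteria,
      gamma_pass_rate = gamma_pass_rate(gm),
      ddm_pass_rate = ddm_pass_rate(dm, tolerance_pct = ddm_tolerance_pct),
      ddm_tolerance_pct = ddm_tolerance_pct,
      tool_version = as.character(utils::packageVersion("ddmqa"))
    ),
    class = "ddmqa_comparison"
  )
}

#' @export
print.ddmqa_comparison <- function(x, ...) {
  cat("<plane comparison>\n")
  if (!is.null(x$registration)) print(x$registration)
  gs <- gamma_summary(x$gamma)
  cat(sprintf(
    "  gamma %.3g%%/%.3gmm: pass %.2f%% | max %.2f | %%>1.5: %.2f\n",
    x$criteria$dose_pct, x$criteria$distance_mm, x$gamma_pass_rate,
    gs$max_gamma, gs$pct_above_1p5
  ))
  cat(sprintf(
    "  DDM   %.3g%%/%.3gmm: pass %.2f%% | mu %+.2f%% | sigma %.2f%%\n",
    x$ddm_tolerance_pct, x$criteria$search_radius_mm, x$ddm_pass_rate,
    x$histogram$mu, if (is.na(x$histogram$sigma)) 0 else x$histogram$sigma
  ))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' A stable, human-readable schema: criteria, registration shifts, gamma
#' pass rate and supplementary metrics, DDM pass rate, histogram mu/sigma
#' and bins, and the optional mean-offset flag (`mu_within_1pct`) some
#' clinics attach to the DDM pass decision.
#'
#' @param report A `ddmqa_comparison`.
#' @param path Optional output path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ddmqa_comparison"))
  gs <- gamma_summary(report$gamma)
  obj <- list(
    tool = list(name = "ddmqa", version = report$tool_version),
    criteria = unclass(report$criteria),
    registration = if (!is.null(report$registration)) {
      r <- report$registration
      list(shift_mm = as.list(r$shift_mm),
           coarse_shift_mm = as.list(r$coarse_shift_mm),
           residual = r$residual, converged = r$converged,
           within_setup_tolerance = r$within_setup_tolerance)
    },
    gamma = list(pass_rate_pct = report$gamma_pass_rate,
                 max_gamma = gs$max_gamma,
                 pct_above_1p5 = gs$pct_above_1p5,
                 mean_gamma = gs$mean_gamma,
                 n_evaluated = gs$n_evaluated,
                 max_dose_cgy = report$gamma$max_dose),
    ddm = list(pass_rate_pct = report$ddm_pass_rate,
               tolerance_pct = report$ddm_tolerance_pct,
               r_mm = report$ddm$r_mm,
               mu_pct = report$histogram$mu,
               sigma_pct = report$histogram$sigma,
               mu_within_1pct = abs(report$histogram$mu) < 1,
               n_evaluated = report$histogram$n),
    histogram = list(bin_width_pct = report$histogram$bin_width_pct,
                     bin_center = report$histogram$bins$bin_center,
                     count = report$histogram$bins$count)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Per-pixel comparison table
#'
#' Joins the gamma and DDM per-pixel results on the measured grid.
#'
#' @param report A `ddmqa_comparison`.
#' @return Tibble with one row per measured pixel: positions, measured dose,
#'   gamma (+ its minimizer provenance), DDM value and masks.
#' @export
pixel_table <- function(report) {
  stopifnot(inherits(report, "ddmqa_comparison"))
  g <- report$gamma$pixels
  d <- report$ddm$pixels
  out <- g[c("row", "col", "y_mm", "x_mm", "measured_cgy", "evaluated",
             "gamma", "argmin_distance_mm", "argmin_dose_diff_pct")]
  names(out)[names(out) == "argmin_distance_mm"] <- "gamma_argmin_distance_mm"
  names(out)[names(out) == "argmin_dose_diff_pct"] <- "gamma_argmin_dose_diff_pct"
  out$ddm_pct <- d$ddm_pct
  out$ddm_argmin_distance_mm <- d$argmin_distance_mm
  out$ddm_truncated <- d$truncated
  out
}

#' Run the comparison pipeline on files
#'
#' Reads the measured and calculated planes, runs [compare_planes()], and
#' optionally writes the JSON report, the per-pixel CSV and the composite
#' figure.
#'
#' @param measured_path,calc_path Input dose-plane files (grid-csv or DICOM
#'   RT Dose).
#' @param criteria A [criteria()] object.
#' @param out_json,out_csv Optional output paths.
#' @param figs_dir Optional directory for figure output (PDF).
#' @param ... Passed to [compare_planes()].
#' @return The `ddmqa_comparison`, invisibly.
#' @export
run_compare <- function(measured_path, calc_path, criteria = ddmqa::criteria(),
                        out_json = NULL, out_csv = NULL, figs_dir = NULL, ...) {
  measured <- read_dose_plane(measured_path)
  calculated <- read_dose_plane(calc_path)
  report <- compare_planes(measured, calculated, criteria, ...)
  if (!is.null(out_json)) report_json(report, out_json)
  if (!is.null(out_csv)) {
    utils::write.csv(pixel_table(report), out_csv, row.names = FALSE)
  }
  if (!is.null(figs_dir)) {
    dir.create(figs_dir, showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(file.path(figs_dir, "heatmap.pdf"),
                    ddm_heatmap(report$ddm, report$gamma),
                    width = 7, height = 6)
    ggplot2::ggsave(file.path(figs_dir, "histogram.pdf"),
                    ggplot2::autoplot(report$histogram),
                    width = 7, height = 5)
  }
  invisible(report)
}
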