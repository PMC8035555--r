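#' Comparison tolerances for planar dose QA
#'
#' Bundles the tolerances shared by the gamma and DDM comparisons. Clinic
#' defaults follow common PSQA practice: 3% dose, 2 mm gamma DTA, 1 mm DDM
#' search radius, 10% low-dose cutoff, global normalization.
#'
#' @param dose_pct Dose-difference tolerance, percent of the global maximum
#'   dose (the gamma dose criterion and the DDM pass tolerance).
#' @param distance_mm Gamma distance-to-agreement criterion, mm.
#' @param search_radius_mm DDM fixed search radius `r`, mm. Derived per
#'   clinic from beamlet spatial accuracy (see
#'   [recommend_search_radius()]).
#' @param low_dose_cutoff_pct Measured pixels at or below this percentage of
#'   the maximum dose are excluded from scoring.
#' @param normalization `"global"` (percentages of the plane maximum) or
#'   `"local"` (of the measured pixel's own dose).
#' @return A `ddmqa_criteria` list.
#' @examples
#' criteria()               # 3% / 2 mm gamma, 1 mm DDM radius
#' criteria(distance_mm = 1)
#' @export
criteria <- function(dose_pct = 3, distance_mm = 2, search_radius_mm = 1,
                     low_dose_cutoff_pct = 10,
                     normalization = c("global", "local")) {
  normalization <- match.arg(normalization)
  for (v in list(dose_pct, distance_mm, search_radius_mm, low_dose_cutoff_pct)) {
    if (!is_number(v) || v <= 0) {
      abort_ddmqa("all criteria must be strictly positive numbers.",
                  "ddmqa_config_error")
    }
  }
  if (low_dose_cutoff_pct >= 100) {
    abort_ddmqa("`low_dose_cutoff_pct` must lie in (0, 100).",
                "ddmqa_config_error")
  }
  structure(
    list(dose_pct = dose_pct, distance_mm = distance_mm,
         search_radius_mm = search_radius_mm,
         low_dose_cutoff_pct = low_dose_cutoff_pct,
         normalization = normalization),
    class = "ddmqa_criteria"
  )
}

#' @export
print.ddmqa_criteria <- function(x, ...) {
  cat(sprintf(
    "<criteria> %.3g%% dose / %.3g mm DTA (gamma), r = %.3g mm (DDM), cutoff %.3g%%, %s normalization\n",
    x$dose_pct, x$distance_mm, x$search_radius_mm, x$low_dose_cutoff_pct,
    x$normalization
  ))
  invisible(x)
}
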