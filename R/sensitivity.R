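#' Acceptance-region geometry: gamma ellipse vs DDM rectangle
#'
#' In the dose (% of maximum) vs distance (mm) plane, the gamma test's
#' passing region is one quadrant of an ellipse with semiaxes
#' (`dose_pct`, `dta_mm`): the dose tolerance shrinks as the distance to
#' agreement grows. The DDM passing region is a rectangle `dose_pct` by
#' `r_mm`: the dose tolerance is invariant across the whole search radius.
#' The area under each acceptance boundary (AUC) quantifies how much
#' combined variation each test lets through; at equal distance limits the
#' quadrant covers only pi/4 of the rectangle, which is why a 1 mm gamma DTA
#' is too dose-restrictive to be clinically workable while a 1 mm DDM radius
#' is not.
#'
#' @param dose_pct Dose semiaxis / rectangle height, percent of maximum dose.
#' @param dta_mm Gamma DTA semiaxis, mm.
#' @param r_mm DDM search radius (rectangle width), mm.
#' @return Area in percent times mm.
#' @examples
#' ellipse_quadrant_auc(3, 2)  # 4.71
#' ellipse_quadrant_auc(3, 1)  # 2.36
#' rectangle_auc(3, 1)         # 3.0
#' @export
ellipse_quadrant_auc <- function(dose_pct, dta_mm) {
  if (!is_number(dose_pct) || !is_number(dta_mm) || dose_pct <= 0 || dta_mm <= 0) {
    abort_ddmqa("semiaxes must be positive.", "ddmqa_config_error")
  }
  pi * dose_pct * dta_mm / 4
}

#' @rdname ellipse_quadrant_auc
#' @export
rectangle_auc <- function(dose_pct, r_mm) {
  if (!is_number(dose_pct) || !is_number(r_mm) || dose_pct <= 0 || r_mm <= 0) {
    abort_ddmqa("rectangle sides must be positive.", "ddmqa_config_error")
  }
  dose_pct * r_mm
}

#' Coverage of the machine-relevant region by a gamma ellipse
#'
#' The machine-relevant region is formalized as the rectangle of deviations
#' the delivery system can actually produce (|dose difference| within the
#' tolerance, distance within the empirically achievable radius), with
#' uniform area measure. This returns the fraction of that rectangle covered
#' by the gamma quadrant with semiaxes `ellipse = c(dose_pct, dta_mm)` — a
#' closed-form elliptic-segment integral, no sampling.
#'
#' @param ellipse Gamma semiaxes `c(dose_pct, dta_mm)`.
#' @param relevant Machine-relevant rectangle `c(dose_pct, r_mm)`.
#' @return Fraction in (0, 1].
#' @examples
#' relevant_coverage(c(3, 1), c(3, 1))  # pi/4: under 80% of relevant points
#' @export
relevant_coverage <- function(ellipse, relevant) {
  ellipse <- as.numeric(ellipse)
  relevant <- as.numeric(relevant)
  if (length(ellipse) != 2L || length(relevant) != 2L ||
      any(!is.finite(c(relevant))) || any(relevant <= 0) ||
      any(ellipse <= 0)) {
    abort_ddmqa("`ellipse` and `relevant` must be positive pairs.",
                "ddmqa_config_error")
  }
  a <- ellipse[1]   # dose semiaxis
  d <- ellipse[2]   # distance semiaxis (may be Inf for the limiting case)
  h <- relevant[1]  # rectangle dose height
  r <- relevant[2]  # rectangle distance width
  if (!is.finite(d)) {
    return(min(a, h) * r / (h * r))
  }
  X <- min(r, d)
  # ellipse height a*sqrt(1-(x/d)^2) exceeds h for x < xc
  xc <- if (h >= a) 0 else d * sqrt(1 - (h / a)^2)
  x0 <- min(xc, X)
  F <- function(u) (u * sqrt(pmax(0, 1 - u^2)) + asin(pmin(1, pmax(-1, u)))) / 2
  area <- h * x0 + a * d * (F(X / d) - F(x0 / d))
  area / (h * r)
}

#' Table of acceptance-region areas and coverages
#'
#' Convenience summary comparing gamma criteria with a DDM radius.
#'
#' @param dose_pct Dose tolerance, percent.
#' @param dta_mm Gamma DTA criteria to tabulate, mm (vector).
#' @param r_mm DDM search radius, mm.
#' @return Tibble with one row per region: `test`, `dose_pct`,
#'   `distance_mm`, `auc`, `coverage_of_relevant`.
#' @export
auc_table <- function(dose_pct = 3, dta_mm = c(1, 2), r_mm = 1) {
  gamma_rows <- purrr::map_dfr(dta_mm, function(d) {
    tibble::tibble(
      test = sprintf("gamma %g%%/%gmm", dose_pct, d),
      dose_pct = dose_pct, distance_mm = d,
      auc = ellipse_quadrant_auc(dose_pct, d),
      coverage_of_relevant = relevant_coverage(c(dose_pct, d),
                                               c(dose_pct, r_mm))
    )
  })
  ddm_row <- tibble::tibble(
    test = sprintf("DDM %g%%/%gmm", dose_pct, r_mm),
    dose_pct = dose_pct, distance_mm = r_mm,
    auc = rectangle_auc(dose_pct, r_mm),
    coverage_of_relevant = 1
  )
  dplyr::bind_rows(gamma_rows, ddm_row)
}
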