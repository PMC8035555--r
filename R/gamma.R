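#' Gamma-index comparison of measured vs calculated dose planes
#'
#' The classical gamma index: for each measured pixel above the low-dose
#' cutoff, the minimum over calculated test points within `max_search_mm` of
#' \deqn{\gamma = \min_n \sqrt{(\Delta dist_n/\Delta d_M)^2 +
#'   (\delta_n/\Delta D_M)^2}}
#' where \eqn{\delta_n} is the signed dose difference
#' (measured - calculated test point) in percent of the normalization dose.
#' The engine is instrumented: the distance and signed dose difference of the
#' minimizing test point are recorded per pixel, so the user can see whether
#' a pixel passed on dose, on distance, or at a distance beyond the machine's
#' achievable spot accuracy (a likely false positive).
#'
#' @param measured Measured [dose_plane()] (coarse detector grid; its pixels
#'   are never interpolated).
#' @param calculated Calculated (TPS) [dose_plane()]; resampled internally
#'   onto the fine search grid when coarser than `search_spacing_mm`.
#' @param criteria A [criteria()] object.
#' @param max_search_mm Cap on the gamma search radius. A gamma search may
#'   range beyond the DTA when no nearby point agrees; the default `3 *
#'   distance_mm` bounds the runtime while leaving the reported index exact
#'   for every gamma below 3.
#' @param search_spacing_mm Pitch of the fine search grid, mm (default
#'   0.1 mm, at least 10x finer than typical criteria so disk discretization
#'   is negligible).
#' @param normalize_to `"calculated"` (default; the noise-free plane) or
#'   `"measured"`: which plane's global maximum normalizes dose differences
#'   under global normalization.
#' @return A `ddmqa_gamma` object: a per-pixel tibble (`gamma`,
#'   `argmin_distance_mm`, `argmin_dose_diff_pct`, `evaluated`, positions)
#'   plus the normalization dose and settings. Use [tidy()][generics::tidy],
#'   [glance()][generics::glance], [gamma_pass_rate()], [gamma_summary()]
#'   and [autoplot()][ggplot2::autoplot].
#' @examples
#' calc <- dose_plane(matrix(200, 41, 41), spacing = 2.5)
#' meas <- dose_plane(matrix(200, 11, 11), spacing = 7.62)
#' g <- compute_gamma(meas, calc, criteria(), search_spacing_mm = 0.5)
#' gamma_pass_rate(g)
#' @export
compute_gamma <- function(measured, calculated, criteria = ddmqa::criteria(),
                          max_search_mm = 3 * criteria$distance_mm,
                          search_spacing_mm = 0.1,
                          normalize_to = c("calculated", "measured")) {
  stopifnot(inherits(measured, "dose_plane"), inherits(calculated, "dose_plane"),
            inherits(criteria, "ddmqa_criteria"))
  normalize_to <- match.arg(normalize_to)
  if (!is_number(max_search_mm) || max_search_mm < criteria$distance_mm) {
    abort_ddmqa("`max_search_mm` must be >= the DTA criterion.",
                "ddmqa_config_error")
  }
  fine <- prepare_search_plane(calculated, search_spacing_mm)
  M <- normalization_dose(measured, fine, normalize_to)
  if (M <= 0) abort_ddmqa("normalization dose is zero.", "ddmqa_comparison_error")

  scan <- scan_plane(
    measured, fine, radius = max_search_mm,
    cutoff_pct = criteria$low_dose_cutoff_pct, max_dose = M,
    fun = function(m, d2, cvals) {
      delta <- signed_delta_pct(m, cvals, M, criteria$normalization)
      dist <- sqrt(d2)
      gam <- sqrt((dist / criteria$distance_mm)^2 +
                    (delta / criteria$dose_pct)^2)
      k <- order(gam, d2, abs(delta))[1L]
      c(gam[k], dist[k], delta[k])
    },
    n_out = 3L
  )

  px <- scan$pixels
  names(px)[names(px) == "v1"] <- "gamma"
  names(px)[names(px) == "v2"] <- "argmin_distance_mm"
  names(px)[names(px) == "v3"] <- "argmin_dose_diff_pct"
  structure(
    list(pixels = px, max_dose = M, criteria = criteria,
         max_search_mm = max_search_mm, normalize_to = normalize_to,
         spacing = measured$spacing, origin = measured$origin,
         dim = dim(measured$values)),
    class = "ddmqa_gamma"
  )
}

#' Gamma pass rate
#'
#' Percentage of evaluated pixels passing the gamma test. The boundary
#' gamma = 1 passes under the default inclusive convention.
#'
#' @param map A `ddmqa_gamma` from [compute_gamma()].
#' @param boundary `"inclusive"` (gamma <= 1 passes, default) or
#'   `"strict"` (gamma < 1).
#' @return Pass rate, percent.
#' @export
gamma_pass_rate <- function(map, boundary = c("inclusive", "strict")) {
  stopifnot(inherits(map, "ddmqa_gamma"))
  boundary <- match.arg(boundary)
  g <- map$pixels$gamma[map$pixels$evaluated]
  if (!length(g)) abort_ddmqa("no evaluated pixels.", "ddmqa_comparison_error")
  pass <- if (boundary == "inclusive") g <= 1 else g < 1
  100 * mean(pass)
}

#' Supplementary gamma metrics
#'
#' The additional per-plane metrics recommended alongside the pass rate for
#' catching extreme deviations: the maximum gamma, the percentage of gamma
#' values above 1.5, and the mean gamma.
#'
#' @param map A `ddmqa_gamma`.
#' @return One-row tibble: `max_gamma`, `pct_above_1p5`, `mean_gamma`,
#'   `n_evaluated`.
#' @export
gamma_summary <- function(map) {
  stopifnot(inherits(map, "ddmqa_gamma"))
  g <- map$pixels$gamma[map$pixels$evaluated]
  if (!length(g)) abort_ddmqa("no evaluated pixels.", "ddmqa_comparison_error")
  tibble::tibble(
    max_gamma = max(g),
    pct_above_1p5 = 100 * mean(g > 1.5),
    mean_gamma = mean(g),
    n_evaluated = length(g)
  )
}

#' @export
print.ddmqa_gamma <- function(x, ...) {
  s <- gamma_summary(x)
  cat(sprintf(
    "<gamma map> %d x %d pixels, %d evaluated | %.3g%%/%.3g mm | pass %.2f%% | max gamma %.2f | %%>1.5: %.2f\n",
    x$dim[1], x$dim[2], s$n_evaluated, x$criteria$dose_pct,
    x$criteria$distance_mm, gamma_pass_rate(x), s$max_gamma, s$pct_above_1p5
  ))
  invisible(x)
}

# Generic disk scan over evaluated measured pixels. `fun(m, d2, cvals)`
# returns `n_out` numbers per pixel; pixels with no candidate nodes stay NA
# and are dropped from the evaluation mask.
scan_plane <- function(measured, fine, radius, cutoff_pct, max_dose, fun,
                       n_out) {
  yf <- plane_rows_mm(fine)
  xf <- plane_cols_mm(fine)
  ym_all <- plane_rows_mm(measured)
  xm_all <- plane_cols_mm(measured)
  eval_mask <- evaluated_mask(measured, max_dose, cutoff_pct)
  nr <- nrow(measured$values)
  nc <- ncol(measured$values)
  out <- matrix(NA_real_, nr * nc, n_out)
  truncated <- matrix(FALSE, nr, nc)
  any_candidates <- FALSE
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!eval_mask[i, j]) next
      cand <- pixel_candidates(fine$values, yf, xf, ym_all[i], xm_all[j], radius)
      if (is.null(cand)) {
        eval_mask[i, j] <- FALSE
        next
      }
      any_candidates <- TRUE
      truncated[i, j] <- disk_truncated(yf, xf, ym_all[i], xm_all[j], radius)
      out[i + (j - 1L) * nr, ] <- fun(measured$values[i, j], cand$d2, cand$vals)
    }
  }
  if (!any_candidates && any(measured$values > (cutoff_pct / 100) * max_dose)) {
    abort_ddmqa("measured and calculated grids do not overlap within the search radius.",
                "ddmqa_comparison_error")
  }
  px <- tibble::tibble(
    row = rep(seq_len(nr) - 1L, times = nc),
    col = rep(seq_len(nc) - 1L, each = nr),
    y_mm = rep(ym_all, times = nc),
    x_mm = rep(xm_all, each = nr),
    measured_cgy = as.vector(measured$values),
    evaluated = as.vector(eval_mask),
    truncated = as.vector(truncated)
  )
  for (k in seq_len(n_out)) px[[paste0("v", k)]] <- out[, k]
  list(pixels = px)
}
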