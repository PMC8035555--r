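#' Dose-difference minimum (DDM) within a fixed search radius
#'
#' The DDM metric: for each measured pixel above the low-dose cutoff, search
#' every calculated test point within the closed disk of radius `r`
#' (`criteria$search_radius_mm`) and report the signed dose deviation
#' \deqn{DDM = \min_n |100 (D^{meas} - D^{calc}_n) / MaxDose|}
#' of the point with the smallest deviation magnitude — the best dose
#' agreement within a statistically probable search distance, per pixel.
#' Unlike the gamma test, the dose tolerance is invariant across the whole
#' disk and the search never leaves it, and the signed value carries both
#' magnitude and direction of the deviation forward to the user.
#'
#' Ties in deviation magnitude are broken toward the smaller distance, then
#' the positive sign, so the argmin is deterministic. Pixels whose disk
#' extends beyond the calculated grid use the available test points and are
#' flagged in `truncated`.
#'
#' @inheritParams compute_gamma
#' @return A `ddmqa_ddm` object with a per-pixel tibble (`ddm_pct` signed,
#'   in percent of the normalization dose; `argmin_distance_mm`;
#'   `evaluated`; `truncated`), the search radius and normalization dose.
#'   Use [ddm_pass_rate()], [ddm_histogram()], [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [autoplot()][ggplot2::autoplot].
#' @examples
#' calc <- dose_plane(matrix(200, 41, 41), spacing = 2.5)
#' meas <- dose_plane(matrix(204, 11, 11), spacing = 7.62)  # +2% of max
#' d <- compute_ddm(meas, calc, criteria(), search_spacing_mm = 0.5)
#' ddm_pass_rate(d)
#' @export
compute_ddm <- function(measured, calculated, criteria = ddmqa::criteria(),
                        search_spacing_mm = 0.1,
                        normalize_to = c("calculated", "measured")) {
  stopifnot(inherits(measured, "dose_plane"), inherits(calculated, "dose_plane"),
            inherits(criteria, "ddmqa_criteria"))
  normalize_to <- match.arg(normalize_to)
  fine <- prepare_search_plane(calculated, search_spacing_mm)
  r <- criteria$search_radius_mm
  if (r < max(fine$spacing) - 1e-12) {
    abort_ddmqa("search radius r is smaller than the search-grid spacing.",
                "ddmqa_config_error")
  }
  M <- normalization_dose(measured, fine, normalize_to)
  if (M <= 0) abort_ddmqa("normalization dose is zero.", "ddmqa_comparison_error")

  scan <- scan_plane(
    measured, fine, radius = r,
    cutoff_pct = criteria$low_dose_cutoff_pct, max_dose = M,
    fun = function(m, d2, cvals) {
      delta <- signed_delta_pct(m, cvals, M, criteria$normalization)
      k <- order(abs(delta), d2, -sign(delta))[1L]
      c(delta[k], sqrt(d2[k]))
    },
    n_out = 2L
  )
  px <- scan$pixels
  names(px)[names(px) == "v1"] <- "ddm_pct"
  names(px)[names(px) == "v2"] <- "argmin_distance_mm"
  structure(
    list(pixels = px, r_mm = r, max_dose = M, criteria = criteria,
         normalize_to = normalize_to, spacing = measured$spacing,
         origin = measured$origin, dim = dim(measured$values)),
    class = "ddmqa_ddm"
  )
}

#' DDM pass rate
#'
#' Percentage of evaluated pixels whose deviation magnitude is within the
#' dose tolerance. The comparison is strict (`|DDM| < tolerance`) by
#' default; the boundary convention is switchable.
#'
#' @param map A `ddmqa_ddm` from [compute_ddm()].
#' @param tolerance_pct Dose tolerance, percent (default 3).
#' @param boundary `"strict"` (default, `< tolerance`) or `"inclusive"`
#'   (`<= tolerance`).
#' @return Pass rate, percent.
#' @export
ddm_pass_rate <- function(map, tolerance_pct = 3,
                          boundary = c("strict", "inclusive")) {
  stopifnot(inherits(map, "ddmqa_ddm"))
  boundary <- match.arg(boundary)
  if (!is_number(tolerance_pct) || tolerance_pct <= 0) {
    abort_ddmqa("`tolerance_pct` must be positive.", "ddmqa_config_error")
  }
  v <- map$pixels$ddm_pct[map$pixels$evaluated]
  if (!length(v)) abort_ddmqa("no evaluated pixels.", "ddmqa_comparison_error")
  pass <- if (boundary == "strict") abs(v) < tolerance_pct else abs(v) <= tolerance_pct
  100 * mean(pass)
}

#' Dose-deviation histogram of a DDM map
#'
#' Aggregates the per-pixel signed deviations into bins and reports the
#' Average Dose Offset (mu) and Standard Deviation (sigma) of the evaluated
#' pixels. Bins are centered so that a zero deviation falls at the center of
#' a bin. The companion [autoplot()][ggplot2::autoplot] renders the
#' histogram with a logarithmic count axis, red tolerance lines at plus and
#' minus the tolerance, and dashed guides at 1% and 10% of the evaluated
#' pixel count.
#'
#' @param map A `ddmqa_ddm`.
#' @param bin_width_pct Bin width, percent of maximum dose (default 0.5).
#' @param tolerance_pct Tolerance marked on the rendered histogram
#'   (default 3).
#' @return A `ddmqa_histogram`: tibble of bins (`bin_low`, `bin_high`,
#'   `bin_center`, `count`) with attributes `mu`, `sigma`, `n`,
#'   `tolerance_pct`.
#' @export
ddm_histogram <- function(map, bin_width_pct = 0.5, tolerance_pct = 3) {
  stopifnot(inherits(map, "ddmqa_ddm"))
  if (!is_number(bin_width_pct) || bin_width_pct <= 0) {
    abort_ddmqa("`bin_width_pct` must be positive.", "ddmqa_config_error")
  }
  v <- map$pixels$ddm_pct[map$pixels$evaluated]
  if (!length(v)) abort_ddmqa("no evaluated pixels.", "ddmqa_comparison_error")
  h <- bin_width_pct
  # zero-centred bins: bin k covers [(k - 1/2) h, (k + 1/2) h)
  k <- floor(v / h + 0.5)
  kr <- seq(min(k), max(k))
  counts <- vapply(kr, function(kk) sum(k == kk), integer(1))
  bins <- tibble::tibble(
    bin_center = kr * h,
    bin_low = (kr - 0.5) * h,
    bin_high = (kr + 0.5) * h,
    count = counts
  )
  structure(
    list(bins = bins, mu = mean(v), sigma = stats::sd(v), n = length(v),
         bin_width_pct = h, tolerance_pct = tolerance_pct),
    class = "ddmqa_histogram"
  )
}

#' @export
print.ddmqa_histogram <- function(x, ...) {
  cat(sprintf(
    "<DDM histogram> n = %d evaluated pixels, mu = %+.2f%%, sigma = %.2f%%, bin width %.2g%%\n",
    x$n, x$mu, if (is.na(x$sigma)) 0 else x$sigma, x$bin_width_pct
  ))
  invisible(x)
}

#' @export
print.ddmqa_ddm <- function(x, ...) {
  v <- x$pixels$ddm_pct[x$pixels$evaluated]
  cat(sprintf(
    "<DDM map> %d x %d pixels, %d evaluated | r = %.3g mm | pass(<3%%) %.2f%% | mu %+.2f%%\n",
    x$dim[1], x$dim[2], length(v), x$r_mm, ddm_pass_rate(x), mean(v)
  ))
  invisible(x)
}

#' Signed DDM deviations as a matrix aligned to the measured grid
#'
#' @param map A `ddmqa_ddm` or `ddmqa_gamma`.
#' @return Matrix with the measured plane's dimensions (`NA` where not
#'   evaluated): `ddm_pct` for DDM maps, `gamma` for gamma maps.
#' @export
as_matrix <- function(map) {
  col <- if (inherits(map, "ddmqa_ddm")) {
    "ddm_pct"
  } else if (inherits(map, "ddmqa_gamma")) {
    "gamma"
  } else {
    abort_ddmqa("`map` must be a ddmqa_ddm or ddmqa_gamma.", "ddmqa_config_error")
  }
  v <- map$pixels[[col]]
  v[!map$pixels$evaluated] <- NA_real_
  matrix(v, nrow = map$dim[1], ncol = map$dim[2])
}
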