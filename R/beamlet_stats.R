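#' Validate a set of beamlet radial deviations
#'
#' Per-spot radial deviations of delivered pencil-beam positions from the
#' x-ray isocenter, with clinical-use frequency weights (e.g. from delivery
#' logs). These measurements drive the empirical choice of the DDM search
#' radius.
#'
#' @param data Data frame with columns `radial_deviation_mm` (>= 0) and
#'   optionally `weight` (>= 0, at least one positive; defaults to uniform).
#' @return A tibble with both columns, validated.
#' @export
beamlet_deviations <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"radial_deviation_mm" %in% names(data)) {
    abort_ddmqa("`data` needs a `radial_deviation_mm` column.",
                "ddmqa_format_error")
  }
  if (!"weight" %in% names(data)) data$weight <- 1
  x <- data$radial_deviation_mm
  w <- data$weight
  if (!nrow(data) || any(!is.finite(x)) || any(x < 0)) {
    abort_ddmqa("radial deviations must be finite and >= 0.",
                "ddmqa_format_error")
  }
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
    abort_ddmqa("weights must be >= 0 with a positive total.",
                "ddmqa_format_error")
  }
  data[c("radial_deviation_mm", "weight")]
}

# Weights act as frequency weights in the moments. The variance uses the
# frequency-weight analogue of the sample variance, sum w (x - m)^2 / (W - 1),
# which reduces to var() at uniform unit weights.
weighted_moments <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  if (W <= 1) {
    return(list(mean = m, sd = NA_real_, skewness = NA_real_,
                kurtosis = NA_real_))
  }
  m2 <- sum(w * (x - m)^2) / W
  s2 <- sum(w * (x - m)^2) / (W - 1)
  if (m2 <= 0) {
    return(list(mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_))
  }
  m3 <- sum(w * (x - m)^3) / W
  m4 <- sum(w * (x - m)^4) / W
  list(mean = m, sd = sqrt(s2), skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}

# Deterministic frequency replication for the weighted hypothesis tests:
# weights are normalized to sum to n and rounded to repetition counts
# (identity for uniform weights).
replicate_by_weight <- function(x, w) {
  n <- length(x)
  reps <- round(w / sum(w) * n)
  reps[reps < 0] <- 0
  if (sum(reps) == 0) reps <- rep(1L, n)
  rep(x, times = reps)
}

#' Descriptive statistics and location tests for beamlet deviations
#'
#' Weighted four-moment summary of the radial-deviation distribution, the
#' sigma distance of a spatial limit from the mean, the weighted fraction of
#' deviations below the limit, and one-sided location tests (Student's t and
#' Wilcoxon signed rank) of mean deviation < limit. The deviations are
#' non-negative by construction, so normality is a large-sample
#' approximation justified by the Central Limit Theorem, not a property of
#' the underlying distribution.
#'
#' @param data A [beamlet_deviations()] data frame (coerced through it).
#' @param limit_mm Spatial limit to test against, mm (default 1, matching
#'   the 1 mm beam/x-ray isocenter agreement standard).
#' @return One-row tibble: `n`, `min_mm`, `max_mm`, `mean_mm`, `sd_mm`,
#'   `skewness`, `kurtosis`, `sigma_limit` = (limit - mean)/sd,
#'   `frac_below_limit` (weighted), `p_t`, `p_wilcoxon`. Tests are `NA` for
#'   n < 2; an all-equal sample yields `sd = 0` and an infinite
#'   `sigma_limit` with a warning.
#' @examples
#' set <- beamlet_deviations(data.frame(radial_deviation_mm = c(.2, .4, .6)))
#' summarize_deviations(set, limit_mm = 1)
#' @export
summarize_deviations <- function(data, limit_mm = 1) {
  data <- beamlet_deviations(data)
  if (!is_number(limit_mm) || limit_mm <= 0) {
    abort_ddmqa("`limit_mm` must be positive.", "ddmqa_config_error")
  }
  x <- data$radial_deviation_mm
  w <- data$weight
  mom <- weighted_moments(x, w)
  sigma_limit <- if (is.na(mom$sd)) {
    NA_real_
  } else if (mom$sd == 0) {
    rlang::warn("all deviations equal: sd = 0, sigma limit is infinite.")
    Inf * sign(limit_mm - mom$mean)
  } else {
    (limit_mm - mom$mean) / mom$sd
  }
  frac <- sum(w * (x < limit_mm)) / sum(w)
  p_t <- p_w <- NA_real_
  if (length(x) >= 2L && !is.na(mom$sd) && mom$sd > 0) {
    xr <- replicate_by_weight(x, w)
    if (length(unique(xr)) > 1L) {
      p_t <- stats::t.test(xr, mu = limit_mm, alternative = "less")$p.value
      p_w <- suppressWarnings(
        stats::wilcox.test(xr, mu = limit_mm, alternative = "less")$p.value
      )
    }
  }
  tibble::tibble(
    n = length(x), min_mm = min(x), max_mm = max(x),
    mean_mm = mom$mean, sd_mm = mom$sd,
    skewness = mom$skewness, kurtosis = mom$kurtosis,
    sigma_limit = sigma_limit, frac_below_limit = frac,
    p_t = p_t, p_wilcoxon = p_w
  )
}

#' Normal-model fraction of beamlets within a spatial limit
#'
#' Large-sample normal approximation to the probability that a beamlet lands
#' within `limit_mm` of nominal: `pnorm((limit - mean)/sd)`.
#'
#' @param mean_mm,sd_mm Mean and standard deviation of the radial-deviation
#'   distribution, mm (`sd_mm > 0`).
#' @param limit_mm Spatial limit, mm.
#' @return Probability in (0, 1).
#' @examples
#' normal_model_fraction_below(0.38, 0.19, 1)  # ~0.9994
#' @export
normal_model_fraction_below <- function(mean_mm, sd_mm, limit_mm) {
  if (!is_number(sd_mm) || sd_mm <= 0) {
    abort_ddmqa("`sd_mm` must be positive.", "ddmqa_config_error")
  }
  stats::pnorm((limit_mm - mean_mm) / sd_mm)
}

#' Recommend a DDM search radius from beamlet accuracy
#'
#' The smallest radius containing at least the requested weighted fraction
#' of observed radial deviations (the empirical weighted quantile), rounded
#' *up* to 0.1 mm — a conservative search radius covering at least a
#' 3-sigma-equivalent confidence interval of beamlet accuracy by default.
#'
#' @param data A [beamlet_deviations()] data frame.
#' @param confidence Required coverage probability (default 0.997).
#' @return Radius in mm, a multiple of 0.1.
#' @export
recommend_search_radius <- function(data, confidence = 0.997) {
  data <- beamlet_deviations(data)
  if (!is_number(confidence) || confidence <= 0 || confidence > 1) {
    abort_ddmqa("`confidence` must lie in (0, 1].", "ddmqa_config_error")
  }
  ord <- order(data$radial_deviation_mm)
  x <- data$radial_deviation_mm[ord]
  cw <- cumsum(data$weight[ord]) / sum(data$weight)
  r <- x[which(cw >= confidence - 1e-12)[1]]
  ceiling_to(r, 0.1)
}

#' Probability-weighted histogram of radial deviations
#'
#' Normalized weighted density over radial bins, the distribution from which
#' the search radius is read off.
#'
#' @param data A [beamlet_deviations()] data frame.
#' @param bin_width_mm Bin width, mm.
#' @return Tibble: `bin_low`, `bin_high`, `bin_center`, `weight` (sum of
#'   weights in bin), `probability` (weights normalized to 1), `density`
#'   (probability / bin width).
#' @export
weighted_deviation_histogram <- function(data, bin_width_mm = 0.05) {
  data <- beamlet_deviations(data)
  if (!is_number(bin_width_mm) || bin_width_mm <= 0) {
    abort_ddmqa("`bin_width_mm` must be positive.", "ddmqa_config_error")
  }
  h <- bin_width_mm
  k <- pmax(0L, floor(data$radial_deviation_mm / h + 1e-12))
  kr <- seq(0L, max(k))
  wsum <- vapply(kr, function(kk) sum(data$weight[k == kk]), numeric(1))
  out <- tibble::tibble(
    bin_low = kr * h, bin_high = (kr + 1L) * h, bin_center = (kr + 0.5) * h,
    weight = wsum, probability = wsum / sum(data$weight)
  )
  out$density <- out$probability / h
  structure(out, class = c("ddmqa_deviation_histogram", class(out)))
}
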