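#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-pixel results of a gamma map
#'
#' @param x A `ddmqa_gamma`.
#' @param ... Unused.
#' @return The per-pixel tibble.
#' @exportS3Method generics::tidy
tidy.ddmqa_gamma <- function(x, ...) x$pixels

#' @rdname tidy.ddmqa_gamma
#' @exportS3Method generics::tidy
tidy.ddmqa_ddm <- function(x, ...) x$pixels

#' @rdname tidy.ddmqa_gamma
#' @exportS3Method generics::tidy
tidy.ddmqa_histogram <- function(x, ...) x$bins

#' @rdname tidy.ddmqa_gamma
#' @exportS3Method generics::tidy
tidy.ddmqa_registration <- function(x, ...) {
  tibble::tibble(
    dx_mm = unname(x$shift_mm[1]), dy_mm = unname(x$shift_mm[2]),
    coarse_dx_mm = unname(x$coarse_shift_mm[1]),
    coarse_dy_mm = unname(x$coarse_shift_mm[2]),
    residual = x$residual, converged = x$converged,
    within_setup_tolerance = x$within_setup_tolerance
  )
}

#' One-row summaries of comparison objects
#'
#' @param x A `ddmqa_gamma`, `ddmqa_ddm`, `ddmqa_histogram` or
#'   `ddmqa_comparison`.
#' @param ... Unused.
#' @return A one-row tibble of headline metrics.
#' @exportS3Method generics::glance
glance.ddmqa_gamma <- function(x, ...) {
  s <- gamma_summary(x)
  tibble::tibble(
    pass_rate_pct = gamma_pass_rate(x),
    max_gamma = s$max_gamma, pct_above_1p5 = s$pct_above_1p5,
    mean_gamma = s$mean_gamma, n_evaluated = s$n_evaluated,
    dose_pct = x$criteria$dose_pct, distance_mm = x$criteria$distance_mm,
    max_dose_cgy = x$max_dose
  )
}

#' @rdname glance.ddmqa_gamma
#' @exportS3Method generics::glance
glance.ddmqa_ddm <- function(x, ...) {
  v <- x$pixels$ddm_pct[x$pixels$evaluated]
  tibble::tibble(
    pass_rate_pct = ddm_pass_rate(x),
    mu_pct = mean(v), sigma_pct = stats::sd(v),
    max_abs_pct = max(abs(v)), n_evaluated = length(v),
    n_truncated = sum(x$pixels$truncated[x$pixels$evaluated]),
    r_mm = x$r_mm, max_dose_cgy = x$max_dose
  )
}

#' @rdname glance.ddmqa_gamma
#' @exportS3Method generics::glance
glance.ddmqa_histogram <- function(x, ...) {
  tibble::tibble(mu_pct = x$mu, sigma_pct = x$sigma, n = x$n,
                 bin_width_pct = x$bin_width_pct,
                 tolerance_pct = x$tolerance_pct)
}

#' @rdname glance.ddmqa_gamma
#' @exportS3Method generics::glance
glance.ddmqa_comparison <- function(x, ...) {
  out <- tibble::tibble(
    gamma_pass_rate_pct = x$gamma_pass_rate,
    ddm_pass_rate_pct = x$ddm_pass_rate,
    mu_pct = x$histogram$mu, sigma_pct = x$histogram$sigma,
    max_gamma = gamma_summary(x$gamma)$max_gamma,
    n_evaluated = x$histogram$n
  )
  if (!is.null(x$registration)) {
    out$dx_mm <- unname(x$registration$shift_mm[1])
    out$dy_mm <- unname(x$registration$shift_mm[2])
  }
  out
}
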