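#' Coarse DFT alignment of measured to calculated plane
#'
#' Stage 1 of the two-stage registration: both planes are resampled onto a
#' common-pitch grid, thresholded at `mask_pct` of their own maxima, and
#' cross-correlated with an FFT. The integer-pixel translation (on the
#' common grid) maximizing the masked cross-correlation is returned in mm.
#' Correlation ties are broken toward the smallest shift magnitude, so the
#' result is deterministic.
#'
#' The shift convention throughout ddmqa: a shift `c(dx, dy)` *applied to
#' the measured plane* moves its pixels to `position + (dx, dy)`, i.e. the
#' measured pixel at `p` is compared against the calculation at `p + shift`.
#'
#' @param measured,calculated [dose_plane()]s with overlapping physical
#'   extent.
#' @param mask_pct Coarse-alignment mask: only dose above this percentage of
#'   each plane's maximum enters the correlation (default 20).
#' @param grid_spacing_mm Pitch of the common correlation grid; defaults to
#'   the calculated plane's (finer) pitch.
#' @param max_shift_mm Largest physical shift considered (default 30 mm, a
#'   gross setup error anywhere beyond it).
#' @return Numeric `c(dx, dy)` in mm (column-axis, row-axis).
#' @export
coarse_register <- function(measured, calculated, mask_pct = 20,
                            grid_spacing_mm = NULL, max_shift_mm = 30) {
  stopifnot(inherits(measured, "dose_plane"), inherits(calculated, "dose_plane"))
  if (!is_number(mask_pct) || mask_pct <= 0 || mask_pct >= 100) {
    abort_ddmqa("`mask_pct` must lie in (0, 100).", "ddmqa_config_error")
  }
  pitch <- grid_spacing_mm %||% min(calculated$spacing)
  mg <- resample_common(measured, pitch)
  cg <- resample_common(calculated, pitch)
  mask <- function(p) {
    v <- p$values
    v[v <= (mask_pct / 100) * max(v)] <- 0
    v
  }
  mv <- mask(mg)
  cv <- mask(cg)
  if (all(mv == 0) || all(cv == 0)) {
    abort_ddmqa("empty coarse-alignment mask: no dose above the threshold.",
                "ddmqa_registration_error")
  }

  # linear (zero-padded) cross-correlation C(k) = sum_p m(p) c(p + k)
  nr <- nrow(mv) + nrow(cv) - 1L
  nc <- ncol(mv) + ncol(cv) - 1L
  pad <- function(v) {
    out <- matrix(0, nr, nc)
    out[seq_len(nrow(v)), seq_len(ncol(v))] <- v
    out
  }
  cc <- Re(stats::fft(Conj(stats::fft(pad(mv))) * stats::fft(pad(cv)),
                      inverse = TRUE)) / (nr * nc)
  # circular lag (ki, kj) corresponds to c being offset by +k grid steps
  ki <- c(0:(nr - 1L))
  ki[ki > nr / 2] <- ki[ki > nr / 2] - nr
  kj <- c(0:(nc - 1L))
  kj[kj > nc / 2] <- kj[kj > nc / 2] - nc

  # shift (in the c(dx, dy) convention) for lag k: measured pixel at p aligns
  # with calculated at p + shift, where grid origins differ too.
  og <- cg$origin - mg$origin
  shift_y <- ki * pitch + og[1]
  shift_x <- kj * pitch + og[2]
  ok_i <- abs(shift_y) <= max_shift_mm
  ok_j <- abs(shift_x) <= max_shift_mm
  if (!any(ok_i) || !any(ok_j)) {
    abort_ddmqa("no admissible shift within `max_shift_mm`.",
                "ddmqa_registration_error")
  }
  sub <- cc[ok_i, ok_j, drop = FALSE]
  sy <- shift_y[ok_i]
  sx <- shift_x[ok_j]
  best <- max(sub)
  cand <- which(sub >= best - 1e-9 * abs(best), arr.ind = TRUE)
  mag <- sy[cand[, 1]]^2 + sx[cand[, 2]]^2
  k <- order(mag, abs(sy[cand[, 1]]), abs(sx[cand[, 2]]))[1L]
  c(dx = sx[cand[k, 2]], dy = sy[cand[k, 1]])
}

# Resample a plane to `pitch` for registration purposes only (the comparison
# engines never interpolate the measured plane; registration may).
resample_common <- function(plane, pitch) {
  if (min(plane$spacing) > pitch + 1e-12) {
    resample_to_search_grid(plane, pitch)
  } else {
    plane
  }
}

#' Least-squares refinement of the registration shift
#'
#' Stage 2: starting from the coarse shift, a derivative-free Nelder-Mead
#' search minimizes the sum of squared dose differences over *all* measured
#' pixels (no threshold), with calculated values obtained by bilinear
#' interpolation of the fine search grid. Measured pixels whose shifted
#' position leaves the calculated extent are dropped from the sum.
#'
#' @inheritParams coarse_register
#' @param init_shift Starting shift `c(dx, dy)` in mm, normally from
#'   [coarse_register()].
#' @param search_spacing_mm Pitch of the interpolation grid used when the
#'   calculated plane is coarser (default 0.25 mm).
#' @param tolerance_mm Setup tolerance used to set the
#'   `within_setup_tolerance` flag (default 2 mm, a typical laser-alignment
#'   tolerance).
#' @return A `ddmqa_registration` list: `shift_mm` (`c(dx, dy)`),
#'   `coarse_shift_mm`, `residual` (sum of squared dose differences),
#'   `converged`, `within_setup_tolerance`, `n_compared`.
#' @export
fine_register <- function(measured, calculated, init_shift = c(0, 0),
                          search_spacing_mm = 0.25, tolerance_mm = 2) {
  stopifnot(inherits(measured, "dose_plane"), inherits(calculated, "dose_plane"))
  init_shift <- as.numeric(init_shift)
  stopifnot(length(init_shift) == 2L)
  fine <- prepare_search_plane(calculated, search_spacing_mm)
  ym <- rep(plane_rows_mm(measured), times = ncol(measured$values))
  xm <- rep(plane_cols_mm(measured), each = nrow(measured$values))
  mv <- as.vector(measured$values)
  ssd <- function(shift) {
    cv <- interp_plane(fine, ym + shift[2], xm + shift[1])
    ok <- !is.na(cv)
    if (!any(ok)) return(sum(mv^2) * 1e6)
    sum((mv[ok] - cv[ok])^2)
  }
  res0 <- ssd(init_shift)
  opt <- stats::optim(
    init_shift, ssd, method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 500,
                   parscale = c(1, 1), abstol = 0)
  )
  converged <- opt$convergence == 0L
  if (!converged || opt$value > res0 + 1e-12) {
    # non-convergence (or a degenerate flat objective): keep the coarse shift
    shift <- init_shift
    residual <- res0
  } else {
    shift <- opt$par
    residual <- opt$value
  }
  # flat fields: if the objective is indifferent, report the initial shift
  if (abs(residual - res0) <= 1e-12 * max(res0, 1)) {
    shift <- init_shift
    residual <- res0
  }
  cv <- interp_plane(fine, ym + shift[2], xm + shift[1])
  structure(
    list(
      shift_mm = c(dx = shift[1], dy = shift[2]),
      coarse_shift_mm = c(dx = init_shift[1], dy = init_shift[2]),
      residual = residual,
      converged = converged,
      within_setup_tolerance = sqrt(sum(shift^2)) <= tolerance_mm,
      n_compared = sum(!is.na(cv))
    ),
    class = "ddmqa_registration"
  )
}

#' Register a measured plane to a calculated plane (both stages)
#'
#' Convenience wrapper: coarse DFT alignment on the masked dose patterns,
#' then least-squares refinement without the threshold.
#'
#' @inheritParams coarse_register
#' @inheritParams fine_register
#' @return A `ddmqa_registration`, see [fine_register()].
#' @export
register_planes <- function(measured, calculated, mask_pct = 20,
                            search_spacing_mm = 0.25, tolerance_mm = 2) {
  cs <- coarse_register(measured, calculated, mask_pct = mask_pct)
  fine_register(measured, calculated, init_shift = cs,
                search_spacing_mm = search_spacing_mm,
                tolerance_mm = tolerance_mm)
}

#' Apply a registration shift to a plane
#'
#' Moves the plane's origin by the shift so that subsequent same-frame
#' comparisons see the aligned geometry. Pixel values are untouched.
#'
#' @param plane A [dose_plane()].
#' @param shift_mm `c(dx, dy)` in mm or a `ddmqa_registration`.
#' @return The shifted [dose_plane()].
#' @export
apply_shift <- function(plane, shift_mm) {
  stopifnot(inherits(plane, "dose_plane"))
  if (inherits(shift_mm, "ddmqa_registration")) shift_mm <- shift_mm$shift_mm
  shift_mm <- as.numeric(shift_mm)
  stopifnot(length(shift_mm) == 2L)
  dose_plane(plane$values, plane$spacing,
             plane$origin + c(shift_mm[2], shift_mm[1]), plane$label)
}

#' @export
print.ddmqa_registration <- function(x, ...) {
  cat(sprintf(
    "<registration> shift (dx, dy) = (%.3f, %.3f) mm [coarse (%.2f, %.2f)], residual %.4g, %s setup tolerance\n",
    x$shift_mm[1], x$shift_mm[2], x$coarse_shift_mm[1], x$coarse_shift_mm[2],
    x$residual, if (x$within_setup_tolerance) "within" else "EXCEEDS"
  ))
  invisible(x)
}

#' Session consistency report for tracked registration shifts
#'
#' Setup shifts are tracked per measurement session to confirm they stay
#' within the tolerance of laser-based equipment setup and are consistent in
#' magnitude and direction.
#'
#' @param results A list of `ddmqa_registration` objects (or a single one).
#' @param tolerance_mm Setup tolerance, mm (default 2).
#' @return A list with `shifts` (per-result tibble: `dx_mm`, `dy_mm`,
#'   `magnitude_mm`, `flagged`), `mean_shift_mm`, `max_magnitude_mm`,
#'   `n_flagged`.
#' @export
track_shifts <- function(results, tolerance_mm = 2) {
  if (inherits(results, "ddmqa_registration")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "ddmqa_registration")))
  shifts <- purrr::map_dfr(seq_along(results), function(i) {
    s <- results[[i]]$shift_mm
    tibble::tibble(
      session = i, dx_mm = unname(s[1]), dy_mm = unname(s[2]),
      magnitude_mm = sqrt(sum(s^2))
    )
  })
  shifts$flagged <- shifts$magnitude_mm > tolerance_mm
  list(
    shifts = shifts,
    mean_shift_mm = c(dx = mean(shifts$dx_mm), dy = mean(shifts$dy_mm)),
    max_magnitude_mm = max(shifts$magnitude_mm),
    n_flagged = sum(shifts$flagged)
  )
}
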