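#' Discrete spot-scanning field model
#'
#' A pencil-beam-scanning field is emulated as a sum of 2D Gaussian lateral
#' spot profiles. Defaults model a typical scanned proton field at depth:
#' 5 mm lateral sigma, 5 mm spot pitch.
#'
#' @param spots Tibble/data frame with columns `x_mm`, `y_mm`, `weight`
#'   (peak dose contribution, cGy(RBE), > 0) and `sigma_mm` (> 0). If
#'   `NULL`, a uniform grid of spots covering `extent_mm` is built from
#'   `pitch_mm`, `sigma_mm` and `weight`.
#' @param extent_mm Field bounding box, mm: half-width of the spot grid on
#'   each axis (total field size `2 * extent_mm`).
#' @param pitch_mm,sigma_mm,weight Defaults for the generated uniform grid.
#' @return A `ddmqa_spot_field` list (`spots`, `extent_mm`).
#' @export
spot_field <- function(spots = NULL, extent_mm = 50, pitch_mm = 5,
                       sigma_mm = 5, weight = 1) {
  if (is.null(spots)) {
    pos <- seq(-extent_mm, extent_mm, by = pitch_mm)
    spots <- tidyr::expand_grid(x_mm = pos, y_mm = pos)
    spots$weight <- weight
    spots$sigma_mm <- sigma_mm
  }
  spots <- tibble::as_tibble(spots)
  need <- c("x_mm", "y_mm", "weight", "sigma_mm")
  if (!all(need %in% names(spots)) || !nrow(spots)) {
    abort_ddmqa("`spots` needs rows with x_mm, y_mm, weight, sigma_mm.",
                "ddmqa_format_error")
  }
  if (any(spots$weight <= 0) || any(spots$sigma_mm <= 0)) {
    abort_ddmqa("spot weights and sigmas must be positive.",
                "ddmqa_format_error")
  }
  structure(list(spots = spots, extent_mm = extent_mm),
            class = "ddmqa_spot_field")
}

#' Render a spot field to a dose plane
#'
#' Deterministic superposition: `dose(x, y) = sum_s w_s G((x, y); center_s,
#' sigma_s)` with unit-peak Gaussians.
#'
#' @param field A [spot_field()].
#' @param spacing_mm Grid pitch, mm.
#' @param margin_mm Rendered margin beyond the spot bounding box (default
#'   `3 * max(sigma)` so the dose falls off naturally).
#' @param label Plane label.
#' @return A [dose_plane()].
#' @export
render_plane <- function(field, spacing_mm = 1, margin_mm = NULL,
                         label = "synthetic") {
  stopifnot(inherits(field, "ddmqa_spot_field"))
  if (!is_number(spacing_mm) || spacing_mm <= 0) {
    abort_ddmqa("`spacing_mm` must be positive.", "ddmqa_config_error")
  }
  sp <- field$spots
  margin <- margin_mm %||% (3 * max(sp$sigma_mm))
  lo <- c(min(sp$y_mm), min(sp$x_mm)) - margin
  hi <- c(max(sp$y_mm), max(sp$x_mm)) + margin
  ys <- seq(lo[1], hi[1], by = spacing_mm)
  xs <- seq(lo[2], hi[2], by = spacing_mm)
  vals <- matrix(0, length(ys), length(xs))
  for (s in seq_len(nrow(sp))) {
    gy <- exp(-(ys - sp$y_mm[s])^2 / (2 * sp$sigma_mm[s]^2))
    gx <- exp(-(xs - sp$x_mm[s])^2 / (2 * sp$sigma_mm[s]^2))
    vals <- vals + sp$weight[s] * outer(gy, gx)
  }
  dose_plane(vals, spacing = spacing_mm, origin = lo, label = label)
}

#' Homogeneous dose plane
#'
#' The error-injection testbed: a uniform dose across a square plane, the
#' planar face of a homogeneous dose cube.
#'
#' @param dose_cgy Uniform dose value, cGy(RBE).
#' @param size_mm Side length, mm.
#' @param spacing_mm Grid pitch, mm.
#' @param label Plane label.
#' @return A [dose_plane()] centered on the isocenter.
#' @export
uniform_plane <- function(dose_cgy = 200, size_mm = 100, spacing_mm = 1,
                          label = "synthetic") {
  n <- as.integer(round(size_mm / spacing_mm)) + 1L
  dose_plane(matrix(dose_cgy, n, n), spacing = spacing_mm, label = label)
}

#' Controlled error specification
#'
#' @param kind One of `"global_scale"` (all doses multiplied by
#'   `1 + magnitude_pct/100`), `"region_offset"` (doses inside `region`
#'   scaled likewise), `"spot_jitter"` (spots re-rendered with Gaussian
#'   positional displacements of sd `jitter_mm`), `"noise"` (zero-mean
#'   Gaussian perturbation with sd `magnitude_pct`% of the plane maximum).
#' @param magnitude_pct Error magnitude, percent (scale/offset/noise kinds).
#' @param jitter_mm Positional jitter sd, mm (`spot_jitter`).
#' @param region Rectangle `c(y_lo, y_hi, x_lo, x_hi)` in mm
#'   (`region_offset`).
#' @param seed Integer seed fixing any randomness of the error draw.
#' @return A `ddmqa_error_spec` list.
#' @export
error_spec <- function(kind = c("global_scale", "region_offset",
                                "spot_jitter", "noise"),
                       magnitude_pct = 0, jitter_mm = 0, region = NULL,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "region_offset") {
    if (is.null(region) || length(region) != 4L) {
      abort_ddmqa("`region_offset` needs region = c(y_lo, y_hi, x_lo, x_hi).",
                  "ddmqa_config_error")
    }
  }
  structure(list(kind = kind, magnitude_pct = magnitude_pct,
                 jitter_mm = jitter_mm, region = region,
                 seed = as.integer(seed)),
            class = "ddmqa_error_spec")
}

#' Inject a controlled error into a plane
#'
#' @param plane A [dose_plane()].
#' @param spec An [error_spec()].
#' @param field The [spot_field()] the plane was rendered from; required for
#'   `spot_jitter`, which re-renders the field with displaced spots.
#' @return The perturbed [dose_plane()]. For `spot_jitter` the drawn
#'   displacements are attached as attribute `"jitter_draws_mm"` (a tibble)
#'   for auditability.
#' @export
apply_error <- function(plane, spec, field = NULL) {
  stopifnot(inherits(plane, "dose_plane"), inherits(spec, "ddmqa_error_spec"))
  switch(spec$kind,
    global_scale = {
      dose_plane(plane$values * (1 + spec$magnitude_pct / 100),
                 plane$spacing, plane$origin, plane$label)
    },
    region_offset = {
      rg <- spec$region
      ys <- plane_rows_mm(plane)
      xs <- plane_cols_mm(plane)
      if (rg[1] < ys[1] - 1e-9 || rg[2] > ys[length(ys)] + 1e-9 ||
          rg[3] < xs[1] - 1e-9 || rg[4] > xs[length(xs)] + 1e-9) {
        abort_ddmqa("error region extends outside the plane.",
                    "ddmqa_config_error")
      }
      v <- plane$values
      ii <- ys >= rg[1] & ys <= rg[2]
      jj <- xs >= rg[3] & xs <= rg[4]
      v[ii, jj] <- v[ii, jj] * (1 + spec$magnitude_pct / 100)
      dose_plane(v, plane$spacing, plane$origin, plane$label)
    },
    spot_jitter = {
      if (is.null(field)) {
        abort_ddmqa("`spot_jitter` needs the originating `field`.",
                    "ddmqa_config_error")
      }
      sp <- field$spots
      old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
      on.exit(restore_seed(old_seed), add = TRUE)
      set.seed(spec$seed)
      dxy <- tibble::tibble(dx_mm = stats::rnorm(nrow(sp), 0, spec$jitter_mm),
                            dy_mm = stats::rnorm(nrow(sp), 0, spec$jitter_mm))
      sp$x_mm <- sp$x_mm + dxy$dx_mm
      sp$y_mm <- sp$y_mm + dxy$dy_mm
      jf <- spot_field(sp, extent_mm = field$extent_mm)
      # render on exactly the original geometry
      ys <- plane_rows_mm(plane)
      xs <- plane_cols_mm(plane)
      vals <- matrix(0, length(ys), length(xs))
      for (s in seq_len(nrow(sp))) {
        gy <- exp(-(ys - sp$y_mm[s])^2 / (2 * sp$sigma_mm[s]^2))
        gx <- exp(-(xs - sp$x_mm[s])^2 / (2 * sp$sigma_mm[s]^2))
        vals <- vals + sp$weight[s] * outer(gy, gx)
      }
      out <- dose_plane(vals, plane$spacing, plane$origin, plane$label)
      attr(out, "jitter_draws_mm") <- dxy
      out
    },
    noise = {
      old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
      on.exit(restore_seed(old_seed), add = TRUE)
      set.seed(spec$seed)
      sdv <- spec$magnitude_pct / 100 * global_max(plane)
      v <- plane$values + matrix(stats::rnorm(length(plane$values), 0, sdv),
                                 nrow(plane$values))
      v[v < 0] <- 0
      dose_plane(v, plane$spacing, plane$origin, plane$label)
    }
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Sample a plane at ion-chamber-array detector positions
#'
#' Point sampling (no volume averaging) at detector pixel centers with the
#' given pitch, symmetric about the plane's physical center. The default
#' pitch is the 7.62 mm chamber spacing of a Matrixx-class array.
#'
#' @param plane A [dose_plane()] (fine grid).
#' @param pitch_mm Detector pitch, mm; must be at least the plane's pitch.
#' @param label Label of the sampled plane.
#' @return A [dose_plane()] on the detector grid.
#' @export
downsample_to_detector <- function(plane, pitch_mm = 7.62,
                                   label = "measured") {
  stopifnot(inherits(plane, "dose_plane"))
  if (!is_number(pitch_mm) || pitch_mm <= 0) {
    abort_ddmqa("`pitch_mm` must be positive.", "ddmqa_config_error")
  }
  if (pitch_mm < max(plane$spacing) - 1e-12) {
    abort_ddmqa("detector pitch must be >= the plane's pitch.",
                "ddmqa_config_error")
  }
  centers <- function(lo, hi) {
    mid <- (lo + hi) / 2
    k <- floor((hi - lo) / pitch_mm)
    mid + (seq_len(k + 1L) - 1L - k / 2) * pitch_mm
  }
  ys <- plane_rows_mm(plane)
  xs <- plane_cols_mm(plane)
  yd <- centers(ys[1], ys[length(ys)])
  xd <- centers(xs[1], xs[length(xs)])
  vals <- interp_plane(plane, rep(yd, times = length(xd)),
                       rep(xd, each = length(yd)))
  dose_plane(matrix(vals, length(yd), length(xd)),
             spacing = pitch_mm, origin = c(yd[1], xd[1]), label = label)
}

#' Sample synthetic beamlet radial deviations
#'
#' Non-negative radial deviations drawn from a folded normal whose
#' *population* mean and sd match the targets exactly (the underlying normal
#' parameters are solved by moment matching to 1e-6), with uniform weights.
#'
#' @param n Number of samples.
#' @param mean_target_mm,sd_target_mm Target population moments, mm. The
#'   pair must be feasible for a folded normal (`mean/sd` at least about
#'   1.32, the half-normal ratio).
#' @param seed Integer seed.
#' @return A [beamlet_deviations()] tibble with `n` rows.
#' @examples
#' d <- sample_radial_deviations(1000, 0.38, 0.19, seed = 7)
#' summarize_deviations(d)$mean_mm
#' @export
sample_radial_deviations <- function(n, mean_target_mm, sd_target_mm, seed) {
  if (!is_number(n) || n < 1) {
    abort_ddmqa("`n` must be >= 1.", "ddmqa_config_error")
  }
  par <- folded_normal_params(mean_target_mm, sd_target_mm)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  x <- abs(stats::rnorm(n, par$mu, par$sigma))
  beamlet_deviations(tibble::tibble(radial_deviation_mm = x, weight = 1))
}

# Folded-normal moments for underlying N(mu, sigma).
folded_moments <- function(mu, sigma) {
  m <- sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
  v <- mu^2 + sigma^2 - m^2
  list(mean = m, sd = sqrt(v))
}

# Solve (mu, sigma) of the underlying normal so the folded moments match the
# targets. mean/sd of a folded normal is a strictly increasing function of
# k = mu/sigma over k >= 0, minimized at the half-normal ratio
# sqrt(2/pi)/sqrt(1 - 2/pi) ~ 1.3237.
folded_normal_params <- function(mean_target, sd_target, tol = 1e-6) {
  if (!is_number(mean_target) || !is_number(sd_target) ||
      mean_target <= 0) {
    abort_ddmqa("targets must be positive numbers.", "ddmqa_config_error")
  }
  if (sd_target <= 0) {
    # degenerate: all samples at the mean
    return(list(mu = mean_target, sigma = 1e-12))
  }
  ratio <- mean_target / sd_target
  half_normal_ratio <- sqrt(2 / pi) / sqrt(1 - 2 / pi)
  if (ratio < half_normal_ratio - 1e-9) {
    abort_ddmqa(sprintf(
      "infeasible moment pair: mean/sd = %.3f below the folded-normal minimum %.4f.",
      ratio, half_normal_ratio), "ddmqa_config_error")
  }
  if (ratio > 1e3) {
    # folding is numerically irrelevant this far from zero
    return(list(mu = mean_target, sigma = sd_target))
  }
  f <- function(k) {
    fm <- folded_moments(k, 1)
    fm$mean / fm$sd - ratio
  }
  # for k = mu/sigma large the folded normal is the normal, so the ratio
  # approaches k: bracket the root accordingly
  upper <- max(60, ratio + 10)
  k <- if (f(0) >= 0) 0 else stats::uniroot(f, c(0, upper), tol = tol)$root
  fm1 <- folded_moments(k, 1)
  sigma <- mean_target / fm1$mean
  list(mu = k * sigma, sigma = sigma)
}

#' Generate a measured/calculated synthetic plane pair
#'
#' One call builds a controlled QA scenario: a calculated plane (fine grid),
#' a measured plane (detector grid) carrying an injected error, and a
#' manifest recording the ground truth. Presets:
#' \describe{
#'   \item{`identical`}{Measured is the noiseless detector sampling of the
#'     calculated plane.}
#'   \item{`region-error`}{A homogeneous plane with a square region (default
#'     3x3 cm^2) of the measured plane offset by `magnitude_pct`.}
#'   \item{`global-scale`}{The whole measured plane scaled by
#'     `magnitude_pct` (e.g. -3 for a 3% underdose).}
#'   \item{`noise`}{Zero-mean Gaussian measurement noise of sd
#'     `magnitude_pct`% of maximum.}
#'   \item{`jitter`}{A spot field re-rendered with per-spot positional
#'     displacements of sd `jitter_mm`.}
#' }
#' The `region-error` and `global-scale` presets use the homogeneous
#' error-injection testbed (a uniform `field_size_mm` plane); `identical`,
#' `noise` and `jitter` use a rendered spot field.
#'
#' @param preset Scenario name.
#' @param magnitude_pct Error magnitude, percent.
#' @param jitter_mm Spot-position jitter sd, mm.
#' @param seed Integer seed.
#' @param field_size_mm Field side length, mm (default 100).
#' @param calc_spacing_mm Calculated-grid pitch, mm (default 1).
#' @param detector_pitch_mm Detector pitch, mm (default 7.62).
#' @param region_size_mm Side of the offset region, mm (default 30).
#' @param noise_pct Additional measurement noise applied on top of the
#'   preset error (default 0 = noiseless).
#' @return List: `measured`, `calculated` ([dose_plane()]s) and `manifest`
#'   (ground-truth list).
#' @export
synth_pair <- function(preset = c("identical", "region-error", "global-scale",
                                  "noise", "jitter"),
                       magnitude_pct = 5, jitter_mm = 0.19, seed = 1L,
                       field_size_mm = 100, calc_spacing_mm = 1,
                       detector_pitch_mm = 7.62, region_size_mm = 30,
                       noise_pct = 0) {
  preset <- match.arg(preset)
  uniform_presets <- c("region-error", "global-scale")
  if (preset %in% uniform_presets) {
    calc <- uniform_plane(200, field_size_mm, calc_spacing_mm,
                          label = "calculated")
    field <- NULL
  } else {
    field <- spot_field(extent_mm = field_size_mm / 2)
    calc <- render_plane(field, spacing_mm = calc_spacing_mm,
                         label = "calculated")
  }
  meas <- downsample_to_detector(calc, detector_pitch_mm)
  manifest <- list(preset = preset, seed = seed,
                   field_size_mm = field_size_mm,
                   detector_pitch_mm = detector_pitch_mm)
  if (preset == "region-error") {
    half <- region_size_mm / 2
    rg <- c(-half, half, -half, half)
    meas <- apply_error(meas, error_spec("region_offset",
                                         magnitude_pct = magnitude_pct,
                                         region = rg, seed = seed))
    manifest$magnitude_pct <- magnitude_pct
    manifest$region_mm <- rg
  } else if (preset == "global-scale") {
    meas <- apply_error(meas, error_spec("global_scale",
                                         magnitude_pct = magnitude_pct,
                                         seed = seed))
    manifest$magnitude_pct <- magnitude_pct
  } else if (preset == "noise") {
    meas <- apply_error(meas, error_spec("noise",
                                         magnitude_pct = magnitude_pct,
                                         seed = seed))
    manifest$magnitude_pct <- magnitude_pct
  } else if (preset == "jitter") {
    jittered <- apply_error(calc, error_spec("spot_jitter",
                                             jitter_mm = jitter_mm,
                                             seed = seed),
                            field = field)
    meas <- downsample_to_detector(jittered, detector_pitch_mm)
    manifest$jitter_mm <- jitter_mm
  }
  if (noise_pct > 0) {
    meas <- apply_error(meas, error_spec("noise", magnitude_pct = noise_pct,
                                         seed = seed + 1L))
    manifest$noise_pct <- noise_pct
  }
  meas$label <- "measured"
  list(measured = meas, calculated = calc, manifest = manifest)
}
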