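# Shared machinery for the gamma and DDM disk searches.
#
# Both metrics evaluate each measured pixel (never interpolated) against the
# calculated plane resampled onto a fine search grid. Disk membership is the
# closed disk, tested on squared distance with a 1e-9 mm^2 float guard:
# d2 <= R^2 + 1e-9.

DISK_EPS <- 1e-9

# Resample the calculated plane onto the search grid unless already fine.
prepare_search_plane <- function(calculated, search_spacing_mm) {
  if (min(calculated$spacing) > search_spacing_mm + 1e-12) {
    resample_to_search_grid(calculated, search_spacing_mm)
  } else {
    calculated
  }
}

normalization_dose <- function(measured, fine, normalize_to) {
  if (normalize_to == "measured") global_max(measured) else global_max(fine)
}

# Per-pixel candidate test points within `radius` of (ym, xm).
# Returns NULL when the pixel sees no calculated node at all.
pixel_candidates <- function(fine_vals, yf, xf, ym, xm, radius) {
  ii <- which(abs(yf - ym) <= radius + DISK_EPS)
  jj <- which(abs(xf - xm) <= radius + DISK_EPS)
  if (!length(ii) || !length(jj)) return(NULL)
  dy2 <- (yf[ii] - ym)^2
  dx2 <- (xf[jj] - xm)^2
  d2 <- outer(dy2, dx2, "+")
  keep <- d2 <= radius^2 + DISK_EPS
  if (!any(keep)) return(NULL)
  list(d2 = d2[keep], vals = fine_vals[ii, jj, drop = FALSE][keep])
}

disk_truncated <- function(yf, xf, ym, xm, radius) {
  (ym - radius < yf[1] - DISK_EPS) ||
    (ym + radius > yf[length(yf)] + DISK_EPS) ||
    (xm - radius < xf[1] - DISK_EPS) ||
    (xm + radius > xf[length(xf)] + DISK_EPS)
}

# Evaluation mask: measured pixels strictly above the low-dose cutoff.
evaluated_mask <- function(measured, max_dose, cutoff_pct) {
  measured$values > (cutoff_pct / 100) * max_dose
}

signed_delta_pct <- function(m, cvals, max_dose, normalization) {
  if (normalization == "local") {
    100 * (m - cvals) / m
  } else {
    100 * (m - cvals) / max_dose
  }
}
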