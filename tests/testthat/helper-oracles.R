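# Independent brute-force oracles and constructed fixtures.
#
# The oracles enumerate every test point of the fine grid (no windowing, no
# shared code with the package engines) and apply the documented disk
# membership rule d^2 <= R^2 + 1e-9.

# Exhaustive gamma: loop over measured pixels, test every fine-grid node.
oracle_gamma <- function(meas, fine, crit, max_search) {
  yf <- plane_rows_mm(fine)
  xf <- plane_cols_mm(fine)
  M <- max(fine$values)
  ym <- plane_rows_mm(meas)
  xm <- plane_cols_mm(meas)
  grid_y <- rep(yf, times = length(xf))
  grid_x <- rep(xf, each = length(yf))
  cv <- as.vector(fine$values)
  out <- matrix(NA_real_, nrow(meas$values), ncol(meas$values))
  for (i in seq_along(ym)) {
    for (j in seq_along(xm)) {
      m <- meas$values[i, j]
      if (m <= crit$low_dose_cutoff_pct / 100 * M) next
      d2 <- (grid_y - ym[i])^2 + (grid_x - xm[j])^2
      keep <- d2 <= max_search^2 + 1e-9
      if (!any(keep)) next
      delta <- 100 * (m - cv[keep]) / M
      out[i, j] <- min(sqrt((sqrt(d2[keep]) / crit$distance_mm)^2 +
                              (delta / crit$dose_pct)^2))
    }
  }
  out
}

# Exhaustive DDM with the package's documented tie rule (smallest |delta|,
# then smallest distance, then positive sign), tracked scalar-wise.
oracle_ddm <- function(meas, fine, crit) {
  yf <- plane_rows_mm(fine)
  xf <- plane_cols_mm(fine)
  M <- max(fine$values)
  ym <- plane_rows_mm(meas)
  xm <- plane_cols_mm(meas)
  r <- crit$search_radius_mm
  grid_y <- rep(yf, times = length(xf))
  grid_x <- rep(xf, each = length(yf))
  cv <- as.vector(fine$values)
  out <- matrix(NA_real_, nrow(meas$values), ncol(meas$values))
  for (i in seq_along(ym)) {
    for (j in seq_along(xm)) {
      m <- meas$values[i, j]
      if (m <= crit$low_dose_cutoff_pct / 100 * M) next
      d2 <- (grid_y - ym[i])^2 + (grid_x - xm[j])^2
      keep <- which(d2 <= r^2 + 1e-9)
      if (!length(keep)) next
      delta <- 100 * (m - cv[keep]) / M
      ord <- order(abs(delta), d2[keep], -sign(delta))
      out[i, j] <- delta[ord[1]]
    }
  }
  out
}

# Scalar double-double loop gamma for tiny toy grids (slow, maximally dumb).
oracle_gamma_scalar <- function(meas, fine, crit, max_search) {
  yf <- plane_rows_mm(fine)
  xf <- plane_cols_mm(fine)
  M <- max(fine$values)
  ym <- plane_rows_mm(meas)
  xm <- plane_cols_mm(meas)
  out <- matrix(NA_real_, nrow(meas$values), ncol(meas$values))
  for (i in seq_along(ym)) for (j in seq_along(xm)) {
    m <- meas$values[i, j]
    if (m <= crit$low_dose_cutoff_pct / 100 * M) next
    best <- Inf
    for (ii in seq_along(yf)) for (jj in seq_along(xf)) {
      d2 <- (yf[ii] - ym[i])^2 + (xf[jj] - xm[j])^2
      if (d2 > max_search^2 + 1e-9) next
      delta <- 100 * (m - fine$values[ii, jj]) / M
      g <- sqrt((sqrt(d2) / crit$distance_mm)^2 + (delta / crit$dose_pct)^2)
      if (g < best) best <- g
    }
    out[i, j] <- if (is.finite(best)) best else NA_real_
  }
  out
}

gamma_matrix <- function(map) {
  m <- matrix(map$pixels$gamma, nrow = map$dim[1])
  m[!matrix(map$pixels$evaluated, nrow = map$dim[1])] <- NA
  m
}

ddm_matrix <- function(map) {
  m <- matrix(map$pixels$ddm_pct, nrow = map$dim[1])
  m[!matrix(map$pixels$evaluated, nrow = map$dim[1])] <- NA
  m
}

# A random smooth plane pair: calculated on a 1.5 mm grid from a handful of
# Gaussian spots, measured point-sampled on a 10x10, 3 mm detector with
# multiplicative noise.
random_pair <- function(noise_sd = 0.03) {
  grid <- expand.grid(x_mm = seq(-10, 10, 5), y_mm = seq(-10, 10, 5))
  f <- spot_field(spots = data.frame(
    x_mm = grid$x_mm, y_mm = grid$y_mm,
    weight = stats::runif(nrow(grid), 20, 150),
    sigma_mm = stats::runif(nrow(grid), 3, 8)
  ))
  calc <- render_plane(f, spacing_mm = 1.5, margin_mm = 5, label = "calculated")
  yd <- seq(-13.5, 13.5, by = 3)
  vals <- interp_plane(calc, rep(yd, times = 10), rep(yd, each = 10))
  vals <- vals * (1 + matrix(stats::rnorm(100, 0, noise_sd), 10))
  vals[vals < 0] <- 0
  meas <- dose_plane(matrix(vals, 10, 10), spacing = 3,
                     origin = c(-13.5, -13.5), label = "measured")
  list(measured = meas, calculated = calc)
}

# Analytic dose of a spot field at one point (independent of render_plane).
spot_dose_at <- function(field, y, x) {
  sp <- field$spots
  sum(sp$weight * exp(-((x - sp$x_mm)^2 + (y - sp$y_mm)^2) / (2 * sp$sigma_mm^2)))
}

# Measured plane sampled analytically from a spot field at positions
# shifted by `shift = c(dx, dy)` (ground truth for registration tests:
# measured pixel at p carries the field value at p + shift).
shifted_measurement <- function(field, detector, shift) {
  ys <- plane_rows_mm(detector)
  xs <- plane_cols_mm(detector)
  vals <- outer(ys, xs, Vectorize(function(y, x) {
    spot_dose_at(field, y + shift[2], x + shift[1])
  }))
  dose_plane(vals, detector$spacing, detector$origin, "measured")
}

# --- DICOM fixture writer (bytes built in code; nothing stored on disk) ----

dicom_bytes <- function(group, elem, vr, payload, explicit = TRUE) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  if (length(payload) %% 2L == 1L) {
    payload <- c(payload, if (vr %in% c("OB", "OW")) as.raw(0) else charToRaw(" "))
  }
  hdr <- c(u16(group), u16(elem))
  if (explicit) {
    long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
    hdr <- c(hdr, charToRaw(vr),
             if (long_vr) c(as.raw(c(0, 0)), u32(length(payload)))
             else u16(length(payload)))
  } else {
    hdr <- c(hdr, u32(length(payload)))
  }
  c(hdr, payload)
}

# Minimal Part-10 RT Dose file. `pixels` is an integer matrix (row-major in
# the file); doses decode as pixels * scaling.
write_fixture_dicom <- function(path, pixels, scaling, spacing = c(2, 2),
                                ipp = c(-1, -1), bits = 16L,
                                explicit = TRUE, drop_geometry = FALSE) {
  u16v <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  ds <- function(x) charToRaw(paste(sprintf("%.10g", x), collapse = "\\"))
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  meta <- dicom_bytes(0x0002, 0x0010, "UI", charToRaw(ts), explicit = TRUE)
  meta <- c(dicom_bytes(0x0002, 0x0000, "UL",
                        writeBin(length(meta), raw(), size = 4,
                                 endian = "little"), explicit = TRUE),
            meta)
  px <- as.vector(t(pixels))  # row-major
  px_payload <- if (bits == 16L) {
    u16v(px)
  } else {
    writeBin(as.integer(px), raw(), size = 4, endian = "little")
  }
  body <- c(
    if (!drop_geometry) {
      dicom_bytes(0x0020, 0x0032, "DS", ds(c(ipp[2], ipp[1], 0)), explicit)
    },
    dicom_bytes(0x0028, 0x0010, "US", u16v(nrow(pixels)), explicit),
    dicom_bytes(0x0028, 0x0011, "US", u16v(ncol(pixels)), explicit),
    if (!drop_geometry) {
      dicom_bytes(0x0028, 0x0030, "DS", ds(spacing), explicit)
    },
    dicom_bytes(0x0028, 0x0100, "US", u16v(bits), explicit),
    dicom_bytes(0x0028, 0x0103, "US", u16v(0L), explicit),
    dicom_bytes(0x3004, 0x000E, "DS", ds(scaling), explicit),
    dicom_bytes(0x7FE0, 0x0010, "OW", px_payload, explicit)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# A calculated-grid plane carrying the field evaluated at p + shift
# (ground truth for the reverse registration direction).
shifted_calc_plane <- function(field, calc, shift) {
  ys <- plane_rows_mm(calc)
  xs <- plane_cols_mm(calc)
  vals <- outer(ys, xs, Vectorize(function(y, x) {
    spot_dose_at(field, y + shift[2], x + shift[1])
  }))
  dose_plane(vals, calc$spacing, calc$origin, "calculated")
}
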