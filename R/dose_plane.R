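#' Construct a planar dose distribution
#'
#' A `dose_plane` is the common currency of all comparisons in ddmqa: a 2D
#' grid of absolute dose values together with its physical geometry. The
#' coordinate frame is isocenter-centered, in mm, with a pixel-center
#' convention: the physical location of pixel `(i, j)` (0-based) is
#' `origin + c(i * spacing[1], j * spacing[2])`, where axis 1 runs along the
#' matrix rows (the y axis of plots) and axis 2 along the columns (x).
#'
#' @param values Numeric matrix of dose, cGy(RBE). All values must be finite
#'   and non-negative.
#' @param spacing Pixel pitch in mm, `c(row, col)`; a single value is
#'   recycled to both axes.
#' @param origin Physical coordinate (mm) of the center of pixel `(0, 0)`,
#'   `c(row, col)`. Defaults to centering the grid on the isocenter.
#' @param label Free-text provenance tag, e.g. `"measured"`, `"calculated"`
#'   or `"synthetic"`. Must not contain commas (the grid-csv header is
#'   comma-delimited).
#'
#' @return An object of class `dose_plane`.
#' @examples
#' pl <- dose_plane(matrix(100, 5, 5), spacing = 7.62)
#' global_max(pl)
#' @export
dose_plane <- function(values, spacing, origin = NULL, label = "unlabelled") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_ddmqa("`values` must be a numeric matrix.", "ddmqa_geometry_error")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort_ddmqa("dose values must be finite and >= 0.", "ddmqa_geometry_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_ddmqa("`spacing` must be one or two positive pitches in mm.",
                "ddmqa_geometry_error")
  }
  if (is.null(origin)) {
    origin <- -spacing * (dim(values) - 1L) / 2
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin))) {
    abort_ddmqa("`origin` must be two finite mm coordinates (row, col).",
                "ddmqa_geometry_error")
  }
  label <- as.character(label)[1L]
  if (grepl(",", label, fixed = TRUE)) {
    abort_ddmqa("`label` must not contain commas.", "ddmqa_geometry_error")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, label = label),
    class = "dose_plane"
  )
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf(
    "<dose_plane '%s'> %d x %d pixels, pitch %.4g x %.4g mm, origin (%.4g, %.4g) mm, max %.4g cGy(RBE)\n",
    x$label, nrow(x$values), ncol(x$values),
    x$spacing[1], x$spacing[2], x$origin[1], x$origin[2], global_max(x)
  ))
  invisible(x)
}

#' Physical pixel-center coordinates of a plane
#'
#' @param plane A [dose_plane()].
#' @return `plane_rows_mm()` / `plane_cols_mm()`: numeric vectors of the
#'   row-axis (y) and column-axis (x) pixel-center coordinates, mm.
#' @export
plane_rows_mm <- function(plane) {
  plane$origin[1] + (seq_len(nrow(plane$values)) - 1L) * plane$spacing[1]
}

#' @rdname plane_rows_mm
#' @export
plane_cols_mm <- function(plane) {
  plane$origin[2] + (seq_len(ncol(plane$values)) - 1L) * plane$spacing[2]
}

#' Global maximum dose of a plane
#'
#' The normalization value used by global dose-difference criteria.
#'
#' @param plane A [dose_plane()].
#' @return Maximum dose, cGy(RBE).
#' @export
global_max <- function(plane) {
  stopifnot(inherits(plane, "dose_plane"))
  max(plane$values)
}

#' @importFrom tibble as_tibble tibble
#' @exportS3Method tibble::as_tibble
as_tibble.dose_plane <- function(x, ...) {
  nr <- nrow(x$values)
  nc <- ncol(x$values)
  tibble::tibble(
    row = rep(seq_len(nr) - 1L, times = nc),
    col = rep(seq_len(nc) - 1L, each = nr),
    y_mm = rep(plane_rows_mm(x), times = nc),
    x_mm = rep(plane_cols_mm(x), each = nr),
    dose_cgy = as.vector(x$values)
  )
}

#' Bilinear interpolation of a plane at arbitrary physical points
#'
#' Values outside the plane's pixel-center bounding box are `NA`.
#'
#' @param plane A [dose_plane()].
#' @param y_mm,x_mm Numeric vectors (same length) of row-axis / column-axis
#'   coordinates, mm.
#' @return Numeric vector of interpolated dose values.
#' @export
interp_plane <- function(plane, y_mm, x_mm) {
  stopifnot(inherits(plane, "dose_plane"), length(y_mm) == length(x_mm))
  ys <- plane_rows_mm(plane)
  xs <- plane_cols_mm(plane)
  if (length(ys) == 1L && length(xs) == 1L) {
    out <- rep(NA_real_, length(y_mm))
    hit <- abs(y_mm - ys) < 1e-9 & abs(x_mm - xs) < 1e-9
    out[hit] <- plane$values[1L, 1L]
    return(out)
  }
  out <- rep(NA_real_, length(y_mm))
  inside <- y_mm >= ys[1] - 1e-9 & y_mm <= ys[length(ys)] + 1e-9 &
    x_mm >= xs[1] - 1e-9 & x_mm <= xs[length(xs)] + 1e-9
  if (any(inside)) {
    out[inside] <- pracma::interp2(
      x = xs, y = ys, Z = plane$values,
      xp = pmin(pmax(x_mm[inside], xs[1]), xs[length(xs)]),
      yp = pmin(pmax(y_mm[inside], ys[1]), ys[length(ys)]),
      method = "linear"
    )
  }
  out
}

#' Resample the calculated plane onto the fine search grid
#'
#' Bilinear interpolation onto a finer grid covering exactly the same
#' physical bounding box (pixel centers from first to last center on each
#' axis). Only calculated planes should ever be resampled; measured pixels
#' are compared as-is, without interpolation.
#'
#' @param plane A [dose_plane()] (typically the TPS calculation).
#' @param target_spacing_mm Requested pitch of the search grid, mm; must be
#'   positive and no larger than the plane's current pitch. The realized
#'   pitch is adjusted per axis so the physical extent is spanned exactly
#'   (e.g. a 100 mm extent at a 0.1 mm request keeps 0.1 mm exactly).
#' @return A [dose_plane()] on the fine grid, same label.
#' @export
resample_to_search_grid <- function(plane, target_spacing_mm) {
  stopifnot(inherits(plane, "dose_plane"))
  if (!is_number(target_spacing_mm) || target_spacing_mm <= 0) {
    abort_ddmqa("`target_spacing_mm` must be a positive number.",
                "ddmqa_config_error")
  }
  if (target_spacing_mm > min(plane$spacing) + 1e-12) {
    abort_ddmqa("`target_spacing_mm` must not exceed the plane's pitch.",
                "ddmqa_config_error")
  }
  axis_new <- function(n, pitch) {
    if (n == 1L) return(list(n = 1L, pitch = pitch))
    extent <- (n - 1L) * pitch
    n_new <- max(2L, as.integer(round(extent / target_spacing_mm)) + 1L)
    list(n = n_new, pitch = extent / (n_new - 1L))
  }
  ar <- axis_new(nrow(plane$values), plane$spacing[1])
  ac <- axis_new(ncol(plane$values), plane$spacing[2])
  yn <- plane$origin[1] + (seq_len(ar$n) - 1L) * ar$pitch
  xn <- plane$origin[2] + (seq_len(ac$n) - 1L) * ac$pitch
  grid_y <- rep(yn, times = ac$n)
  grid_x <- rep(xn, each = ar$n)
  vals <- interp_plane(plane, grid_y, grid_x)
  dose_plane(
    matrix(vals, nrow = ar$n, ncol = ac$n),
    spacing = c(ar$pitch, ac$pitch),
    origin = plane$origin,
    label = plane$label
  )
}

#' Local dose-gradient magnitude of a plane
#'
#' Central differences in the interior, one-sided at the edges.
#'
#' @param plane A [dose_plane()].
#' @return Matrix of gradient magnitudes, cGy(RBE)/mm, same shape as the
#'   plane.
#' @export
plane_gradient <- function(plane) {
  stopifnot(inherits(plane, "dose_plane"))
  v <- plane$values
  nr <- nrow(v)
  nc <- ncol(v)
  gy <- matrix(0, nr, nc)
  gx <- matrix(0, nr, nc)
  if (nr > 1L) {
    if (nr > 2L) {
      gy[2:(nr - 1), ] <- (v[3:nr, , drop = FALSE] - v[1:(nr - 2), , drop = FALSE]) /
        (2 * plane$spacing[1])
    }
    gy[1, ] <- (v[2, ] - v[1, ]) / plane$spacing[1]
    gy[nr, ] <- (v[nr, ] - v[nr - 1, ]) / plane$spacing[1]
  }
  if (nc > 1L) {
    if (nc > 2L) {
      gx[, 2:(nc - 1)] <- (v[, 3:nc, drop = FALSE] - v[, 1:(nc - 2), drop = FALSE]) /
        (2 * plane$spacing[2])
    }
    gx[, 1] <- (v[, 2] - v[, 1]) / plane$spacing[2]
    gx[, nc] <- (v[, nc] - v[, nc - 1]) / plane$spacing[2]
  }
  sqrt(gy^2 + gx^2)
}
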