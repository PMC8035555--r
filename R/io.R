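#' Read a planar dose file
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`grid-csv`}{An open plain-text format: a 3-line header with keys
#'     `spacing_mm`, `origin_mm` and `label`, then comma-separated dose rows.
#'     See [write_dose_plane()].}
#'   \item{`dicom-rt-dose`}{A single-frame DICOM RT Dose file (little-endian,
#'     explicit or implicit VR). Stored pixel values are multiplied by the
#'     file's Dose Grid Scaling; Pixel Spacing and Image Position (Patient)
#'     populate the geometry. Missing geometry is an error — there are no
#'     silent defaults.}
#' }
#'
#' @param path Path to the file.
#' @param format One of `"grid-csv"`, `"dicom-rt-dose"`, or `"auto"` (the
#'   default: DICOM is recognized by its `DICM` magic, anything else is
#'   treated as grid-csv).
#' @return A [dose_plane()].
#' @export
read_dose_plane <- function(path, format = c("auto", "grid-csv", "dicom-rt-dose")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_ddmqa(paste0("file not found: ", path), "ddmqa_format_error")
  }
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 132L)
    format <- if (length(magic) == 132L &&
                  rawToChar(magic[129:132]) == "DICM") "dicom-rt-dose" else "grid-csv"
  }
  switch(format,
    "grid-csv" = read_grid_csv(path),
    "dicom-rt-dose" = read_dicom_rt_dose(path)
  )
}

#' Write a plane to the grid-csv format
#'
#' The open plain-text dialect used throughout ddmqa: three header lines
#' (`spacing_mm,<row>,<col>`, `origin_mm,<row>,<col>`, `label,<text>`)
#' followed by one comma-separated line per pixel row. Doses are written
#' with 17 significant digits so the write/read round trip is bit-faithful.
#'
#' @param plane A [dose_plane()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_plane <- function(plane, path) {
  stopifnot(inherits(plane, "dose_plane"))
  num <- function(x) sprintf("%.17g", x)
  header <- c(
    paste0("spacing_mm,", num(plane$spacing[1]), ",", num(plane$spacing[2])),
    paste0("origin_mm,", num(plane$origin[1]), ",", num(plane$origin[2])),
    paste0("label,", plane$label)
  )
  body <- apply(plane$values, 1L, function(r) paste(num(r), collapse = ","))
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_ddmqa(paste0("cannot write: ", path), "ddmqa_format_error")
  invisible(path)
}

read_grid_csv <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (is.null(lines) || length(lines) < 4L) {
    abort_ddmqa("grid-csv needs a 3-line header and at least one dose row.",
                "ddmqa_format_error")
  }
  header_num <- function(line, key, n) {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) != n + 1L || parts[1] != key) {
      abort_ddmqa(sprintf("grid-csv header line '%s' expected, got '%s'.",
                          key, line), "ddmqa_geometry_error")
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(vals))) {
      abort_ddmqa(sprintf("non-numeric %s header.", key), "ddmqa_geometry_error")
    }
    vals
  }
  spacing <- header_num(lines[1], "spacing_mm", 2L)
  origin <- header_num(lines[2], "origin_mm", 2L)
  lab_parts <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  if (lab_parts[1] != "label") {
    abort_ddmqa("grid-csv third header line must be 'label,<text>'.",
                "ddmqa_geometry_error")
  }
  label <- if (length(lab_parts) >= 2L) lab_parts[2] else "unlabelled"
  rows <- lapply(lines[-(1:3)], function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, ",", fixed = TRUE)[[1]]))
    if (any(is.na(v))) {
      abort_ddmqa("non-numeric dose row in grid-csv.", "ddmqa_format_error")
    }
    v
  })
  if (length(unique(lengths(rows))) != 1L) {
    abort_ddmqa("ragged dose rows in grid-csv.", "ddmqa_format_error")
  }
  dose_plane(do.call(rbind, rows), spacing = spacing, origin = origin,
             label = label)
}
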