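# Minimal single-frame DICOM RT Dose reader.
#
# Only what a planar RT Dose export needs: Part-10 files, little-endian
# transfer syntaxes (explicit 1.2.840.10008.1.2.1 and implicit
# 1.2.840.10008.1.2), uncompressed 16- or 32-bit unsigned pixel data.
# Undefined-length (0xFFFFFFFF) elements are rejected rather than parsed.

DICOM_TAGS <- list(
  transfer_syntax = c(0x0002L, 0x0010L),
  rows            = c(0x0028L, 0x0010L),
  cols            = c(0x0028L, 0x0011L),
  pixel_spacing   = c(0x0028L, 0x0030L),
  bits_allocated  = c(0x0028L, 0x0100L),
  pixel_rep       = c(0x0028L, 0x0103L),
  position        = c(0x0020L, 0x0032L),
  dose_scaling    = c(0x3004L, 0x000EL),
  pixel_data      = c(0x7FE0L, 0x0010L)
)

#' Read a single-frame DICOM RT Dose plane
#'
#' Stored integer pixels are multiplied by Dose Grid Scaling (3004,000E);
#' Pixel Spacing (0028,0030) gives the row/column pitch and Image Position
#' (Patient) (0020,0032) the in-plane coordinate of the first pixel center.
#'
#' @param path Path to a DICOM file.
#' @return A [dose_plane()] labelled `"calculated"`.
#' @export
read_dicom_rt_dose <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM") {
    abort_ddmqa("not a Part-10 DICOM file (missing DICM magic).",
                "ddmqa_format_error")
  }
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) {
    as.numeric(u16(i)) + 65536 * as.numeric(u16(i + 2L))
  }
  found <- list()
  tag_name <- function(g, e) {
    for (nm in names(DICOM_TAGS)) {
      t <- DICOM_TAGS[[nm]]
      if (t[1] == g && t[2] == e) return(nm)
    }
    NA_character_
  }

  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")
  pos <- 133L
  explicit <- TRUE  # file meta group is always explicit VR
  meta_done <- FALSE
  transfer <- NULL

  while (pos + 7L <= length(raw)) {
    g <- u16(pos)
    e <- u16(pos + 2L)
    if (!meta_done && g != 0x0002L) {
      meta_done <- TRUE
      transfer <- if (is.null(found$transfer_syntax)) {
        "1.2.840.10008.1.2.1"
      } else {
        # UI values may be padded with NUL or space
        trimws(rawToChar(found$transfer_syntax[found$transfer_syntax != 0]))
      }
      if (transfer == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (transfer != "1.2.840.10008.1.2.1") {
        abort_ddmqa(paste0("unsupported transfer syntax: ", transfer),
                    "ddmqa_format_error")
      }
    }
    if (explicit || g == 0x0002L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L)
        hdr <- 12L
      } else {
        len <- as.numeric(u16(pos + 6L))
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L)
      hdr <- 8L
    }
    if (len >= 4294967295) {
      abort_ddmqa("undefined-length DICOM element unsupported.",
                  "ddmqa_format_error")
    }
    start <- pos + hdr
    nm <- tag_name(g, e)
    if (!is.na(nm) && len > 0L) {
      bytes <- raw[start:(start + len - 1L)]
      found[[nm]] <- bytes
    }
    pos <- start + len
  }

  as_string <- function(bytes) trimws(rawToChar(bytes))
  as_ds <- function(bytes) as.numeric(strsplit(as_string(bytes), "\\", fixed = TRUE)[[1]])
  as_us <- function(bytes) as.integer(bytes[1]) + 256L * as.integer(bytes[2])
  found$transfer_syntax <- if (!is.null(found$transfer_syntax)) {
    as_string(found$transfer_syntax)
  }

  need <- c("rows", "cols", "bits_allocated", "dose_scaling", "pixel_data")
  missing_tags <- setdiff(need, names(found))
  if (length(missing_tags)) {
    abort_ddmqa(paste0("DICOM RT Dose missing required element(s): ",
                       paste(missing_tags, collapse = ", ")),
                "ddmqa_format_error")
  }
  if (is.null(found$pixel_spacing) || is.null(found$position)) {
    abort_ddmqa("DICOM RT Dose lacks geometry (Pixel Spacing / Image Position).",
                "ddmqa_geometry_error")
  }

  nr <- as_us(found$rows)
  nc <- as_us(found$cols)
  bits <- as_us(found$bits_allocated)
  scaling <- as_ds(found$dose_scaling)[1]
  spacing <- as_ds(found$pixel_spacing)  # row pitch, col pitch
  ipp <- as_ds(found$position)           # x (col axis), y (row axis), z
  if (length(spacing) < 2L || length(ipp) < 2L) {
    abort_ddmqa("malformed DICOM geometry element.", "ddmqa_geometry_error")
  }

  px_raw <- found$pixel_data
  if (bits == 16L) {
    if (length(px_raw) < 2L * nr * nc) {
      abort_ddmqa("DICOM pixel data shorter than Rows x Columns.",
                  "ddmqa_format_error")
    }
    px <- readBin(px_raw, "integer", n = nr * nc, size = 2L,
                  signed = FALSE, endian = "little")
    px <- as.numeric(px)
  } else if (bits == 32L) {
    if (length(px_raw) < 4L * nr * nc) {
      abort_ddmqa("DICOM pixel data shorter than Rows x Columns.",
                  "ddmqa_format_error")
    }
    px <- readBin(px_raw, "integer", n = nr * nc, size = 4L, endian = "little")
    px <- as.numeric(px)
    px[px < 0] <- px[px < 0] + 4294967296
  } else {
    abort_ddmqa("only 16- or 32-bit DICOM pixel data supported.",
                "ddmqa_format_error")
  }

  values <- matrix(px * scaling, nrow = nr, ncol = nc, byrow = TRUE)
  dose_plane(values, spacing = spacing[1:2], origin = c(ipp[2], ipp[1]),
             label = "calculated")
}
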