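# Reading mammography-style source images: monochrome uncompressed DICOM
# (explicit or implicit VR, little endian) or grayscale PNG fixtures.  The
# DICOM parser is deliberately minimal: single-frame, single-sample,
# uncompressed transfer syntaxes only, which covers presentation-state-free
# screening mammograms and the package's fixtures.

morfse_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "morfse_error")))
}

#' Construct a source-image object
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param patient_id,image_id Identifier strings.
#' @param bit_depth Stored bit depth of the source file.
#' @return An object of class `source_image`.
#' @export
source_image <- function(pixels, patient_id, image_id, bit_depth = 8L) {
  stopifnot(is.matrix(pixels))
  if (anyNA(pixels) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    morfse_error("source image intensities must lie in [0, 1]", "morfse_format_error")
  structure(list(pixels = pixels, patient_id = as.character(patient_id),
                 image_id = as.character(image_id),
                 bit_depth = as.integer(bit_depth)),
            class = "source_image")
}

#' @export
print.source_image <- function(x, ...) {
  cat(sprintf("<source_image %s: %dx%d, %d-bit, patient %s>\n", x$image_id,
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$patient_id))
  invisible(x)
}

#' Read a source mammogram
#'
#' Dispatches on file extension: `.dcm`/`.dicom` through the built-in
#' monochrome DICOM parser, anything else through [png::readPNG()].
#' Intensities are rescaled to `[0, 1]` using the stored bit depth.
#'
#' @param path File path.
#' @param patient_id,image_id Optional identifier overrides (PNG fixtures
#'   carry no embedded IDs; DICOM IDs come from the PatientID and
#'   SOPInstanceUID tags when present).
#' @return A [source_image()].
#' @export
read_source_image <- function(path, patient_id = NULL, image_id = NULL) {
  if (!file.exists(path))
    morfse_error(paste0("no such file: ", path), "morfse_format_error")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("dcm", "dicom")) read_dicom_image(path)
         else read_png_image(path)
  if (!is.null(patient_id)) img$patient_id <- as.character(patient_id)
  if (!is.null(image_id)) img$image_id <- as.character(image_id)
  img
}

read_png_image <- function(path) {
  pix <- tryCatch(png::readPNG(path), error = function(e)
    morfse_error(paste0("cannot read PNG ", path, ": ", conditionMessage(e)),
                 "morfse_format_error"))
  if (length(dim(pix)) == 3) {
    if (dim(pix)[3] > 2)           # color PNG: not a mammography fixture
      morfse_error("color PNG is not a supported source image",
                   "morfse_unsupported_modality")
    pix <- pix[, , 1]
  }
  source_image(pix, patient_id = NA_character_,
               image_id = tools::file_path_sans_ext(basename(path)),
               bit_depth = 8L)
}

# --- minimal DICOM ----------------------------------------------------------

# DICOM strings are padded with spaces or NUL bytes
dcm_string <- function(v) trimws(rawToChar(v[v != as.raw(0)]))

dcm_uint16 <- function(raw, i) {
  as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
}
dcm_uint32 <- function(raw, i) {
  as.double(raw[i]) + 256 * as.double(raw[i + 1L]) +
    65536 * as.double(raw[i + 2L]) + 16777216 * as.double(raw[i + 3L])
}

read_dicom_image <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    morfse_error(paste0(path, ": not a DICOM file (missing DICM magic)"),
                 "morfse_format_error")
  elems <- tryCatch(dcm_parse_elements(raw),
                    error = function(e) if (inherits(e, "morfse_error")) stop(e) else
                      morfse_error(paste0(path, ": ", conditionMessage(e)),
                                   "morfse_format_error"))
  get_el <- function(tag) elems[[tag]]
  str_el <- function(tag) {
    v <- get_el(tag)
    if (is.null(v)) return(NA_character_)
    dcm_string(v)
  }
  us_el <- function(tag) {
    v <- get_el(tag)
    if (is.null(v)) return(NA_integer_)
    dcm_uint16(v, 1L)
  }
  spp <- us_el("0028,0002")
  if (!is.na(spp) && spp != 1L)
    morfse_error("color (multi-sample) DICOM is unsupported",
                 "morfse_unsupported_modality")
  nframes <- suppressWarnings(as.integer(str_el("0028,0008")))
  if (!is.na(nframes) && nframes > 1L)
    morfse_error("multi-frame DICOM is unsupported", "morfse_unsupported_modality")
  rows <- us_el("0028,0010"); cols <- us_el("0028,0011")
  ba <- us_el("0028,0100"); bs <- us_el("0028,0101")
  if (is.na(bs)) bs <- ba
  pixel <- get_el("7fe0,0010")
  if (is.na(rows) || is.na(cols) || is.na(ba) || is.null(pixel))
    morfse_error(paste0(path, ": missing image geometry or pixel data"),
                 "morfse_format_error")
  npix <- rows * cols
  if (ba == 8L) {
    if (length(pixel) < npix)
      morfse_error(paste0(path, ": truncated pixel data"), "morfse_format_error")
    vals <- as.integer(pixel[seq_len(npix)])
  } else if (ba == 16L) {
    if (length(pixel) < 2 * npix)
      morfse_error(paste0(path, ": truncated pixel data"), "morfse_format_error")
    signed <- identical(us_el("0028,0103"), 1L)
    vals <- readBin(pixel, "integer", n = npix, size = 2L, signed = signed,
                    endian = "little")
  } else {
    morfse_error(paste0("unsupported BitsAllocated: ", ba),
                 "morfse_unsupported_modality")
  }
  pix <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE) / (2^bs - 1)
  photo <- str_el("0028,0004")
  if (!is.na(photo) && photo == "MONOCHROME1") pix <- 1 - pix
  pix <- pmin(pmax(pix, 0), 1)
  source_image(pix,
               patient_id = str_el("0010,0020"),
               image_id = if (is.na(str_el("0008,0018")))
                 tools::file_path_sans_ext(basename(path)) else str_el("0008,0018"),
               bit_depth = bs)
}

# Parse the data elements of an uncompressed little-endian DICOM stream into
# a named list tag -> raw value.  The file meta group (0002) is always
# explicit VR; the main dataset follows the declared transfer syntax.
dcm_parse_elements <- function(raw) {
  n <- length(raw)
  pos <- 133L                      # first byte after the DICM magic
  elems <- list()
  explicit <- TRUE
  ts_checked <- FALSE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- dcm_uint16(raw, pos); elem <- dcm_uint16(raw, pos + 2L)
    if (!ts_checked && group != 2L) {
      # leaving the meta header: fix the dataset's transfer syntax
      ts <- elems[["0002,0010"]]
      ts <- if (is.null(ts)) "1.2.840.10008.1.2.1" else dcm_string(ts)
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        morfse_error(paste0("unsupported transfer syntax ", ts,
                            " (compressed or big-endian)"),
                     "morfse_unsupported_modality")
      ts_checked <- TRUE
    }
    use_explicit <- if (group == 2L) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- dcm_uint32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- dcm_uint16(raw, pos + 6L); hdr <- 8L
      }
      if (vr == "SQ" || len == 4294967295)
        morfse_error("DICOM sequences / undefined lengths are unsupported",
                     "morfse_unsupported_modality")
    } else {
      len <- dcm_uint32(raw, pos + 4L); hdr <- 8L
      if (len == 4294967295)
        morfse_error("DICOM undefined lengths are unsupported",
                     "morfse_unsupported_modality")
    }
    if (pos + hdr + len - 1L > n)
      morfse_error("truncated DICOM element", "morfse_format_error")
    tag <- sprintf("%04x,%04x", group, elem)
    elems[[tag]] <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    pos <- pos + hdr + as.integer(len)
  }
  elems
}
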