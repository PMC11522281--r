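# Minimal single-frame grayscale DICOM reader.
#
# Supports Part-10 files with a standard 128-byte preamble and the two
# uncompressed little-endian transfer syntaxes (implicit VR 1.2.840.10008.1.2
# and explicit VR 1.2.840.10008.1.2.1). Rescale slope/intercept and
# PixelSpacing are honoured; color, multi-frame and compressed files are
# rejected. This deliberately covers only what the pipeline ingests; it is
# not a general DICOM toolkit.

.TS_IMPLICIT <- "1.2.840.10008.1.2"
.TS_EXPLICIT <- "1.2.840.10008.1.2.1"

.u16 <- function(raw, i) {
  as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
}

.u32 <- function(raw, i) {
  as.numeric(raw[i]) + 256 * as.numeric(raw[i + 1L]) +
    65536 * as.numeric(raw[i + 2L]) + 16777216 * as.numeric(raw[i + 3L])
}

# VRs carrying a 2-byte reserved field + 4-byte length in explicit mode
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a single-frame grayscale DICOM file
#'
#' Parses the element stream, applies RescaleSlope/RescaleIntercept, min-max
#' normalizes the result to \[0, 1\] and picks up PixelSpacing (first value)
#' when present, else 1 mm.
#'
#' @param path path to a DICOM Part-10 file.
#' @return A [GrayImage-class].
#' @keywords internal
readDicomGray <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  n <- length(raw)

  readElement <- function(pos, explicit) {
    group <- .u16(raw, pos); elem <- .u16(raw, pos + 2L)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .LONG_VRS) {
        len <- .u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- .u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- .u32(raw, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements unsupported")
    list(group = group, elem = elem, vr = vr, len = len,
         start = pos + hdr, next_ = pos + hdr + as.integer(len))
  }

  tags <- list()
  keyOf <- function(group, elem) sprintf("%04x,%04x", group, elem)

  # file meta group: always explicit VR little endian
  ts <- NA_character_
  while (pos + 7L <= n) {
    el <- readElement(pos, explicit = TRUE)
    if (el$group != 2L) break
    if (el$elem == 0x0010) {
      ts <- sub("\\x00+$", "", rawToChar(raw[el$start:(el$next_ - 1L)]))
      ts <- trimws(ts)
    }
    pos <- el$next_
  }
  if (is.na(ts)) stop("missing TransferSyntaxUID in DICOM meta header")
  if (!ts %in% c(.TS_IMPLICIT, .TS_EXPLICIT))
    stop("unsupported DICOM transfer syntax: ", ts)
  explicit <- identical(ts, .TS_EXPLICIT)

  pixelRaw <- NULL
  while (pos + 7L <= n) {
    el <- readElement(pos, explicit)
    if (el$len > 0 && el$next_ - 1L > n) stop("truncated DICOM element")
    if (el$group == 0x7fe0 && el$elem == 0x0010) {
      pixelRaw <- raw[el$start:(el$next_ - 1L)]
    } else if (el$len > 0 && !identical(el$vr, "SQ")) {
      tags[[keyOf(el$group, el$elem)]] <- raw[el$start:(el$next_ - 1L)]
    }
    pos <- el$next_
  }

  getStr <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NA_character_)
    trimws(sub("\\x00+$", "", rawToChar(v)))
  }
  getU16 <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NA_integer_)
    .u16(v, 1L)
  }

  samples <- getU16("0028,0002")
  if (!is.na(samples) && samples > 1)
    stop("color DICOM (SamplesPerPixel > 1) is unsupported")
  frames <- suppressWarnings(as.integer(getStr("0028,0008")))
  if (!is.na(frames) && frames > 1)
    stop("multi-frame DICOM is unsupported")

  rows <- getU16("0028,0010"); cols <- getU16("0028,0011")
  bits <- getU16("0028,0100")
  if (is.na(rows) || is.na(cols) || is.na(bits))
    stop("DICOM file lacks Rows/Columns/BitsAllocated")
  if (!bits %in% c(8L, 16L)) stop("only 8/16-bit DICOM pixels supported")
  signed <- identical(getU16("0028,0103"), 1L)
  if (is.null(pixelRaw)) stop("DICOM file has no PixelData")
  need <- rows * cols * (bits / 8L)
  if (length(pixelRaw) < need) stop("PixelData shorter than Rows x Columns")

  if (bits == 8L) {
    vals <- as.integer(pixelRaw[seq_len(need)])
    if (signed) vals <- ifelse(vals > 127L, vals - 256L, vals)
  } else {
    vals <- readBin(pixelRaw, what = "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
    if (!signed) vals <- ifelse(vals < 0L, vals + 65536L, vals)
  }

  slope <- suppressWarnings(as.numeric(getStr("0028,1053")))
  intercept <- suppressWarnings(as.numeric(getStr("0028,1052")))
  if (is.na(slope)) slope <- 1
  if (is.na(intercept)) intercept <- 0
  m <- matrix(vals * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)

  spacingStr <- getStr("0028,0030")
  spacing <- 1
  if (!is.na(spacingStr) && nzchar(spacingStr)) {
    sp <- suppressWarnings(as.numeric(strsplit(spacingStr, "\\\\")[[1]][1]))
    if (!is.na(sp) && sp > 0) spacing <- sp
    else message("unparseable PixelSpacing in ", path, "; using 1 mm")
  } else {
    message("no PixelSpacing in ", path, "; using 1 mm")
  }

  GrayImage(normalizeImage(m), spacingMm = spacing, sourceId = basename(path))
}
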