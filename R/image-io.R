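#' Min-max normalize a raster to \[0, 1\]
#'
#' A constant raster (max == min) normalizes to all zeros with a warning.
#' Normalization is idempotent on already-\[0, 1\] full-range rasters and is
#' a monotone (order-preserving) map of the raw intensities.
#'
#' @param m numeric matrix.
#' @return Matrix with values in \[0, 1\].
#' @export
normalizeImage <- function(m) {
  m <- asPixelMatrix(m)
  rng <- range(m)
  if (rng[1] == rng[2]) {
    warning("constant image normalized to all zeros")
    return(matrix(0, nrow(m), ncol(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

# ITU-R BT.601 luminance weights for RGB inputs
.lumaWeights <- c(0.299, 0.587, 0.114)

#' Read a grayscale image (PNG or DICOM) into a GrayImage
#'
#' PNG files (8/16-bit, gray or RGB) are read with \pkg{png}; RGB is
#' converted to BT.601 luminance and any alpha channel is dropped. DICOM
#' files go through the minimal single-frame reader, which applies the
#' rescale slope/intercept and picks up PixelSpacing. In both cases the
#' result is min-max normalized to \[0, 1\].
#'
#' @param path input file.
#' @param formatHint `"auto"` (default; decided by magic bytes, then
#'   extension), `"png"` or `"dicom"`.
#' @param spacingMm spacing override for PNG inputs (default 1 mm).
#' @return A [GrayImage-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(seq(0, 1, length.out = 256), 16, 16), f)
#' readImage(f)
readImage <- function(path, formatHint = c("auto", "png", "dicom"),
                      spacingMm = 1) {
  formatHint <- match.arg(formatHint)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- formatHint
  if (fmt == "auto") {
    head <- readBin(path, "raw", n = 132)
    if (length(head) >= 8 &&
        identical(head[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                      0x0d, 0x0a, 0x1a, 0x0a)))) {
      fmt <- "png"
    } else if (length(head) >= 132 && rawToChar(head[129:132]) == "DICM") {
      fmt <- "dicom"
    } else if (grepl("\\.(dcm|dicom)$", tolower(path))) {
      fmt <- "dicom"
    } else {
      fmt <- "png"
    }
  }
  if (fmt == "dicom") return(readDicomGray(path))
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      arr <- .lumaWeights[1] * arr[, , 1] + .lumaWeights[2] * arr[, , 2] +
        .lumaWeights[3] * arr[, , 3]
    } else {
      arr <- arr[, , 1]  # gray + alpha
    }
  }
  GrayImage(normalizeImage(arr), spacingMm = spacingMm,
            sourceId = basename(path))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground maps to 255, background to 0; [readMask()] reproduces the mask
#' exactly.
#'
#' @param mask a [BinaryMask-class] (or 0/1 matrix).
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  m <- asPixelMatrix(mask)
  if (!all(m %in% c(0, 1))) stop("mask values must be 0/1")
  png::writePNG(m * 1.0, target = path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' Pixels with raw value > 127 map to 1, all others to 0.
#'
#' @param path PNG file.
#' @param spacingMm spacing to attach (default 1 mm).
#' @return A [BinaryMask-class].
#' @export
readMask <- function(path, spacingMm = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  BinaryMask((round(arr * 255) > 127) * 1L, spacingMm = spacingMm)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param image a [GrayImage-class] or \[0, 1\] matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGrayPNG <- function(image, path) {
  m <- asPixelMatrix(image)
  png::writePNG(pmin(pmax(m, 0), 1), target = path)
  invisible(path)
}

#' Write a diagnostic overlay of a mask boundary on an image
#'
#' Produces an RGB PNG in which the mask's internal boundary (mask pixels
#' with at least one 4-neighbour outside the mask, or on the image frame) is
#' drawn in red. With an empty mask the output is the grayscale image
#' replicated to three channels.
#'
#' @param image a [GrayImage-class].
#' @param mask a [BinaryMask-class] of the same shape.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
overlayMask <- function(image, mask, path) {
  img <- asPixelMatrix(image)
  m <- asPixelMatrix(mask)
  if (!all(dim(img) == dim(m)))
    stop("image and mask shapes differ: ", paste(dim(img), collapse = "x"),
         " vs ", paste(dim(m), collapse = "x"))
  boundary <- maskBoundary(m)
  rgb <- array(rep(img, 3), dim = c(dim(img), 3))
  rgb[, , 1][boundary] <- 1
  rgb[, , 2][boundary] <- 0
  rgb[, , 3][boundary] <- 0
  png::writePNG(rgb, target = path)
  invisible(path)
}

#' Internal: interior boundary of a 0/1 matrix (4-connectivity)
#' @noRd
maskBoundary <- function(m) {
  fg <- m > 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- fg[rs[ok_r], cs[ok_c]]
    out
  }
  inner <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  fg & !inner
}
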