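# In-code DICOM fixture writer (explicit or implicit VR little endian),
# matching what the package's minimal reader supports. Fixtures are built
# at test time; nothing binary is stored in the repository.

.rawU16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
.rawU32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256,
                                (x %/% 16777216) %% 256))

.padEven <- function(v, padByte = 0x20) {
  if (length(v) %% 2) c(v, as.raw(padByte)) else v
}

dicomElement <- function(group, elem, vr, value, explicit = TRUE) {
  v <- if (is.character(value)) {
    .padEven(charToRaw(value), if (vr == "UI") 0x00 else 0x20)
  } else value
  hdr <- c(.rawU16(group), .rawU16(elem))
  if (explicit) {
    hdr <- c(hdr, charToRaw(vr))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      c(hdr, as.raw(c(0, 0)), .rawU32(length(v)), v)
    } else {
      c(hdr, .rawU16(length(v)), v)
    }
  } else {
    c(hdr, .rawU32(length(v)), v)
  }
}

pixelBytes <- function(pix, bits) {
  vals <- as.integer(t(pix))  # DICOM stores rows sequentially
  if (bits == 8) as.raw(vals)
  else writeBin(vals, raw(), size = 2L, endian = "little")
}

writeDicomFixture <- function(path, pix, bits = 16, explicit = TRUE,
                              spacing = NULL, slope = NULL, intercept = NULL,
                              samplesPerPixel = NULL, numberOfFrames = NULL) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  out <- c(raw(128), charToRaw("DICM"),
           dicomElement(0x0002, 0x0010, "UI", ts, explicit = TRUE))
  el <- function(group, elem, vr, value)
    dicomElement(group, elem, vr, value, explicit = explicit)
  if (!is.null(samplesPerPixel))
    out <- c(out, el(0x0028, 0x0002, "US", .rawU16(samplesPerPixel)))
  if (!is.null(numberOfFrames))
    out <- c(out, el(0x0028, 0x0008, "IS", as.character(numberOfFrames)))
  out <- c(out, el(0x0028, 0x0010, "US", .rawU16(nrow(pix))))
  out <- c(out, el(0x0028, 0x0011, "US", .rawU16(ncol(pix))))
  if (!is.null(spacing))
    out <- c(out, el(0x0028, 0x0030, "DS",
                     paste(format(spacing), collapse = "\\")))
  out <- c(out, el(0x0028, 0x0100, "US", .rawU16(bits)))
  out <- c(out, el(0x0028, 0x0103, "US", .rawU16(0)))
  if (!is.null(intercept))
    out <- c(out, el(0x0028, 0x1052, "DS", as.character(intercept)))
  if (!is.null(slope))
    out <- c(out, el(0x0028, 0x1053, "DS", as.character(slope)))
  out <- c(out, dicomElement(0x7fe0, 0x0010, "OW", pixelBytes(pix, bits),
                             explicit = explicit))
  writeBin(out, path)
  invisible(path)
}
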