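# Seeded synthetic brain phantom generator.
#
# A phantom is an elliptical "head" of base intensity 0.5 over a dark
# (0.05) background, plus a smooth correlated tissue texture, plus an
# optional bright tumor disc, plus iid Gaussian noise, clipped to [0, 1].
# Generation is a pure function of (spec, seed): identical specs give
# bit-identical rasters.

#' Internal: evaluate code under a temporary RNG seed, restoring global state
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Construct a PhantomSpec
#'
#' Defaults describe a 256 x 256 axial-slice-like phantom at 1 mm spacing
#' with a 16 mm tumor of contrast 0.3 over tissue texture of SD 0.05 and
#' pixel noise of SD 0.02.
#'
#' @param size (rows, cols), default c(256, 256).
#' @param spacingMm pixel edge in mm, default 1.
#' @param headAxes ellipse semi-axes (row, col) in pixels; default scales
#'   with the image (0.42 and 0.36 of the axes).
#' @param tissueTextureSd SD of the smooth tissue variation, default 0.05.
#' @param textureCorrelationPx texture correlation length, default 16 px.
#' @param tumorPresent logical, default TRUE.
#' @param tumorCenter (row, col); default upper-right of center.
#' @param tumorDiameterMm default 16.
#' @param tumorContrast default 0.3.
#' @param noiseSd default 0.02.
#' @param seed integer, default 1.
#' @return A [PhantomSpec-class].
#' @export
#' @examples
#' spec <- PhantomSpec(seed = 7)
#' ph <- makePhantom(spec)
#' sum(pixels(ph$mask))
PhantomSpec <- function(size = c(256, 256), spacingMm = 1,
                        headAxes = c(0.42, 0.36) * size,
                        tissueTextureSd = 0.05, textureCorrelationPx = 16,
                        tumorPresent = TRUE,
                        tumorCenter = round(c(0.40, 0.62) * size),
                        tumorDiameterMm = 16, tumorContrast = 0.3,
                        noiseSd = 0.02, seed = 1) {
  new("PhantomSpec", size = as.integer(size), spacingMm = as.numeric(spacingMm),
      headAxes = as.numeric(headAxes),
      tissueTextureSd = as.numeric(tissueTextureSd),
      textureCorrelationPx = as.numeric(textureCorrelationPx),
      tumorPresent = isTRUE(tumorPresent),
      tumorCenter = as.numeric(tumorCenter),
      tumorDiameterMm = as.numeric(tumorDiameterMm),
      tumorContrast = as.numeric(tumorContrast),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Internal: rasterize a disc with the pixel-corner-centred convention
#'
#' Pixel (i, j) belongs to the disc when its centre lies within radius of
#' the continuous point (r0 + 0.5, c0 + 0.5). This convention keeps the
#' rasterized area close to pi r^2 (80 px for a radius-5 disc, vs 81 for
#' the integer-centre convention).
#' @noRd
discMask <- function(nr, nc, center, radiusPx) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - center[1] - 0.5)^2 + (cc - center[2] - 0.5)^2 <= radiusPx^2
}

#' Generate one phantom image and its ground-truth tumor mask
#'
#' @param spec a [PhantomSpec-class].
#' @return `list(image = GrayImage, mask = BinaryMask)`; the mask is the
#'   exact rasterized tumor disc (all zeros when `tumorPresent` is FALSE).
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  nr <- spec@size[1]; nc <- spec@size[2]
  ctr <- (spec@size + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  head <- ((rr - ctr[1]) / spec@headAxes[1])^2 +
    ((cc - ctr[2]) / spec@headAxes[2])^2 <= 1

  img <- matrix(0.05, nr, nc)
  img[head] <- 0.5

  withSeed(spec@seed, {
    if (spec@tissueTextureSd > 0) {
      tex <- matrix(stats::rnorm(nr * nc), nr, nc)
      tex <- EBImage::gblur(tex, sigma = spec@textureCorrelationPx / 2)
      sdTex <- stats::sd(tex[head])
      if (sdTex > 0) tex <- tex * (spec@tissueTextureSd / sdTex)
      img[head] <- img[head] + tex[head]
    }
    if (spec@tumorPresent) {
      disc <- discMask(nr, nc, spec@tumorCenter,
                       spec@tumorDiameterMm / 2 / spec@spacingMm)
      img[disc] <- img[disc] + spec@tumorContrast
    } else {
      disc <- matrix(FALSE, nr, nc)
    }
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, sd = spec@noiseSd), nr, nc)
  })

  img <- pmin(pmax(img, 0), 1)
  list(image = GrayImage(img, spacingMm = spec@spacingMm,
                         sourceId = sprintf("phantom-seed%d", spec@seed)),
       mask = BinaryMask(disc, spacingMm = spec@spacingMm))
}

#' Internal: derive a per-image seed below 2^31 from (seed, index)
#' @noRd
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 100003 + index * 7919) %% 2147483629)
}

#' Generate a phantom dataset on disk with a manifest
#'
#' Writes `n` image/mask PNG pairs under `outDir` plus `manifest.csv` with
#' columns `image, mask, tumor_present, diameter_mm, contrast, noise_sd,
#' seed`. Exactly `round(n * tumorFraction)` images carry a tumor; tumor
#' center, diameter and contrast are randomized per image within
#' `diameterRangeMm` and `contrastRange`, the center uniform over positions
#' keeping the disc inside the head.
#'
#' @param n number of images.
#' @param tumorFraction proportion in \[0, 1\] of tumor-positive images.
#' @param outDir output directory (created if needed).
#' @param baseSpec template [PhantomSpec-class]; per-image fields are
#'   overridden.
#' @param seed dataset seed; per-image seeds are derived from it.
#' @param diameterRangeMm sampled uniformly, default c(10, 30).
#' @param contrastRange sampled uniformly, default c(0.2, 0.4).
#' @return The manifest as a data.frame (also written as CSV).
#' @export
makeDataset <- function(n, tumorFraction, outDir, baseSpec = PhantomSpec(),
                        seed = 1, diameterRangeMm = c(10, 30),
                        contrastRange = c(0.2, 0.4)) {
  if (n < 1) stop("n must be >= 1")
  if (tumorFraction < 0 || tumorFraction > 1)
    stop("tumorFraction must be in [0, 1]")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  nTumor <- round(n * tumorFraction)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- childSeed(seed, i)
    present <- i <= nTumor
    spec <- baseSpec
    spec@seed <- si
    spec@tumorPresent <- present
    if (present) {
      withSeed(si + 1L, {
        spec@tumorDiameterMm <- stats::runif(1, diameterRangeMm[1],
                                             diameterRangeMm[2])
        spec@tumorContrast <- stats::runif(1, contrastRange[1],
                                           contrastRange[2])
        ctr <- (spec@size + 1) / 2
        radPx <- spec@tumorDiameterMm / 2 / spec@spacingMm
        a <- spec@headAxes[1] - radPx - 1
        b <- spec@headAxes[2] - radPx - 1
        repeat {
          cand <- c(ctr[1] + stats::runif(1, -a, a),
                    ctr[2] + stats::runif(1, -b, b))
          if (((cand[1] - ctr[1]) / a)^2 + ((cand[2] - ctr[2]) / b)^2 < 0.92)
            break
        }
        spec@tumorCenter <- round(cand)
      })
    }
    ph <- makePhantom(spec)
    imgPath <- file.path(outDir, sprintf("phantom_%03d.png", i))
    maskPath <- file.path(outDir, sprintf("phantom_%03d_mask.png", i))
    writeGrayPNG(ph$image, imgPath)
    writeMask(ph$mask, maskPath)
    rows[[i]] <- data.frame(
      image = imgPath, mask = maskPath, tumor_present = present,
      diameter_mm = if (present) spec@tumorDiameterMm else 0,
      contrast = if (present) spec@tumorContrast else 0,
      noise_sd = spec@noiseSd, seed = si, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
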