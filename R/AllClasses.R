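#' @import methods
NULL

.axisMin <- 8L

#' GrayImage: a normalized 2-D intensity raster
#'
#' The pipeline's canonical image container: a rows x cols matrix of
#' intensities in \[0, 1\] together with the physical pixel edge length in
#' millimetres and a free-text provenance label. Coordinates are 0-based
#' conceptually but stored as ordinary R matrices (1-based indexing); row
#' index increases downward.
#'
#' @slot pixels numeric matrix, values in \[0, 1\].
#' @slot spacingMm positive scalar, edge length of one pixel in mm.
#' @slot sourceId character provenance label.
#' @export
setClass("GrayImage", representation(
  pixels = "matrix", spacingMm = "numeric", sourceId = "character"
))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  msg <- character()
  if (!is.numeric(p)) msg <- c(msg, "pixels must be numeric")
  if (nrow(p) < .axisMin || ncol(p) < .axisMin)
    msg <- c(msg, sprintf("image must be at least %d x %d", .axisMin, .axisMin))
  if (anyNA(p)) msg <- c(msg, "pixels must not contain NA")
  else if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    msg <- c(msg, "pixel values must lie in [0, 1]")
  if (length(object@spacingMm) != 1 || !is.finite(object@spacingMm) ||
      object@spacingMm <= 0)
    msg <- c(msg, "spacingMm must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix with values in \[0, 1\].
#' @param spacingMm physical pixel edge in millimetres (default 1).
#' @param sourceId provenance label.
#' @return A [GrayImage-class] object.
#' @export
#' @examples
#' img <- GrayImage(matrix(runif(64), 8, 8))
#' dim(pixels(img))
GrayImage <- function(pixels, spacingMm = 1, sourceId = "unknown") {
  new("GrayImage", pixels = pixels, spacingMm = as.numeric(spacingMm),
      sourceId = as.character(sourceId))
}

#' BinaryMask: a 0/1 raster congruent with a GrayImage
#'
#' @slot pixels numeric or integer matrix of exactly 0s and 1s.
#' @slot spacingMm positive scalar, pixel edge in mm.
#' @export
setClass("BinaryMask", representation(
  pixels = "matrix", spacingMm = "numeric"
))

setValidity("BinaryMask", function(object) {
  p <- object@pixels
  msg <- character()
  if (anyNA(p) || !all(p == 0 | p == 1))
    msg <- c(msg, "mask values must be exactly 0 or 1")
  if (length(object@spacingMm) != 1 || object@spacingMm <= 0)
    msg <- c(msg, "spacingMm must be a positive scalar")
  if (length(msg)) msg else TRUE
}
)

#' Construct a BinaryMask
#'
#' @param pixels matrix of 0/1 (logical matrices are coerced).
#' @param spacingMm physical pixel edge in millimetres (default 1).
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(pixels, spacingMm = 1) {
  if (is.logical(pixels) || (is.numeric(pixels) && all(pixels %in% c(0, 1)))) {
    storage.mode(pixels) <- "integer"
  }
  new("BinaryMask", pixels = pixels, spacingMm = as.numeric(spacingMm))
}

#' GradientMap: a non-negative edge-strength raster
#'
#' Holds the per-pixel gradient magnitude produced by [centralGradient()] or
#' [morphologicalGradient()], congruent with its source image.
#'
#' @slot pixels non-negative numeric matrix.
#' @export
setClass("GradientMap", representation(pixels = "matrix"))

setValidity("GradientMap", function(object) {
  p <- object@pixels
  if (anyNA(p) || min(p) < -1e-12) "gradient values must be >= 0" else TRUE
})

#' @rdname GradientMap-class
#' @param pixels non-negative numeric matrix.
#' @return A `GradientMap`.
#' @export
GradientMap <- function(pixels) new("GradientMap", pixels = pixels)

#' LabelMap: an integer partition of an image into regions
#'
#' Region ids run 1..R and cover every pixel (the watershed implementation
#' assigns every pixel to a catchment basin; no ridge label 0 is emitted).
#'
#' @slot pixels integer matrix of region ids >= 1.
#' @export
setClass("LabelMap", representation(pixels = "matrix"))

setValidity("LabelMap", function(object) {
  p <- object@pixels
  msg <- character()
  if (anyNA(p) || !all(p == as.integer(p)))
    msg <- c(msg, "labels must be integers")
  else if (min(p) < 1) msg <- c(msg, "labels must be >= 1 (no ridge pixels)")
  if (length(msg)) msg else TRUE
})

#' @rdname LabelMap-class
#' @param pixels integer matrix of region ids.
#' @return A `LabelMap`.
#' @export
LabelMap <- function(pixels) {
  storage.mode(pixels) <- "integer"
  new("LabelMap", pixels = pixels)
}

#' Segmentation parameters for the hybrid gradient/watershed stage
#'
#' @slot gradientKind `"morphological"` (window max - min) or `"central"`
#'   (half root-sum-square of central differences).
#' @slot neighborhoodRadius window half-width in pixels (1 = 3 x 3 window).
#' @slot lambdaDepth depth (normalized intensity units) below which regional
#'   minima of the gradient are filled before flooding.
#' @slot lambdaIters number of times the suppression is applied (one
#'   reconstruction already realizes any depth; kept for fidelity).
#' @slot connectivity 4 or 8 (pixel adjacency used throughout).
#' @slot candidateZ z-score threshold on region mean brightness used to pick
#'   candidate tumor regions.
#' @export
setClass("SegmentationParams", representation(
  gradientKind = "character", neighborhoodRadius = "integer",
  lambdaDepth = "numeric", lambdaIters = "integer",
  connectivity = "integer", candidateZ = "numeric"
))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (!object@gradientKind %in% c("morphological", "central"))
    msg <- c(msg, "gradientKind must be 'morphological' or 'central'")
  if (object@neighborhoodRadius < 1L)
    msg <- c(msg, "neighborhoodRadius must be >= 1")
  if (object@lambdaDepth < 0) msg <- c(msg, "lambdaDepth must be >= 0")
  if (object@lambdaIters < 1L) msg <- c(msg, "lambdaIters must be >= 1")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (object@candidateZ <= 0) msg <- c(msg, "candidateZ must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SegmentationParams-class
#' @param gradientKind,neighborhoodRadius,lambdaDepth,lambdaIters,connectivity,candidateZ
#'   see slot documentation.
#' @return A `SegmentationParams` object.
#' @export
SegmentationParams <- function(gradientKind = "morphological",
                               neighborhoodRadius = 1,
                               lambdaDepth = 0.05,
                               lambdaIters = 1,
                               connectivity = 8,
                               candidateZ = 1.5) {
  new("SegmentationParams", gradientKind = gradientKind,
      neighborhoodRadius = as.integer(neighborhoodRadius),
      lambdaDepth = as.numeric(lambdaDepth),
      lambdaIters = as.integer(lambdaIters),
      connectivity = as.integer(connectivity),
      candidateZ = as.numeric(candidateZ))
}

#' OctagonFrame: a regular octagon circumscribing a bounding box
#'
#' @slot center numeric length-2 (row, col), continuous coordinates.
#' @slot circumradius distance from center to each vertex, in pixels.
#' @slot vertices 8 x 2 matrix of (row, col) vertex coordinates, ordered
#'   counter-clockwise starting at 22.5 degrees from the +col axis.
#' @export
setClass("OctagonFrame", representation(
  center = "numeric", circumradius = "numeric", vertices = "matrix"
))

setValidity("OctagonFrame", function(object) {
  msg <- character()
  if (length(object@center) != 2) msg <- c(msg, "center must be (row, col)")
  if (object@circumradius <= 0) msg <- c(msg, "circumradius must be > 0")
  if (!all(dim(object@vertices) == c(8, 2)))
    msg <- c(msg, "vertices must be an 8 x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' SectorMap: the 8-sector partition of a bounding box
#'
#' Pixels of the box are binned by angle into the 8 center-to-vertex
#' triangles of the circumscribing octagon; ids 1..8 run counter-clockwise,
#' boundary ties go to the lower id.
#'
#' @slot bbox integer length-4 (r0, r1, c0, c1), inclusive.
#' @slot ids integer matrix (box height x box width) of sector ids 1..8.
#' @export
setClass("SectorMap", representation(bbox = "integer", ids = "matrix"))

#' NarrowingState: progress record of the octagon narrowing iteration
#'
#' @slot bbox current bounding box (r0, r1, c0, c1) in image coordinates.
#' @slot stage stages completed so far.
#' @slot history per-stage list: bbox, per-sector signals and scores, the
#'   selected sector and its signal.
#' @slot stopDiameterMm physical stopping scale (default 3 mm).
#' @slot maxStages stage cap (default 10).
#' @slot spacingMm pixel edge in mm.
#' @slot terminated whether the iteration has stopped.
#' @slot noSpot TRUE when no sector carried any candidate signal.
#' @export
setClass("NarrowingState", representation(
  bbox = "integer", stage = "integer", history = "list",
  stopDiameterMm = "numeric", maxStages = "integer", spacingMm = "numeric",
  terminated = "logical", noSpot = "logical"
))

#' AvailabilityMatrix: binary sector-by-stage availability with bookkeeping
#'
#' `alpha[s, k]` is 1 when sector `s` contained at least one candidate pixel
#' at narrowing stage `k`. `delta` is the number of stages (segmented
#' sub-images); `dAvail` the number of 1-entries (floored at 1).
#'
#' @slot alpha binary matrix, 8 x stages.
#' @slot baseValue replacement weight for 1-entries (default 0.176).
#' @slot delta number of segmented sub-images.
#' @slot dAvail availability count.
#' @export
setClass("AvailabilityMatrix", representation(
  alpha = "matrix", baseValue = "numeric", delta = "integer",
  dAvail = "integer"
))

setValidity("AvailabilityMatrix", function(object) {
  msg <- character()
  if (!all(object@alpha %in% c(0, 1))) msg <- c(msg, "alpha must be binary")
  if (object@baseValue <= 0) msg <- c(msg, "baseValue must be > 0")
  if (object@delta < 1L) msg <- c(msg, "delta must be >= 1")
  if (object@dAvail < 1L) msg <- c(msg, "dAvail must be >= 1")
  if (length(msg)) msg else TRUE
})

#' RationalizationDecision: outcome of the availability log-scoring
#'
#' @slot scoreMatrix real matrix congruent with alpha.
#' @slot selectedCell (row, col) of the best positive score, or integer(0).
#' @slot spotConfirmed whether the located spot is confirmed.
#' @export
setClass("RationalizationDecision", representation(
  scoreMatrix = "matrix", selectedCell = "integer", spotConfirmed = "logical"
))

#' PhantomSpec: parameters of one synthetic brain phantom
#'
#' The generator emulates the statistical structure of axial brain MRI
#' slices: an elliptical head region of base intensity 0.5 over a dark
#' background, smooth low-frequency tissue texture, an optional bright
#' compact tumor disc, and additive Gaussian noise.
#'
#' @slot size (rows, cols) in pixels.
#' @slot spacingMm pixel edge in mm.
#' @slot headAxes ellipse semi-axes (row, col) in pixels.
#' @slot tissueTextureSd SD of the smooth tissue intensity variation.
#' @slot textureCorrelationPx correlation length of the texture field.
#' @slot tumorPresent logical.
#' @slot tumorCenter (row, col) of the tumor disc.
#' @slot tumorDiameterMm physical tumor diameter (>= 3 when present).
#' @slot tumorContrast additive intensity of tumor over local tissue, (0, 1].
#' @slot noiseSd SD of the additive Gaussian pixel noise.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec", representation(
  size = "integer", spacingMm = "numeric", headAxes = "numeric",
  tissueTextureSd = "numeric", textureCorrelationPx = "numeric",
  tumorPresent = "logical", tumorCenter = "numeric",
  tumorDiameterMm = "numeric", tumorContrast = "numeric",
  noiseSd = "numeric", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@size < .axisMin)) msg <- c(msg, "size must be >= 8 x 8")
  if (object@spacingMm <= 0) msg <- c(msg, "spacingMm must be > 0")
  if (any(object@headAxes <= 0)) msg <- c(msg, "headAxes must be > 0")
  if (object@tissueTextureSd < 0) msg <- c(msg, "tissueTextureSd must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@tumorPresent) {
    if (object@tumorDiameterMm < 3)
      msg <- c(msg, "tumorDiameterMm must be >= 3 when a tumor is present")
    if (object@tumorContrast <= 0 || object@tumorContrast > 1)
      msg <- c(msg, "tumorContrast must be in (0, 1]")
    radPx <- object@tumorDiameterMm / 2 / object@spacingMm
    ctr <- (object@size + 1) / 2
    a <- object@headAxes[1] - radPx
    b <- object@headAxes[2] - radPx
    if (a <= 0 || b <= 0 ||
        ((object@tumorCenter[1] - ctr[1]) / a)^2 +
        ((object@tumorCenter[2] - ctr[2]) / b)^2 >= 1)
      msg <- c(msg, "tumor disc must lie strictly inside the head ellipse")
  }
  if (length(msg)) msg else TRUE
})

#' MetricsReport: evaluation battery for a dataset run
#'
#' @slot perImage data.frame with one row per image (Dice, centroid error,
#'   tumor ratio, area error, reconstruction MSE/PSNR/SSIM where available).
#' @slot counts named integer vector (tp, fp, tn, fn) of image-level
#'   detection outcomes.
#' @slot summary named numeric vector of dataset-level metrics.
#' @export
setClass("MetricsReport", representation(
  perImage = "data.frame", counts = "integer", summary = "numeric"
))

setValidity("MetricsReport", function(object) {
  if (!all(c("tp", "fp", "tn", "fn") %in% names(object@counts)))
    "counts must be named tp, fp, tn, fn" else TRUE
})
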