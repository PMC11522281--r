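#' Extract the pixel raster of an image-like object
#'
#' @param x a [GrayImage-class], [BinaryMask-class], [GradientMap-class] or
#'   [LabelMap-class].
#' @return The underlying matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "GradientMap", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "LabelMap", function(x) x@pixels)

#' Physical pixel spacing in millimetres
#'
#' @param x a [GrayImage-class] or [BinaryMask-class].
#' @return Scalar spacing in mm.
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname spacingMm
#' @export
setMethod("spacingMm", "GrayImage", function(x) x@spacingMm)
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "BinaryMask", function(x) x@spacingMm)

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage %d x %d, spacing %.3g mm, range [%.3g, %.3g], source '%s'\n",
              nrow(p), ncol(p), object@spacingMm, min(p), max(p),
              object@sourceId))
})

setMethod("show", "BinaryMask", function(object) {
  p <- object@pixels
  cat(sprintf("BinaryMask %d x %d, spacing %.3g mm, %d foreground px\n",
              nrow(p), ncol(p), object@spacingMm, sum(p)))
})

setMethod("show", "LabelMap", function(object) {
  p <- object@pixels
  cat(sprintf("LabelMap %d x %d, %d regions\n", nrow(p), ncol(p),
              length(unique(as.vector(p)))))
})

setMethod("show", "GradientMap", function(object) {
  p <- object@pixels
  cat(sprintf("GradientMap %d x %d, max %.4g\n", nrow(p), ncol(p), max(p)))
})

setMethod("show", "NarrowingState", function(object) {
  cat(sprintf("NarrowingState: stage %d, bbox [%d..%d, %d..%d]%s%s\n",
              object@stage, object@bbox[1], object@bbox[2], object@bbox[3],
              object@bbox[4],
              if (object@terminated) ", terminated" else "",
              if (object@noSpot) ", no spot" else ""))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport:", nrow(object@perImage), "images\n")
  cat("  counts:", paste(names(object@counts), object@counts,
                         sep = "=", collapse = " "), "\n")
  s <- object@summary
  for (nm in names(s))
    cat(sprintf("  %s: %s\n", nm,
                ifelse(is.na(s[[nm]]), "n/a", format(s[[nm]], digits = 5))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %d x %d, spacing %.3g mm, tumor %s, seed %d\n",
              object@size[1], object@size[2], object@spacingMm,
              if (object@tumorPresent)
                sprintf("d=%.3g mm c=%.3g", object@tumorDiameterMm,
                        object@tumorContrast) else "absent",
              object@seed))
})

#' Internal: coerce image-like inputs to a plain numeric matrix
#'
#' Accepts raster S4 objects or bare matrices so that low-level operations
#' (gradients, metrics) can be exercised on unnormalized test rasters.
#' @noRd
asPixelMatrix <- function(x) {
  if (is(x, "GrayImage") || is(x, "BinaryMask") || is(x, "GradientMap") ||
      is(x, "LabelMap")) return(x@pixels)
  if (is.logical(x)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  if (is.matrix(x)) return(x)
  stop("expected a matrix or raster object, got ", class(x)[1])
}
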