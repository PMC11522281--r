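# Max/min rationalization: throughput-style rates and the availability
# log-scoring that confirms or rejects a located spot.

#' Minimum rationalization rate
#'
#' `total * medianProcessed / minS`: the total number of inputs working
#' with the median number of images processed per unit time.
#'
#' @param total total number of images.
#' @param medianProcessed median number of images processed.
#' @param minS positive per-unit-time denominator.
#' @return `list(value, total, processed, perUnitTime)`.
#' @export
#' @examples
#' minRationalization(200, 66, 4)$value  # 3300
minRationalization <- function(total, medianProcessed, minS) {
  if (minS <= 0) stop("minS must be > 0")
  list(value = total * medianProcessed / minS, total = total,
       processed = medianProcessed, perUnitTime = minS)
}

#' Maximum rationalization rate
#'
#' `total * maxProcessed / maxS`, the dual of [minRationalization()] with
#' the maximum number of images processed.
#'
#' @param total total number of images.
#' @param maxProcessed maximum number of images processed.
#' @param maxS positive per-unit-time denominator.
#' @return `list(value, total, processed, perUnitTime)`.
#' @export
maxRationalization <- function(total, maxProcessed, maxS) {
  if (maxS <= 0) stop("maxS must be > 0")
  list(value = total * maxProcessed / maxS, total = total,
       processed = maxProcessed, perUnitTime = maxS)
}

#' Build the sector-by-stage availability matrix of a narrowing run
#'
#' `alpha[s, k] = 1` iff sector `s` contained at least one candidate pixel
#' at stage `k` (that is, the recorded coverage signal was positive).
#' `delta` is the number of stages (segmented sub-images) and `dAvail` the
#' number of 1-entries, floored at 1.
#'
#' @param state a [NarrowingState-class] with at least one stage.
#' @param baseValue weight substituted for 1-entries in the scoring
#'   (default 0.176).
#' @return An [AvailabilityMatrix-class].
#' @export
availabilityMatrix <- function(state, baseValue = 0.176) {
  if (length(state@history) == 0) stop("narrowing history is empty")
  alpha <- vapply(state@history, function(h) as.numeric(h$signals > 0),
                  numeric(8))
  alpha <- matrix(alpha, nrow = 8)
  rownames(alpha) <- paste0("sector", 1:8)
  new("AvailabilityMatrix", alpha = alpha, baseValue = baseValue,
      delta = ncol(alpha), dAvail = max(1L, as.integer(sum(alpha))))
}

#' Score an availability matrix and decide on the spot
#'
#' Each cell scores `alpha[s,k] * baseValue * log(delta / dAvail)` in the
#' configured base (10 by default); scores live only on available cells,
#' and all scores are 0 when `delta == dAvail`. The selected cell is the
#' lexicographically first arg-max among strictly positive scores (none
#' when no score is positive). The spot is confirmed whenever any cell is
#' available — the unique rule consistent with: all-zero availability
#' rejects, zero scores at `delta == dAvail` fall back to availability, and
#' adding availability can never turn a confirmation into a rejection.
#'
#' @param am an [AvailabilityMatrix-class].
#' @param logBase base of the logarithm, default 10.
#' @return A [RationalizationDecision-class].
#' @export
rationalizationScore <- function(am, logBase = 10) {
  ratio <- am@delta / am@dAvail
  scores <- am@alpha * am@baseValue * log(ratio, base = logBase)
  selected <- integer(0)
  pos <- which(scores > 0, arr.ind = TRUE)
  if (nrow(pos) > 0) {
    best <- scores[pos]
    top <- pos[best == max(best), , drop = FALSE]
    ord <- order(top[, 1], top[, 2])
    selected <- as.integer(top[ord[1], ])
  }
  new("RationalizationDecision", scoreMatrix = scores,
      selectedCell = selected,
      spotConfirmed = any(am@alpha == 1))
}

#' Confirm or reject a located spot
#'
#' Returns the spot unchanged when the decision confirms it, otherwise an
#' empty mask of the same shape.
#'
#' @param decision a [RationalizationDecision-class].
#' @param spot a [BinaryMask-class].
#' @return A [BinaryMask-class].
#' @export
confirmSpot <- function(decision, spot) {
  if (decision@spotConfirmed) return(spot)
  BinaryMask(matrix(0L, nrow(spot@pixels), ncol(spot@pixels)),
             spacingMm = spot@spacingMm)
}
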