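# Octagon-division iterative spot localization.
#
# A regular octagon is circumscribed around the current bounding box, the
# box is partitioned into the octagon's 8 center-to-vertex sectors, each
# sector is scored by a stage-indexed ("time attribute") spot signal, the
# best sector is kept and the box shrinks to the candidate pixels it
# contains. Iteration stops at a physical scale (3 mm by default), at a
# stage cap, when no sector carries signal, when the box stops shrinking,
# or when every sector carries signal (no un-spotted region remains to be
# discarded).

#' Internal: bbox helpers; bbox is c(r0, r1, c0, c1), inclusive
#' @noRd
bboxOf <- function(rows, cols) {
  c(min(rows), max(rows), min(cols), max(cols))
}

#' @noRd
bboxArea <- function(b) (b[2] - b[1] + 1) * (b[4] - b[3] + 1)

#' @noRd
bboxSideMax <- function(b) max(b[2] - b[1] + 1, b[4] - b[3] + 1)

#' Circumscribe a regular octagon around a bounding box
#'
#' The octagon is centred on the box centre and sized so that its apothem
#' (centre-to-edge distance) is `(1 + margin)` times the box half-diagonal
#' — the circumradius is that over `cos(22.5deg)` — so all four corners lie
#' strictly inside every edge, whatever the box aspect ratio. One vertex
#' sits on the +col axis, so the 8 center-to-vertex sector boundary rays
#' align with the image axes and diagonals (which also makes the 8 sectors
#' of a square box congruent by reflection).
#'
#' @param bbox integer (r0, r1, c0, c1), inclusive, non-degenerate.
#' @param margin relative enlargement beyond the half-diagonal, default
#'   0.05.
#' @return An [OctagonFrame-class].
#' @export
inscribeOctagon <- function(bbox, margin = 0.05) {
  bbox <- as.integer(bbox)
  if (bbox[2] < bbox[1] || bbox[4] < bbox[3])
    stop("degenerate bounding box")
  h <- bbox[2] - bbox[1] + 1; w <- bbox[4] - bbox[3] + 1
  center <- c((bbox[1] + bbox[2]) / 2, (bbox[3] + bbox[4]) / 2)
  R <- (1 + margin) * sqrt(h^2 + w^2) / 2 / cos(22.5 * pi / 180)
  ang <- (45 * (0:7)) * pi / 180
  vertices <- cbind(row = center[1] - R * sin(ang),
                    col = center[2] + R * cos(ang))
  new("OctagonFrame", center = center, circumradius = R, vertices = vertices)
}

#' Test points against an octagon frame
#'
#' @param frame an [OctagonFrame-class].
#' @param points matrix of (row, col) coordinates.
#' @return Logical vector: point strictly inside the octagon.
#' @export
octagonContains <- function(frame, points) {
  # with vertices at angles k * 45deg the edge midpoints (apothem
  # directions) sit at 22.5 + k * 45deg; containment is the intersection
  # of the 8 half-plane projections
  apo <- frame@circumradius * cos(22.5 * pi / 180)
  dx <- points[, 2] - frame@center[2]
  dy <- frame@center[1] - points[, 1]  # math orientation, y up
  ok <- rep(TRUE, nrow(points))
  for (k in 0:7) {
    a <- (22.5 + k * 45) * pi / 180
    ok <- ok & (dx * cos(a) + dy * sin(a) < apo)
  }
  ok
}

#' Internal: sector id (1..8) for angles theta in degrees
#'
#' Sectors run counter-clockwise; sector d spans ((d-1)*45, d*45) degrees,
#' so sector 1 is the wedge just above the +col axis. Pixels exactly on a
#' boundary ray go to the lower adjacent id; the ray at 0 degrees separates
#' sectors 8 and 1, so it goes to 1.
#' @noRd
sectorOfAngle <- function(theta) {
  u <- theta / 45
  onRay <- abs(u - round(u)) < 1e-9
  id <- (floor(u) %% 8) + 1
  m <- round(u[onRay]) %% 8
  id[onRay] <- ifelse(m == 0, 1, m)
  as.integer(id)
}

#' Partition a bounding box into the octagon's 8 sectors
#'
#' Every pixel of the box is binned by its angle about the octagon centre
#' into one of the 8 center-to-vertex triangles (the box lies inside the
#' octagon, so angle binning and triangle membership coincide). The exact
#' centre point, if it falls on a pixel, is assigned to sector 1.
#'
#' @param frame an [OctagonFrame-class] from [inscribeOctagon()].
#' @param bbox the same bounding box.
#' @return A [SectorMap-class] whose `ids` matrix covers the box.
#' @export
divideSectors <- function(frame, bbox) {
  bbox <- as.integer(bbox)
  rows <- bbox[1]:bbox[2]; cols <- bbox[3]:bbox[4]
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  dy <- frame@center[1] - rr  # y axis points up
  dx <- cc - frame@center[2]
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  ids <- matrix(sectorOfAngle(theta), length(rows), length(cols))
  ids[dy == 0 & dx == 0] <- 1L
  new("SectorMap", bbox = bbox, ids = ids)
}

#' Per-sector spot signals (candidate coverage fractions)
#'
#' @param sectors a [SectorMap-class].
#' @param candidate a [BinaryMask-class] (or 0/1 matrix) over the full
#'   image.
#' @return Numeric length-8: fraction of each sector's pixels lying in the
#'   candidate mask (0 for empty sectors).
#' @export
sectorSignals <- function(sectors, candidate) {
  cm <- asPixelMatrix(candidate)
  b <- sectors@bbox
  sub <- cm[b[1]:b[2], b[3]:b[4], drop = FALSE]
  sig <- numeric(8)
  tab <- tabulate(sectors@ids, nbins = 8)
  hits <- tabulate(sectors@ids[sub > 0], nbins = 8)
  sig[tab > 0] <- hits[tab > 0] / tab[tab > 0]
  sig
}

#' Assemble the three time attributes of a sector
#'
#' The newest attribute is the sector's current coverage signal; the two
#' older ones are the signals recorded along the narrowing path at the two
#' previous stages. Missing history (stages 1-2) is back-filled with the
#' current value.
#'
#' @param signalNow current-stage signal of the sector.
#' @param pathSignals numeric vector of selected-sector signals from
#'   earlier stages (oldest first), possibly empty.
#' @return Numeric `c(tPrime, tDoublePrime, tTriplePrime)` (oldest to
#'   newest).
#' @export
timeAttributes <- function(signalNow, pathSignals = numeric()) {
  k <- length(pathSignals)
  tDbl <- if (k >= 1) pathSignals[k] else signalNow
  tPri <- if (k >= 2) pathSignals[k - 1] else signalNow
  c(tPri, tDbl, signalNow)
}

#' Spot score of one sector
#'
#' `(|t' + t'' + t'''|^v)^(1/v)` with a single division line per sector, so
#' the exponent cancels for any `v >= 1`; `v` is kept configurable for the
#' multi-line variant of the score.
#'
#' @param attrs numeric length-3 time attributes.
#' @param v norm order >= 1, default 2.
#' @return Non-negative scalar; 0 iff all three attributes are 0.
#' @export
spotScore <- function(attrs, v = 2) {
  if (v < 1) stop("norm order v must be >= 1")
  (abs(sum(attrs))^v)^(1 / v)
}

#' Select the spotted sector from 8 scores
#'
#' Arg-max of the score (the reciprocal-of-mean minimization realized
#' directly); ties go to the lowest sector id; all-zero scores mean no spot.
#'
#' @param scores numeric length-8.
#' @return `list(id = <1..8 or NA>, noSpot = <logical>)`.
#' @export
selectSector <- function(scores) {
  if (length(scores) != 8) stop("expected 8 sector scores")
  if (all(scores == 0)) return(list(id = NA_integer_, noSpot = TRUE))
  list(id = which.max(scores), noSpot = FALSE)
}

#' Internal: fresh NarrowingState over a full image
#' @noRd
initNarrowingState <- function(image, stopDiameterMm = 3, maxStages = 10) {
  m <- asPixelMatrix(image)
  new("NarrowingState",
      bbox = c(1L, nrow(m), 1L, ncol(m)), stage = 0L, history = list(),
      stopDiameterMm = as.numeric(stopDiameterMm),
      maxStages = as.integer(maxStages),
      spacingMm = if (is(image, "GrayImage")) image@spacingMm else 1,
      terminated = FALSE, noSpot = FALSE)
}

#' One narrowing stage
#'
#' Inscribes the octagon on the current box, scores the 8 sectors, selects
#' the best one and shrinks the box to the bounding box of (selected sector
#' pixels intersected with the candidate), expanded by 1 px and clipped to
#' the current box. The state terminates when no sector carries signal,
#' when every sector carries signal (nothing un-spotted remains to
#' discard), or when the box stops strictly shrinking.
#'
#' @param state a [NarrowingState-class].
#' @param image the [GrayImage-class] under analysis (geometry only).
#' @param candidate the candidate [BinaryMask-class].
#' @param margin octagon margin (default 0.05).
#' @param v norm order for [spotScore()] (default 2).
#' @return The advanced [NarrowingState-class].
#' @export
narrowStep <- function(state, image, candidate, margin = 0.05, v = 2) {
  if (state@terminated) stop("narrowing state is already terminated")
  bbox <- state@bbox
  frame <- inscribeOctagon(bbox, margin)
  sectors <- divideSectors(frame, bbox)
  signals <- sectorSignals(sectors, candidate)
  pathSignals <- vapply(state@history, function(h) h$selSignal, numeric(1))
  scores <- vapply(1:8, function(s)
    spotScore(timeAttributes(signals[s], pathSignals), v), numeric(1))
  sel <- selectSector(scores)

  rec <- list(bbox = bbox, signals = signals, scores = scores,
              selected = sel$id,
              selSignal = if (sel$noSpot) 0 else signals[sel$id])
  state@history <- c(state@history, list(rec))
  state@stage <- state@stage + 1L

  if (sel$noSpot) {
    state@terminated <- TRUE
    state@noSpot <- TRUE
    return(state)
  }
  if (all(signals > 0)) {
    state@terminated <- TRUE
    return(state)
  }

  cm <- asPixelMatrix(candidate)
  sub <- cm[bbox[1]:bbox[2], bbox[3]:bbox[4], drop = FALSE] > 0
  hit <- sub & sectors@ids == sel$id
  idx <- which(hit, arr.ind = TRUE)
  rows <- idx[, 1] + bbox[1] - 1L
  cols <- idx[, 2] + bbox[3] - 1L
  nb <- bboxOf(rows, cols)
  nb <- c(max(nb[1] - 1L, bbox[1]), min(nb[2] + 1L, bbox[2]),
          max(nb[3] - 1L, bbox[3]), min(nb[4] + 1L, bbox[4]))
  if (bboxArea(nb) >= bboxArea(bbox)) {
    state@terminated <- TRUE
    return(state)
  }
  state@bbox <- as.integer(nb)
  state
}

#' Locate the tumor spot by iterative octagon narrowing
#'
#' Runs [narrowStep()] from the full image until the box's longest side
#' falls to the physical stopping scale (`stopDiameterMm / spacing`
#' pixels), the stage cap is hit, or the step itself terminates (no signal,
#' all sectors spotted, or no shrink). The final spot is the candidate
#' clipped to the final box; an empty candidate returns an empty spot at
#' stage 0.
#'
#' @param image a [GrayImage-class].
#' @param candidate the candidate [BinaryMask-class] from
#'   [taePisSegment()].
#' @param stopDiameterMm stopping scale, default 3 mm.
#' @param maxStages stage cap, default 10.
#' @param margin octagon margin, default 0.05.
#' @param v norm order, default 2.
#' @return `list(spot = BinaryMask, state = NarrowingState)`.
#' @export
locateSpot <- function(image, candidate, stopDiameterMm = 3, maxStages = 10,
                       margin = 0.05, v = 2) {
  state <- initNarrowingState(image, stopDiameterMm, maxStages)
  cm <- asPixelMatrix(candidate)
  spacing <- state@spacingMm
  if (!any(cm > 0)) {
    state@terminated <- TRUE
    state@noSpot <- TRUE
    return(list(spot = BinaryMask(matrix(0L, nrow(cm), ncol(cm)),
                                  spacingMm = spacing),
                state = state))
  }
  stopPx <- stopDiameterMm / spacing
  while (!state@terminated && state@stage < state@maxStages &&
         bboxSideMax(state@bbox) > stopPx) {
    state <- narrowStep(state, image, candidate, margin, v)
  }
  b <- state@bbox
  spot <- matrix(0L, nrow(cm), ncol(cm))
  if (!state@noSpot) {
    spot[b[1]:b[2], b[3]:b[4]] <-
      as.integer(cm[b[1]:b[2], b[3]:b[4], drop = FALSE] > 0)
  }
  list(spot = BinaryMask(spot, spacingMm = spacing), state = state)
}
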