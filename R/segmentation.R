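# Hybrid feature-extraction / partial-image-segmentation stage.
#
# The raw (unfiltered) image is mapped to an edge-strength raster, shallow
# regional minima of that raster are filled by morphological reconstruction
# (depth-lambda suppression, the over-segmentation control), the result is
# flooded into catchment basins by steepest descent, and candidate tumor
# regions are picked by a brightness z-score rule. Noise suppression happens
# after feature extraction, never before it, so that faint compact spots are
# not smoothed away by a pre-filter.

#' Internal: (dr, dc) neighbour offsets for a connectivity
#' @noRd
neighborOffsets <- function(connectivity = 8) {
  four <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 4) return(four)
  c(four, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
}

#' Internal: shift a matrix by (dr, dc) with edge replication
#'
#' Result[r, c] = m[clip(r + dr), clip(c + dc)].
#' @noRd
shiftRep <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
    pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
}

#' Internal: linear indices of the (dr, dc) neighbour of each pixel
#'
#' Column-major linear indices; NA where the neighbour falls outside.
#' @noRd
neighborIndex <- function(nr, nc, dr, dc) {
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rs[rs < 1L | rs > nr] <- NA_integer_
  cs[cs < 1L | cs > nc] <- NA_integer_
  out <- outer(rs, (cs - 1L) * nr, `+`)
  as.integer(out)
}

#' Central-difference gradient magnitude
#'
#' Half the root-sum-square of the two central differences,
#' `0.5 * sqrt((i(x+1,y) - i(x-1,y))^2 + (i(x,y+1) - i(x,y-1))^2)`, with
#' edge replication at the borders. On a linear ramp of slope s this equals
#' s in the interior (half the value of the radius-1 morphological
#' gradient).
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @return A [GradientMap-class].
#' @export
centralGradient <- function(image) {
  m <- asPixelMatrix(image)
  dx <- shiftRep(m, 1L, 0L) - shiftRep(m, -1L, 0L)
  dy <- shiftRep(m, 0L, 1L) - shiftRep(m, 0L, -1L)
  GradientMap(0.5 * sqrt(dx^2 + dy^2))
}

#' Morphological gradient (window max minus window min)
#'
#' Each pixel takes the range of intensities over the centred
#' `(2r+1) x (2r+1)` window, the window clipped at the image borders.
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param neighborhoodRadius window half-width r >= 1 (default 1).
#' @return A [GradientMap-class].
#' @export
morphologicalGradient <- function(image, neighborhoodRadius = 1) {
  m <- asPixelMatrix(image)
  r <- as.integer(neighborhoodRadius)
  if (r < 1L) stop("neighborhoodRadius must be >= 1")
  # separable running max/min: rows first, then columns; edge-replicated
  # shifts reproduce the border-clipped window exactly
  dilR <- m; eroR <- m
  for (d in seq_len(r)) {
    dilR <- pmax(dilR, shiftRep(m, d, 0L), shiftRep(m, -d, 0L))
    eroR <- pmin(eroR, shiftRep(m, d, 0L), shiftRep(m, -d, 0L))
  }
  dil <- dilR; ero <- eroR
  for (d in seq_len(r)) {
    dil <- pmax(dil, shiftRep(dilR, 0L, d), shiftRep(dilR, 0L, -d))
    ero <- pmin(ero, shiftRep(eroR, 0L, d), shiftRep(eroR, 0L, -d))
  }
  GradientMap(dil - ero)
}

#' Internal: morphological reconstruction by erosion (8-connected)
#'
#' Computes the largest image above `mask` whose value at every pixel is
#' reachable from `marker` by geodesic erosion. Implemented as alternating
#' directional line sweeps (down, up, left-to-right, right-to-left), each a
#' sequence of whole-line vectorized updates; the sweep set covers all 8
#' neighbours, so a state stable under all four sweeps is the fixpoint.
#' @noRd
morphoReconstructErode <- function(marker, mask) {
  cur <- pmax(marker, mask)
  nr <- nrow(cur); nc <- ncol(cur)
  shl <- function(v) c(v[-1], v[length(v)])   # neighbour at +1, replicated
  shr <- function(v) c(v[1], v[-length(v)])   # neighbour at -1, replicated
  for (sweep in seq_len(2L * (nr + nc) + 8L)) {
    prev <- cur
    if (nr > 1) {
      for (r in 2:nr) {
        up <- cur[r - 1, ]
        cur[r, ] <- pmax(mask[r, ], pmin(cur[r, ], up, shl(up), shr(up)))
      }
      for (r in (nr - 1):1) {
        dn <- cur[r + 1, ]
        cur[r, ] <- pmax(mask[r, ], pmin(cur[r, ], dn, shl(dn), shr(dn)))
      }
    }
    if (nc > 1) {
      for (cc in 2:nc) {
        lf <- cur[, cc - 1]
        cur[, cc] <- pmax(mask[, cc], pmin(cur[, cc], lf, shl(lf), shr(lf)))
      }
      for (cc in (nc - 1):1) {
        rt <- cur[, cc + 1]
        cur[, cc] <- pmax(mask[, cc], pmin(cur[, cc], rt, shl(rt), shr(rt)))
      }
    }
    if (identical(prev, cur)) break
  }
  cur
}

#' Suppress shallow regional minima (depth-lambda filling)
#'
#' Morphological reconstruction by erosion of `gradient + lambda` above
#' `gradient`: regional minima whose dynamic is smaller than `lambda` are
#' filled to their enclosing saddle, deeper minima are raised by exactly
#' `lambda` (which leaves their basins, and hence the watershed partition,
#' intact). `lambda = 0` is the identity. Raising `lambda` can only merge
#' basins, so the downstream region count is non-increasing in `lambda`.
#'
#' @param gradient a [GradientMap-class] or numeric matrix.
#' @param lambdaDepth suppression depth >= 0, in the gradient's units.
#' @param iterations times to apply the operator (default 1; one
#'   reconstruction already realizes any depth).
#' @return A [GradientMap-class], pointwise >= the input.
#' @export
lambdaSuppress <- function(gradient, lambdaDepth, iterations = 1) {
  g <- asPixelMatrix(gradient)
  if (lambdaDepth < 0) stop("lambdaDepth must be >= 0")
  if (lambdaDepth == 0) return(GradientMap(g))
  for (it in seq_len(iterations)) {
    g <- morphoReconstructErode(g + lambdaDepth, g)
  }
  GradientMap(g)
}

#' Watershed partition by steepest descent
#'
#' Treats the (suppressed) gradient as terrain: every pixel drains along
#' its steepest-descent path to a regional minimum, and the set of pixels
#' draining to one minimum is one catchment basin. Every pixel receives
#' exactly one label (no ridge pixels are emitted), each region contains
#' exactly one regional minimum, and each region is connected under the
#' configured connectivity. Deterministic tie-breaks: among equally low
#' neighbours the lowest linear (column-major) index wins, and plateau
#' pixels drain to their geodesically nearest plateau edge (ties again to
#' the lowest index).
#'
#' @param gradient a [GradientMap-class] or numeric matrix (typically the
#'   output of [lambdaSuppress()]).
#' @param connectivity 4 or 8 (default 8).
#' @return A [LabelMap-class] with region ids 1..R.
#' @export
watershedPartition <- function(gradient, connectivity = 8) {
  g <- asPixelMatrix(gradient)
  nr <- nrow(g); nc <- ncol(g); n <- nr * nc
  gv <- as.vector(g)
  offs <- neighborOffsets(connectivity)
  nbr <- lapply(offs, function(o) neighborIndex(nr, nc, o[1], o[2]))

  # lowest neighbour (value, index) with lowest-index tie-break
  bestVal <- rep(Inf, n); bestIdx <- rep(NA_integer_, n)
  for (nb in nbr) {
    ok <- !is.na(nb)
    v <- rep(Inf, n); v[ok] <- gv[nb[ok]]
    upd <- (v < bestVal) | (v == bestVal & ok & (is.na(bestIdx) | nb < bestIdx))
    bestVal[upd] <- v[upd]; bestIdx[upd] <- nb[upd]
  }
  hasLower <- bestVal < gv

  # equal-value plateau components by min-label propagation with pointer
  # jumping (O(log) rounds)
  comp <- seq_len(n)
  eqMask <- lapply(nbr, function(nb) {
    ok <- !is.na(nb)
    ok[ok] <- gv[nb[ok]] == gv[ok]
    ok
  })
  repeat {
    nxt <- comp
    for (j in seq_along(nbr)) {
      eq <- eqMask[[j]]
      nxt[eq] <- pmin(nxt[eq], comp[nbr[[j]][eq]])
    }
    # full path compression: star-contract before the next merge round
    repeat {
      jmp <- nxt[nxt]
      if (identical(jmp, nxt)) break
      nxt <- jmp
    }
    if (identical(nxt, comp)) break
    comp <- nxt
  }

  # a plateau is a regional minimum iff none of its pixels has a strictly
  # lower neighbour; otherwise the whole plateau drains through its
  # lowest-index boundary ("exit") pixel
  exitIdx <- rep(NA_integer_, n)
  lowers <- which(hasLower)
  if (length(lowers)) {
    exits <- vapply(split(lowers, comp[lowers]), min, numeric(1))
    hit <- match(comp, as.integer(names(exits)))
    exitIdx <- as.integer(exits[hit])
  }
  minima <- is.na(exitIdx)

  ptr <- integer(n)
  ptr[minima] <- which(minima)
  ptr[!minima] <- exitIdx[!minima]
  ptr[hasLower] <- bestIdx[hasLower]

  # path doubling to the sinks
  repeat {
    p2 <- ptr[ptr]
    if (identical(p2, ptr)) break
    ptr <- p2
  }
  roots <- comp[ptr]
  labels <- match(roots, sort(unique(roots)))
  LabelMap(matrix(as.integer(labels), nr, nc))
}

#' Select candidate tumor regions by brightness z-score
#'
#' Brain pixels are those above 10 percent of the image maximum (background
#' exclusion). A watershed region is a candidate when its mean intensity
#' exceeds the brain-wide mean plus `candidateZ` brain-wide standard
#' deviations; the candidate mask is the union of such regions (possibly
#' empty).
#'
#' @param image a [GrayImage-class] or numeric matrix.
#' @param labels a [LabelMap-class] congruent with the image.
#' @param params a [SegmentationParams-class] (only `candidateZ` is used).
#' @return A [BinaryMask-class].
#' @export
candidateMask <- function(image, labels, params = SegmentationParams()) {
  m <- asPixelMatrix(image)
  lv <- as.vector(asPixelMatrix(labels))
  if (length(lv) != length(m)) stop("image and labels shapes differ")
  brain <- as.vector(m) > 0.1 * max(m)
  mv <- as.vector(m)
  if (!any(brain)) {
    return(BinaryMask(matrix(0L, nrow(m), ncol(m)),
                      spacingMm = if (is(image, "GrayImage")) image@spacingMm else 1))
  }
  mu <- mean(mv[brain]); s <- stats::sd(mv[brain])
  if (is.na(s)) s <- 0
  sums <- rowsum(mv, lv)
  cnts <- rowsum(rep(1, length(lv)), lv)
  means <- sums / cnts
  selIds <- as.integer(rownames(sums))[means[, 1] > mu + params@candidateZ * s]
  mask <- matrix(as.integer(lv %in% selIds), nrow(m), ncol(m))
  BinaryMask(mask, spacingMm = if (is(image, "GrayImage")) image@spacingMm else 1)
}

#' Hybrid segmentation: gradient, suppression, watershed, candidate mask
#'
#' Runs the full stage on the raw image: edge-strength raster
#' ([morphologicalGradient()] by default, [centralGradient()] by option),
#' depth-lambda minima suppression, steepest-descent watershed, and the
#' z-score candidate rule.
#'
#' @param image a [GrayImage-class].
#' @param params a [SegmentationParams-class].
#' @return `list(labels = LabelMap, candidate = BinaryMask,
#'   gradient = GradientMap)`.
#' @export
#' @examples
#' ph <- makePhantom(PhantomSpec(size = c(64, 64), headAxes = c(27, 23),
#'                               tumorCenter = c(26, 40),
#'                               tumorDiameterMm = 12, seed = 3))
#' seg <- taePisSegment(ph$image)
#' sum(pixels(seg$candidate))
taePisSegment <- function(image, params = SegmentationParams()) {
  g <- switch(params@gradientKind,
              morphological = morphologicalGradient(image,
                                                    params@neighborhoodRadius),
              central = centralGradient(image))
  gs <- lambdaSuppress(g, params@lambdaDepth, params@lambdaIters)
  labels <- watershedPartition(gs, params@connectivity)
  cand <- candidateMask(image, labels, params)
  list(labels = labels, candidate = cand, gradient = gs)
}

#' Piecewise-constant reconstruction from a watershed partition
#'
#' Replaces every pixel by the mean intensity of its region — the
#' "segmented image" used by the reconstruction-quality metrics (MSE, PSNR,
#' SSIM) against the original.
#'
#' @param image a [GrayImage-class] or matrix.
#' @param labels a congruent [LabelMap-class].
#' @return A numeric matrix.
#' @export
segmentedImage <- function(image, labels) {
  m <- asPixelMatrix(image)
  lv <- as.vector(asPixelMatrix(labels))
  means <- rowsum(as.vector(m), lv) / rowsum(rep(1, length(lv)), lv)
  matrix(means[match(lv, as.integer(rownames(means)))], nrow(m), ncol(m))
}
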