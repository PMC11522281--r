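# Independent brute-force oracles. These deliberately re-derive results
# with plain loops (queues, per-window evaluation, per-pixel descent) so
# that the vectorized implementations are checked against structurally
# different code.

linIndex <- function(r, c, nr) (c - 1L) * nr + r

oracleOffsets <- function(connectivity) {
  if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
}

# Steepest-descent flood-fill watershed, per-pixel path following.
# Tie rules mirror the documented contract: lowest-index minimizer among
# strictly lower neighbours; a plateau drains through its lowest-index
# pixel that has a strictly lower neighbour; plateaus with no such pixel
# are regional minima.
watershedOracle <- function(g, connectivity = 8) {
  nr <- nrow(g); nc <- ncol(g)
  offs <- oracleOffsets(connectivity)
  nbrs <- function(r, c) {
    out <- list()
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        out[[length(out) + 1L]] <- c(rr, cc)
    }
    out
  }
  bestLower <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    bv <- Inf; bi <- NA_integer_
    for (q in nbrs(r, c)) {
      v <- g[q[1], q[2]]; qi <- linIndex(q[1], q[2], nr)
      if (v < bv || (v == bv && qi < bi)) { bv <- v; bi <- qi }
    }
    if (bv < g[r, c]) bestLower[r, c] <- bi
  }
  comp <- matrix(NA_integer_, nr, nc); nComp <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) if (is.na(comp[r, c])) {
    nComp <- nComp + 1L
    queue <- list(c(r, c)); comp[r, c] <- nComp
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nbrs(p[1], p[2]))
        if (is.na(comp[q[1], q[2]]) && g[q[1], q[2]] == g[p[1], p[2]]) {
          comp[q[1], q[2]] <- nComp
          queue <- c(queue, list(q))
        }
    }
  }
  exitOf <- rep(NA_integer_, nComp)
  for (c in seq_len(nc)) for (r in seq_len(nr))
    if (!is.na(bestLower[r, c])) {
      id <- comp[r, c]; li <- linIndex(r, c, nr)
      if (is.na(exitOf[id]) || li < exitOf[id]) exitOf[id] <- li
    }
  sinkOf <- function(r, c) {
    repeat {
      id <- comp[r, c]
      if (is.na(exitOf[id])) return(id)
      nxt <- if (!is.na(bestLower[r, c])) bestLower[r, c] else exitOf[id]
      c <- (nxt - 1L) %/% nr + 1L
      r <- nxt - (c - 1L) * nr
    }
  }
  lab <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) lab[r, c] <- sinkOf(r, c)
  matrix(match(lab, sort(unique(as.vector(lab)))), nr, nc)
}

# Two label maps describe the same partition up to renaming
labelsEquivalent <- function(a, b) {
  joint <- paste(as.vector(a), as.vector(b))
  length(unique(joint)) == length(unique(as.vector(a))) &&
    length(unique(joint)) == length(unique(as.vector(b)))
}

# Jacobi-iterated geodesic erosion (8-connected) until fixpoint
reconstructErodeOracle <- function(marker, mask) {
  nr <- nrow(marker); nc <- ncol(marker)
  cur <- pmax(marker, mask)
  repeat {
    nxt <- cur
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      mn <- cur[r, c]
      for (o in oracleOffsets(8)) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
          mn <- min(mn, cur[rr, cc])
      }
      nxt[r, c] <- max(mask[r, c], mn)
    }
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# Direct windowed SSIM, one window at a time, population moments
ssimOracle <- function(a, b, k1 = 0.01, k2 = 0.03, r = 3, L = 1) {
  w <- 2 * r + 1
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - w + 1)) for (j in seq_len(ncol(a) - w + 1)) {
    x <- a[i:(i + w - 1), j:(j + w - 1)]
    y <- b[i:(i + w - 1), j:(j + w - 1)]
    ux <- mean(x); uy <- mean(y)
    vx <- mean((x - ux)^2); vy <- mean((y - uy)^2)
    cxy <- mean((x - ux) * (y - uy))
    vals <- c(vals, ((2 * ux * uy + C1) * (2 * cxy + C2)) /
                ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# Brute-force clipped-window morphological gradient
morphGradOracle <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    win <- m[max(1, i - r):min(nr, i + r), max(1, j - r):min(nc, j + r)]
    out[i, j] <- max(win) - min(win)
  }
  out
}

# Pixel count of the corner-centred disc rasterization
discCountOracle <- function(nr, nc, center, radiusPx) {
  cnt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i - center[1] - 0.5)^2 + (j - center[2] - 0.5)^2 <= radiusPx^2)
      cnt <- cnt + 1L
  cnt
}

# Exact counter-clockwise quarter rotation of a matrix
rotCCW <- function(m) t(m)[ncol(m):1, , drop = FALSE]

asMat <- function(x) if (is.matrix(x)) x else pixels(x)

centroidOf <- function(mask) {
  idx <- which(asMat(mask) > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  colMeans(idx)
}

bboxNpix <- function(b) as.integer((b[2] - b[1] + 1) * (b[4] - b[3] + 1))

# stage-1 sector selection for a candidate mask over the full image
stage1Sector <- function(cand) {
  b <- c(1L, nrow(cand), 1L, ncol(cand))
  sm <- divideSectors(inscribeOctagon(b), b)
  sig <- sectorSignals(sm, cand)
  selectSector(vapply(1:8, function(s)
    spotScore(timeAttributes(sig[s])), numeric(1)))$id
}
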