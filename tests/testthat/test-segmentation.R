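test_that("central gradient matches hand-computed difference fields", {
  expect_true(all(pixels(centralGradient(matrix(0.4, 10, 10))) == 0))
  # unit ramp (value = row index): interior magnitude 1/2 * sqrt(2^2) = 1
  ramp <- matrix(rep(1:10, times = 10), 10, 10)
  g <- pixels(centralGradient(ramp))
  expect_equal(g[2:9, 2:9], matrix(1, 8, 8), ignore_attr = TRUE)
  # diagonal ramp value = row + col: interior 1/2 * sqrt(4 + 4) = sqrt(2)
  diagRamp <- outer(1:10, 1:10, `+`)
  gd <- pixels(centralGradient(diagRamp))
  expect_equal(gd[2:9, 2:9], matrix(sqrt(2), 8, 8), ignore_attr = TRUE)
})

test_that("morphological gradient equals the clipped-window range", {
  expect_true(all(pixels(morphologicalGradient(matrix(2, 9, 9), 1)) == 0))
  # single bright pixel spreads over its 8-neighbourhood
  m <- matrix(0, 9, 9); m[5, 5] <- 5
  g <- pixels(morphologicalGradient(m, 1))
  expect_equal(g, morphGradOracle(m, 1), ignore_attr = TRUE)
  expect_true(all(g[4:6, 4:6] == 5))
  expect_true(all(g[-(4:6), ] == 0))
  # vertical step 0|1: range 1 on the two columns flanking the step
  s <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  gs <- pixels(morphologicalGradient(s, 1))
  expect_true(all(gs[, 4:5] == 1))
  expect_true(all(gs[, c(1:3, 6:8)] == 0))
  # radius 2 against the brute-force oracle on a random raster
  set.seed(7)
  r <- matrix(runif(100), 10, 10)
  expect_equal(pixels(morphologicalGradient(r, 2)), morphGradOracle(r, 2),
               ignore_attr = TRUE)
})

test_that("gradient operators agree on ramps with the known 2x ratio", {
  ramp <- matrix(rep(seq(0, 3.6, by = 0.4), times = 10), 10, 10)
  cg <- pixels(centralGradient(ramp))[3:8, 3:8]
  mg <- pixels(morphologicalGradient(ramp, 1))[3:8, 3:8]
  expect_equal(mg, 2 * cg, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("lambda suppression fills shallow minima and only those", {
  prof <- matrix(c(5, 0, 5, 4, 5), 1, 5)
  out <- pixels(lambdaSuppress(prof, 2))
  expect_equal(out, reconstructErodeOracle(prof + 2, prof),
               ignore_attr = TRUE)
  # the depth-1 minimum is filled; the deep one survives as a minimum
  expect_equal(out[1, 4], 5)
  expect_lt(out[1, 2], min(out[1, c(1, 3)]))
  # identity at zero depth; a constant image stays a single flat plateau
  # (reconstruction lifts it uniformly by lambda, leaving the topography,
  # and hence the watershed, untouched)
  g <- matrix(runif(64), 8, 8)
  expect_identical(pixels(lambdaSuppress(g, 0)), g)
  flat <- pixels(lambdaSuppress(matrix(1, 8, 8), 0.3))
  expect_identical(max(flat), min(flat))
  expect_identical(max(pixels(watershedPartition(flat))), 1L)
  # output never falls below the input
  expect_true(all(pixels(lambdaSuppress(g, 0.2)) >= g))
})

test_that("lambda suppression matches the reconstruction oracle on random rasters", {
  set.seed(21)
  for (i in 1:5) {
    g <- matrix(round(runif(81), 2), 9, 9)
    lam <- c(0.05, 0.1, 0.2, 0.4, 0.8)[i]
    expect_equal(pixels(lambdaSuppress(g, lam)),
                 reconstructErodeOracle(g + lam, g),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("watershed basics: plateaus, basins, and suppression merging", {
  expect_identical(max(pixels(watershedPartition(matrix(1, 8, 8)))), 1L)
  # two basins split by a tall ridge
  g <- matrix(0.3, 8, 8); g[3, 3] <- 0; g[6, 6] <- 0; g[, 5] <- 1
  expect_identical(max(pixels(watershedPartition(g))), 2L)
  # lambda above the ridge depth merges them
  gs <- lambdaSuppress(g, 1.5)
  expect_identical(max(pixels(watershedPartition(gs))), 1L)
})

test_that("watershed agrees with the steepest-descent oracle", {
  set.seed(31)
  cases <- list()
  for (i in 1:8) cases[[i]] <- matrix(sample(1:144), 12, 12)      # distinct
  for (i in 9:12) cases[[i]] <- matrix(sample(1:6, 100, TRUE), 10, 10)  # plateaus
  cases[[13]] <- matrix(0, 9, 9)
  g <- matrix(0.3, 8, 8); g[3, 3] <- 0; g[6, 6] <- 0; g[, 5] <- 1
  cases[[14]] <- g
  for (g in cases) {
    for (conn in c(4, 8)) {
      got <- pixels(watershedPartition(g, conn))
      want <- watershedOracle(g, conn)
      expect_identical(max(got), max(want))
      expect_true(labelsEquivalent(got, want))
    }
  }
})

test_that("every region contains exactly one regional minimum", {
  set.seed(5)
  g <- matrix(runif(400), 20, 20)
  gs <- pixels(lambdaSuppress(g, 0.1))
  lab <- pixels(watershedPartition(gs))
  # count minima plateaus per region with the oracle's definitions
  oracleLab <- watershedOracle(gs)
  expect_true(labelsEquivalent(lab, oracleLab))
  expect_identical(sort(unique(as.vector(lab))), seq_len(max(lab)))
})

test_that("region count is non-increasing in lambda on seeded phantoms", {
  for (s in 1:3) {
    ph <- makePhantom(PhantomSpec(size = c(96, 96), seed = s))
    g <- morphologicalGradient(ph$image, 1)
    counts <- vapply(c(0, 0.02, 0.05, 0.1, 0.2), function(l)
      max(pixels(watershedPartition(lambdaSuppress(g, l)))), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("four-sigma suppression removes pure Gaussian noise structure", {
  sig <- 0.05
  ones <- 0
  for (s in 1:20) {
    set.seed(s)
    m <- pmin(pmax(matrix(0.5 + rnorm(32 * 32, sd = sig), 32, 32), 0), 1)
    g <- lambdaSuppress(morphologicalGradient(m, 1), 4 * sig)
    ones <- ones + (max(pixels(watershedPartition(g))) == 1)
  }
  expect_gte(ones, 18)
})

test_that("candidate selection keeps bright regions and drops uniform images", {
  u <- matrix(0.5, 16, 16)
  lab <- watershedPartition(matrix(0, 16, 16))
  expect_identical(sum(pixels(candidateMask(u, lab))), 0L)
  # seeded tumor phantom: candidate overlaps truth well
  ph <- makePhantom(PhantomSpec(size = c(128, 128), seed = 8,
                                tumorDiameterMm = 16))
  seg <- taePisSegment(ph$image)
  expect_gte(diceCoefficient(seg$candidate, ph$mask), 0.6)
  # tumor-free phantoms are mostly clean
  emptyN <- 0
  for (s in 1:6) {
    phn <- makePhantom(PhantomSpec(size = c(128, 128), seed = 60 + s,
                                   tumorPresent = FALSE))
    emptyN <- emptyN + (sum(pixels(taePisSegment(phn$image)$candidate)) == 0)
  }
  expect_gte(emptyN, 5)
})

test_that("the composed stage localizes the tumor and partitions the image", {
  suppressWarnings({
    cimg <- GrayImage(matrix(0, 16, 16))
  })
  seg0 <- taePisSegment(cimg)
  expect_identical(max(pixels(seg0$labels)), 1L)
  expect_identical(sum(pixels(seg0$candidate)), 0L)
  ph <- makePhantom(PhantomSpec(size = c(128, 128), seed = 12,
                                tumorDiameterMm = 18))
  seg <- taePisSegment(ph$image)
  # partition: every pixel labelled once, ids 1..R
  expect_true(all(pixels(seg$labels) >= 1))
  expect_identical(dim(pixels(seg$labels)), c(128L, 128L))
  cc <- centroidOf(seg$candidate); tc <- centroidOf(ph$mask)
  expect_lte(sqrt(sum((cc - tc)^2)), 9)
})
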