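test_that("the circumscribing octagon strictly contains the box", {
  fr <- inscribeOctagon(c(1, 256, 1, 256))
  expect_gte(fr@circumradius, 128 * sqrt(2))
  expect_identical(dim(fr@vertices), c(8L, 2L))
  # vertices equally spaced by 45 degrees
  ang <- atan2(fr@center[1] - fr@vertices[, 1],
               fr@vertices[, 2] - fr@center[2]) * 180 / pi
  expect_equal(sort(ang %% 360), seq(0, 315, by = 45), tolerance = 1e-9)
  expect_error(inscribeOctagon(c(5, 4, 1, 2)), "degenerate")
})

test_that("the 8 sectors partition any box and respect tie-breaks", {
  set.seed(17)
  for (i in 1:30) {
    r0 <- sample(1:40, 1); c0 <- sample(1:40, 1)
    b <- c(r0, r0 + sample(7:90, 1), c0, c0 + sample(7:90, 1))
    fr <- inscribeOctagon(b)
    sm <- divideSectors(fr, b)
    expect_true(all(sm@ids %in% 1:8))
    expect_identical(length(sm@ids), bboxNpix(b))
    corners <- cbind(c(b[1], b[1], b[2], b[2]), c(b[3], b[4], b[3], b[4]))
    expect_true(all(octagonContains(fr, corners)))
  }
  # centre pixel of an odd box (angle undefined) goes to sector 1
  b <- c(1L, 9L, 1L, 9L)
  sm <- divideSectors(inscribeOctagon(b), b)
  expect_identical(sm@ids[5, 5], 1L)
})

test_that("square boxes give nearly equal sector populations", {
  b <- c(1L, 256L, 1L, 256L)
  sm <- divideSectors(inscribeOctagon(b), b)
  counts <- tabulate(sm@ids, 8)
  expect_lte(max(abs(counts - mean(counts))) / mean(counts), 0.01)
  # 4-fold symmetry: counts invariant under rotation by two sectors
  expect_identical(counts, counts[((0:7 + 2) %% 8) + 1])
})

test_that("time attributes follow the path bookkeeping rules", {
  expect_identical(timeAttributes(0, numeric()), c(0, 0, 0))
  expect_identical(timeAttributes(1, numeric()), c(1, 1, 1))
  expect_identical(timeAttributes(0.3, c(0.1, 0.2)), c(0.1, 0.2, 0.3))
  expect_identical(timeAttributes(0.5, 0.4), c(0.5, 0.4, 0.5))
})

test_that("spot scores collapse to |t' + t'' + t'''| for any order", {
  expect_identical(spotScore(c(0, 0, 0)), 0)
  expect_equal(spotScore(c(1, 2, 3), v = 2), 6)
  a <- c(0.12, 0.5, 0.07)
  expect_equal(spotScore(a, v = 1), spotScore(a, v = 2), tolerance = 1e-12)
  expect_equal(spotScore(a, v = 3.5), sum(a), tolerance = 1e-12)
  expect_error(spotScore(a, v = 0.5), ">= 1")
})

test_that("sector selection maximizes with deterministic tie-breaks", {
  expect_identical(selectSector(c(0, 0, 5, 0, 0, 0, 0, 0))$id, 3L)
  expect_true(selectSector(rep(0, 8))$noSpot)
  sel <- selectSector(c(2, 2, 1, 0, 0, 0, 0, 0))
  expect_identical(sel$id, 1L)
  expect_false(sel$noSpot)
  expect_error(selectSector(1:3), "8 sector")
})

test_that("stage-1 selection is equivariant under quarter rotation", {
  okn <- 0
  for (s in 1:10) {
    ph <- makePhantom(PhantomSpec(size = c(128, 128), seed = 300 + s,
                                  tumorCenter = c(40 + (s * 11) %% 50,
                                                  40 + (s * 17) %% 50),
                                  tumorDiameterMm = 14))
    cand <- pixels(taePisSegment(ph$image)$candidate)
    id1 <- stage1Sector(cand)
    id2 <- stage1Sector(rotCCW(cand))
    okn <- okn + (id2 == ((id1 - 1 + 2) %% 8) + 1)
  }
  expect_identical(okn, 10)
})

test_that("a candidate in the upper-left selects an upper-left sector", {
  # upper-left diagonal direction is 135 degrees: sectors 3 and 4
  cand <- matrix(0L, 64, 64)
  cand[12:18, 12:18] <- 1L
  expect_true(stage1Sector(cand) %in% c(3L, 4L))
  # and the angular-position oracle agrees for arbitrary placements
  set.seed(23)
  for (i in 1:10) {
    ang <- runif(1, 0, 360)
    ctr <- 32.5 + 22 * c(-sin(ang * pi / 180), cos(ang * pi / 180))
    cand <- matrix(0L, 64, 64)
    cand[round(ctr[1]) + (-2:2), round(ctr[2]) + (-2:2)] <- 1L
    got <- stage1Sector(cand)
    want <- floor((ang %% 360) / 45) + 1
    expect_lte(min(abs(got - want), 8 - abs(got - want)), 1)
  }
})

test_that("narrowing shrinks onto a one-sector candidate and terminates", {
  img <- GrayImage(matrix(0.5, 64, 64) + diag(1e-3, 64))
  cand <- matrix(0L, 64, 64)
  cand[10:14, 40:44] <- 1L  # upper-right, inside one sector
  loc <- locateSpot(img, BinaryMask(cand))
  expect_true(loc$state@terminated)
  expect_lte(loc$state@stage, loc$state@maxStages)
  # the spot is exactly the candidate: nothing was cut away
  expect_identical(pixels(loc$spot), cand)
  # history bbox areas strictly decrease
  areas <- vapply(loc$state@history,
                  function(h) prod(h$bbox[c(2, 4)] - h$bbox[c(1, 3)] + 1),
                  numeric(1))
  expect_true(all(diff(areas) < 0))
  # the final box lies within the first selected sector's quadrant
  expect_true(all(loc$state@bbox == c(9L, 15L, 39L, 45L)) ||
                bboxNpix(loc$state@bbox) <= bboxNpix(c(9L, 15L, 39L, 45L)) * 4)
})

test_that("empty candidates yield empty spots at stage zero", {
  img <- makePhantom(PhantomSpec(size = c(64, 64), seed = 1,
                                 tumorPresent = FALSE))$image
  loc <- locateSpot(img, BinaryMask(matrix(0L, 64, 64)))
  expect_identical(sum(pixels(loc$spot)), 0L)
  expect_identical(loc$state@stage, 0L)
  expect_true(loc$state@noSpot)
})

test_that("narrowing terminates within the stage cap on arbitrary candidates", {
  set.seed(41)
  img <- GrayImage(matrix(runif(64 * 64), 64, 64))
  for (i in 1:10) {
    cand <- matrix(rbinom(64 * 64, 1, runif(1, 0.005, 0.2)), 64, 64)
    loc <- locateSpot(img, BinaryMask(cand), maxStages = 10)
    expect_lte(loc$state@stage, 10)
    areas <- vapply(loc$state@history,
                    function(h) prod(h$bbox[c(2, 4)] - h$bbox[c(1, 3)] + 1),
                    numeric(1))
    if (length(areas) > 1) expect_true(all(diff(areas) < 0))
  }
})

test_that("the located spot preserves tumor pixels inside the chosen sector", {
  for (s in 1:5) {
    # mid-sector placement: the disc stays clear of all boundary rays, so
    # the preservation invariant's precondition holds at stage 1
    ang <- (22.5 + 45 * (s - 1)) * pi / 180
    ctr <- round(64.5 + 34 * c(-sin(ang), cos(ang)))
    ph <- makePhantom(PhantomSpec(size = c(128, 128), seed = 500 + s,
                                  tumorCenter = ctr,
                                  tumorDiameterMm = 12))
    seg <- taePisSegment(ph$image)
    loc <- locateSpot(ph$image, seg$candidate)
    kept <- pixels(loc$spot) & pixels(ph$mask)
    inCand <- pixels(seg$candidate) & pixels(ph$mask)
    # every true-tumor candidate pixel survives the narrowing
    expect_identical(sum(kept), sum(inCand))
    d <- sqrt(sum((centroidOf(loc$spot) - centroidOf(ph$mask))^2))
    expect_lte(d, 6)
  }
})
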