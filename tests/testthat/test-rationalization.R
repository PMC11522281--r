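test_that("rationalization rates are exact products over rates", {
  expect_equal(minRationalization(10, 5, 1)$value, 50)
  expect_equal(minRationalization(0, 99, 1)$value, 0)
  expect_equal(minRationalization(200, 66, 4)$value, 3300)
  expect_equal(maxRationalization(10, 10, 1)$value, 100)
  expect_equal(maxRationalization(1, 1, 2)$value, 0.5)
  expect_equal(maxRationalization(200, 80, 4)$value, 4000)
  expect_error(minRationalization(10, 5, 0), "> 0")
  expect_error(maxRationalization(10, 5, -1), "> 0")
})

test_that("max rationalization dominates min under its preconditions", {
  set.seed(3)
  for (i in 1:25) {
    total <- sample(1:300, 1)
    med <- sample(1:100, 1)
    mx <- med + sample(0:100, 1)          # maxProcessed >= medianProcessed
    minS <- runif(1, 0.5, 10)
    maxS <- runif(1, 0.1, minS)           # maxS <= minS
    expect_gte(maxRationalization(total, mx, maxS)$value,
               minRationalization(total, med, minS)$value)
  }
})

# a minimal narrowing state with prescribed per-stage signals
fakeState <- function(signalList) {
  st <- new("NarrowingState", bbox = c(1L, 8L, 1L, 8L),
            stage = length(signalList),
            history = lapply(signalList, function(s)
              list(bbox = c(1L, 8L, 1L, 8L), signals = s,
                   scores = s, selected = which.max(s),
                   selSignal = max(s))),
            stopDiameterMm = 3, maxStages = 10L, spacingMm = 1,
            terminated = TRUE, noSpot = FALSE)
  st
}

test_that("availability reflects which sectors held candidate pixels", {
  sig0 <- rep(0, 8)
  amEmpty <- availabilityMatrix(fakeState(list(sig0)))
  expect_true(all(amEmpty@alpha == 0))
  expect_identical(amEmpty@dAvail, 1L)  # floored at 1
  amFull <- availabilityMatrix(fakeState(list(rep(0.2, 8))))
  expect_true(all(amFull@alpha[, 1] == 1))
  sig <- c(0, 0, 0.4, 0, 0, 0, 0, 0)
  am <- availabilityMatrix(fakeState(list(sig, sig)))
  expect_identical(unname(which(rowSums(am@alpha) > 0)), 3L)
  expect_identical(am@delta, 2L)
  expect_identical(am@dAvail, 2L)
})

test_that("the availability of a phantom run concentrates on the tumor sector", {
  ph <- makePhantom(PhantomSpec(size = c(128, 128), seed = 77,
                                tumorCenter = c(40, 88),
                                tumorDiameterMm = 12))
  seg <- taePisSegment(ph$image)
  loc <- locateSpot(ph$image, seg$candidate)
  am <- availabilityMatrix(loc$state)
  # stage 1: only the tumor-bearing sector(s) are available
  expect_lte(sum(am@alpha[, 1]), 2)
  expect_gte(sum(am@alpha[, 1]), 1)
})

test_that("scores follow the stated log formula with known values", {
  am <- new("AvailabilityMatrix",
            alpha = cbind(c(1, rep(0, 7)), c(1, rep(0, 7))),
            baseValue = 0.176, delta = 4L, dAvail = 2L)
  dec <- rationalizationScore(am)
  expect_equal(dec@scoreMatrix[1, 1], 0.176 * log10(2), tolerance = 1e-12)
  expect_equal(dec@scoreMatrix[1, 1], 0.05298, tolerance = 1e-4)
  expect_identical(dec@selectedCell, c(1L, 1L))
  expect_true(dec@spotConfirmed)
  # scores live only on available cells
  expect_true(all(dec@scoreMatrix[am@alpha == 0] == 0))
})

test_that("zero availability rejects; log(1) = 0 falls back to availability", {
  amZero <- new("AvailabilityMatrix", alpha = matrix(0, 8, 2),
                baseValue = 0.176, delta = 2L, dAvail = 1L)
  decZero <- rationalizationScore(amZero)
  expect_false(decZero@spotConfirmed)
  expect_identical(length(decZero@selectedCell), 0L)
  amEq <- new("AvailabilityMatrix",
              alpha = matrix(c(1, rep(0, 7), 1, rep(0, 7)), 8, 2),
              baseValue = 0.176, delta = 2L, dAvail = 2L)
  decEq <- rationalizationScore(amEq)
  expect_true(all(decEq@scoreMatrix == 0))
  expect_true(decEq@spotConfirmed)
})

test_that("adding availability never flips a confirmation to a rejection", {
  set.seed(13)
  for (i in 1:20) {
    alpha <- matrix(rbinom(16, 1, 0.4), 8, 2)
    am <- new("AvailabilityMatrix", alpha = alpha, baseValue = 0.176,
              delta = 2L, dAvail = max(1L, as.integer(sum(alpha))))
    before <- rationalizationScore(am)@spotConfirmed
    zero <- which(alpha == 0)
    if (length(zero) == 0 || !before) next
    alpha2 <- alpha; alpha2[zero[1]] <- 1
    am2 <- new("AvailabilityMatrix", alpha = alpha2, baseValue = 0.176,
               delta = 2L, dAvail = max(1L, as.integer(sum(alpha2))))
    expect_true(rationalizationScore(am2)@spotConfirmed)
    # scale bound on every score
    sc <- rationalizationScore(am2)@scoreMatrix
    expect_lte(max(abs(sc)),
               0.176 * log10(max(am2@delta, am2@dAvail)) + 1e-12)
  }
})

test_that("confirmation passes the spot through or empties it", {
  spot <- BinaryMask(matrix(rbinom(64, 1, 0.5), 8, 8))
  yes <- new("RationalizationDecision", scoreMatrix = matrix(1, 8, 1),
             selectedCell = c(1L, 1L), spotConfirmed = TRUE)
  no <- new("RationalizationDecision", scoreMatrix = matrix(0, 8, 1),
            selectedCell = integer(0), spotConfirmed = FALSE)
  expect_identical(pixels(confirmSpot(yes, spot)), pixels(spot))
  expect_identical(sum(pixels(confirmSpot(no, spot))), 0L)
})
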