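# Evaluation battery: reconstruction quality (MSE, PSNR, SSIM), overlap
# (Dice), image-level confusion metrics, tumor area ratio and area error.

#' Mean squared error between two congruent rasters
#'
#' @param reference,test [GrayImage-class] objects or numeric matrices of
#'   equal shape.
#' @return Non-negative scalar.
#' @export
mseMetric <- function(reference, test) {
  a <- asPixelMatrix(reference); b <- asPixelMatrix(test)
  if (!all(dim(a) == dim(b))) stop("shape mismatch in mseMetric")
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(max^2 / MSE)`. Identical inputs (MSE 0) return `Inf`, the
#' unbounded marker.
#'
#' @param reference,test congruent rasters.
#' @param maxValue dynamic range, default 1 (use 255 for 8-bit rasters).
#' @return PSNR in dB, or `Inf`.
#' @export
psnrMetric <- function(reference, test, maxValue = 1) {
  if (maxValue <= 0) stop("maxValue must be > 0")
  mse <- mseMetric(reference, test)
  if (mse == 0) return(Inf)
  10 * log10(maxValue^2 / mse)
}

#' Internal: sums over all fully-contained (2r+1)^2 windows
#' @noRd
boxSumsValid <- function(m, r) {
  S <- rbind(0, cbind(0, m))
  S <- apply(S, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  w <- 2 * r + 1
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr - w + 1); ci <- seq_len(nc - w + 1)
  S[ri + w, ci + w, drop = FALSE] - S[ri, ci + w, drop = FALSE] -
    S[ri + w, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

#' Structural similarity index
#'
#' Standard three-term SSIM averaged over all fully-contained uniform
#' square windows, with `C1 = (k1 L)^2`, `C2 = (k2 L)^2` and population
#' (divide-by-N) window moments. Identical images score 1; the measure is
#' symmetric in its arguments.
#'
#' @param reference,test congruent rasters, both at least as large as the
#'   window.
#' @param k1,k2 stabilization constants, defaults 0.01 and 0.03.
#' @param windowRadius half-width of the uniform window, default 3 (7 x 7).
#' @param maxValue dynamic range L, default 1.
#' @return Scalar in \[-1, 1\].
#' @export
ssimMetric <- function(reference, test, k1 = 0.01, k2 = 0.03,
                       windowRadius = 3, maxValue = 1) {
  a <- asPixelMatrix(reference); b <- asPixelMatrix(test)
  if (!all(dim(a) == dim(b))) stop("shape mismatch in ssimMetric")
  w <- 2 * windowRadius + 1
  if (nrow(a) < w || ncol(a) < w)
    stop("image smaller than the SSIM window (", w, " x ", w, ")")
  N <- w * w
  C1 <- (k1 * maxValue)^2; C2 <- (k2 * maxValue)^2
  ux <- boxSumsValid(a, windowRadius) / N
  uy <- boxSumsValid(b, windowRadius) / N
  Exx <- boxSumsValid(a * a, windowRadius) / N
  Eyy <- boxSumsValid(b * b, windowRadius) / N
  Exy <- boxSumsValid(a * b, windowRadius) / N
  vx <- Exx - ux^2; vy <- Eyy - uy^2; cxy <- Exy - ux * uy
  ssimMap <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(ssimMap)
}

#' Dice similarity coefficient of two masks
#'
#' `2 |T ^ G| / (|T| + |G|)`; two empty masks agree perfectly and score 1.
#'
#' @param test,truth [BinaryMask-class] objects or 0/1 matrices of equal
#'   shape.
#' @return Scalar in \[0, 1\].
#' @export
diceCoefficient <- function(test, truth) {
  a <- asPixelMatrix(test) > 0; b <- asPixelMatrix(truth) > 0
  if (!all(dim(a) == dim(b))) stop("shape mismatch in diceCoefficient")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Confusion-matrix rates from image-level counts
#'
#' TPR (sensitivity) = TP/(TP+FN); TNR (specificity) = TN/(TN+FP), the
#' prose definition; `tnrLiteral` = TN/(TP+FN) is also reported for
#' fidelity audits of the printed (self-contradictory) formula. Precision =
#' TP/(TP+FP); accuracy = (TP+TN)/total. Metrics with a zero denominator
#' are `NA` (undefined marker).
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return Named list `tpr, tnr, tnrLiteral, precision, accuracy`.
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tpr = rate(tp, tp + fn),
       tnr = rate(tn, tn + fp),
       tnrLiteral = rate(tn, tp + fn),
       precision = rate(tp, tp + fp),
       accuracy = rate(tp + tn, tp + fp + tn + fn))
}

#' Tumor-to-brain area ratio in percent
#'
#' @param tumor tumor [BinaryMask-class] or 0/1 matrix.
#' @param brain brain-region mask of the same shape with positive area.
#' @return `100 * |tumor| / |brain|`.
#' @export
tumorRatio <- function(tumor, brain) {
  t <- asPixelMatrix(tumor) > 0; b <- asPixelMatrix(brain) > 0
  if (!all(dim(t) == dim(b))) stop("shape mismatch in tumorRatio")
  if (sum(b) == 0) stop("brain mask is empty")
  100 * sum(t) / sum(b)
}

#' Percent error between mentioned and estimated tumor areas
#'
#' `100 * (mentioned - estimated) / mentioned`, then the selected rounding
#' (truncation toward zero by default, which matches the bulk of published
#' per-case error tables).
#'
#' @param mentioned reference (ground-truth) area, > 0.
#' @param estimated estimated area.
#' @param rounding `"truncate"` (default), `"round"` or `"none"`.
#' @return Percent error, rounded per `rounding`.
#' @export
#' @examples
#' areaError(346828, 319823)  # 7
areaError <- function(mentioned, estimated,
                      rounding = c("truncate", "round", "none")) {
  rounding <- match.arg(rounding)
  if (mentioned <= 0) stop("mentioned area must be > 0")
  e <- 100 * (mentioned - estimated) / mentioned
  switch(rounding, truncate = trunc(e), round = round(e), none = e)
}

#' Internal: centroid (row, col) of a mask; NA for empty masks
#' @noRd
maskCentroid <- function(mask) {
  m <- asPixelMatrix(mask) > 0
  if (!any(m)) return(c(NA_real_, NA_real_))
  idx <- which(m, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Evaluate a dataset of predictions against a manifest
#'
#' For every manifest row the predicted mask is compared with the truth
#' mask (Dice, centroid error, tumor ratio against the brain region, area
#' error), the image-level detection flag is tallied into the confusion
#' counts (a tumor image with a positive flag is a TP, a normal image with
#' a negative flag a TN), and, when reconstructions are supplied, MSE/PSNR/
#' SSIM of the reconstruction against the original image are added.
#'
#' @param manifest data.frame from [makeDataset()] (columns `image`,
#'   `mask`, `tumor_present`).
#' @param predictions list of predicted [BinaryMask-class] objects (or 0/1
#'   matrices), one per row.
#' @param flags logical vector: per-image "tumor detected" calls.
#' @param reconstructions optional list of reconstructed rasters for the
#'   quality metrics.
#' @param psnrMax dynamic range for PSNR (default 1).
#' @param roundingMode rounding for [areaError()] (default `"none"` so the
#'   summary averages unrounded values).
#' @return A [MetricsReport-class].
#' @export
evaluateDataset <- function(manifest, predictions, flags,
                            reconstructions = NULL, psnrMax = 1,
                            roundingMode = "none") {
  n <- nrow(manifest)
  if (length(predictions) != n || length(flags) != n) {
    bad <- paste(setdiff(seq_len(n),
                         seq_len(min(length(predictions), length(flags)))),
                 collapse = ", ")
    stop("every manifest row needs a prediction and a flag; missing rows: ",
         bad)
  }
  rows <- vector("list", n)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(n)) {
    truthMask <- readMask(manifest$mask[i])
    img <- readImage(manifest$image[i])
    pred <- asPixelMatrix(predictions[[i]])
    truth <- pixels(truthMask)
    present <- isTRUE(manifest$tumor_present[i])
    detected <- isTRUE(flags[i])
    if (present && detected) tp <- tp + 1L
    else if (present && !detected) fn <- fn + 1L
    else if (!present && detected) fp <- fp + 1L
    else tn <- tn + 1L

    brain <- pixels(img) > 0.1 * max(pixels(img))
    d <- diceCoefficient(pred, truth)
    predC <- maskCentroid(pred); truthC <- maskCentroid(truth)
    centroidErr <- if (anyNA(predC) || anyNA(truthC)) NA_real_
      else sqrt(sum((predC - truthC)^2))
    ratio <- if (sum(brain) > 0) tumorRatio(pred, brain) else NA_real_
    aErr <- if (sum(truth) > 0)
      areaError(sum(truth), sum(pred), roundingMode) else NA_real_

    mseV <- psnrV <- ssimV <- NA_real_
    if (!is.null(reconstructions)) {
      rec <- asPixelMatrix(reconstructions[[i]])
      mseV <- mseMetric(img, rec)
      psnrV <- psnrMetric(img, rec, psnrMax)
      ssimV <- ssimMetric(img, rec, maxValue = psnrMax)
    }
    rows[[i]] <- data.frame(
      image = manifest$image[i], tumor_present = present,
      detected = detected, dice = d, centroid_error_px = centroidErr,
      tumor_ratio_pct = ratio, area_error_pct = aErr,
      mse = mseV, psnr_db = psnrV, ssim = ssimV,
      stringsAsFactors = FALSE)
  }
  perImage <- do.call(rbind, rows)
  conf <- confusionMetrics(tp, fp, tn, fn)
  tumorRows <- perImage$tumor_present
  summary <- c(
    tpr = conf$tpr, tnr = conf$tnr, precision = conf$precision,
    accuracy = conf$accuracy,
    mean_dice = if (any(tumorRows)) mean(perImage$dice[tumorRows]) else NA_real_,
    mean_area_error_pct = if (any(tumorRows))
      mean(perImage$area_error_pct[tumorRows], na.rm = TRUE) else NA_real_,
    mean_mse = mean(perImage$mse),
    mean_psnr_db = mean(perImage$psnr_db),
    mean_ssim = mean(perImage$ssim))
  new("MetricsReport", perImage = perImage,
      counts = c(tp = tp, fp = fp, tn = tn, fn = fn), summary = summary)
}
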