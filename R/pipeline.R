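# End-to-end orchestration: segment -> locate -> rationalize -> confirm ->
# evaluate, as one reproducible, seeded run with YAML config and JSON/CSV
# artifacts.

#' Default pipeline configuration
#'
#' Every numeric constant of the pipeline is reachable here: segmentation
#' (gradient kind, neighbourhood radius, lambda depth and iterations,
#' connectivity, candidate z), octagon narrowing (stop diameter in mm,
#' stage cap, margin, norm order), rationalization (base value 0.176, log
#' base 10) and evaluation (PSNR max, area-error rounding), plus the global
#' seed and output directory.
#'
#' @return Nested named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    segmentation = list(gradient = "morphological", neighborhood_radius = 1,
                        lambda_depth = 0.05, lambda_iters = 1,
                        connectivity = 8, candidate_z = 1.5),
    octagon = list(stop_diameter_mm = 3, max_stages = 10, margin = 0.05,
                   norm_order = 2),
    rationalization = list(base_value = 0.176, log_base = 10),
    evaluation = list(psnr_max = 1, rounding = "none"),
    seed = 1,
    out_dir = NULL
  )
}

#' Internal: merge a user config onto the defaults, rejecting unknown keys
#' @noRd
mergeConfig <- function(user, defaults = defaultConfig(), path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", paste(path, collapse = "."),
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown,
               sep = "", collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- mergeConfig(user[[k]], defaults[[k]], c(path, k))
    } else {
      defaults[k] <- user[k]
    }
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' Absent keys take their defaults; unknown keys raise an error naming
#' them. An empty file yields [defaultConfig()].
#'
#' @param path YAML file.
#' @return Full configuration list.
#' @export
loadConfig <- function(path) {
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop("malformed config file '", path,
                                            "': ", conditionMessage(e)))
  mergeConfig(user)
}

#' Internal: SegmentationParams from a config list
#' @noRd
paramsFromConfig <- function(config) {
  s <- config$segmentation
  SegmentationParams(gradientKind = s$gradient,
                     neighborhoodRadius = s$neighborhood_radius,
                     lambdaDepth = s$lambda_depth,
                     lambdaIters = s$lambda_iters,
                     connectivity = s$connectivity,
                     candidateZ = s$candidate_z)
}

#' Internal: run all stages on one in-memory image
#' @noRd
processOneImage <- function(img, config) {
  params <- paramsFromConfig(config)
  seg <- taePisSegment(img, params)
  loc <- locateSpot(img, seg$candidate,
                    stopDiameterMm = config$octagon$stop_diameter_mm,
                    maxStages = config$octagon$max_stages,
                    margin = config$octagon$margin,
                    v = config$octagon$norm_order)
  if (loc$state@stage > 0) {
    am <- availabilityMatrix(loc$state,
                             baseValue = config$rationalization$base_value)
    decision <- rationalizationScore(am,
                                     logBase = config$rationalization$log_base)
  } else {
    am <- NULL
    decision <- new("RationalizationDecision",
                    scoreMatrix = matrix(0, 8, 1),
                    selectedCell = integer(0), spotConfirmed = FALSE)
  }
  confirmed <- confirmSpot(decision, loc$spot)
  recon <- segmentedImage(img, seg$labels)
  list(segmentation = seg, location = loc, availability = am,
       decision = decision, confirmed = confirmed, reconstruction = recon,
       detected = decision@spotConfirmed && sum(pixels(confirmed)) > 0)
}

#' Run the full detection pipeline over a manifest or image list
#'
#' For each input image: hybrid segmentation, octagon narrowing,
#' rationalization scoring, confirmation, and (when truth masks are listed)
#' the evaluation battery. Per-image failures are recorded and skipped; the
#' run fails only if every image fails. When `config$out_dir` is set, all
#' artifacts are written beneath it: `masks/` (candidates), `spots/`
#' (confirmed spots), `traces/` (per-image JSON narrowing traces),
#' `report.csv`, `report.json` and `config.used.yaml`.
#'
#' @param config configuration list from [defaultConfig()] /
#'   [loadConfig()].
#' @param inputs data.frame manifest (columns `image`, optional `mask` and
#'   `tumor_present`) or character vector of image paths.
#' @return A run record: `list(config, perImage, report, failures,
#'   elapsedSec, version)`, classed `"octospotRun"`.
#' @export
runPipeline <- function(config = defaultConfig(), inputs) {
  t0 <- Sys.time()
  if (is.character(inputs)) {
    if (length(inputs) == 0) stop("no inputs")
    inputs <- data.frame(image = inputs, mask = NA_character_,
                         tumor_present = NA, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(inputs) || nrow(inputs) == 0) stop("no inputs")
  if (!"mask" %in% names(inputs)) inputs$mask <- NA_character_
  if (!"tumor_present" %in% names(inputs)) inputs$tumor_present <- NA

  outDir <- config$out_dir
  if (!is.null(outDir)) {
    for (d in c("", "masks", "spots", "traces"))
      dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(outDir, "config.used.yaml"))
  }

  results <- vector("list", nrow(inputs))
  failures <- character(0)
  for (i in seq_len(nrow(inputs))) {
    res <- tryCatch({
      img <- readImage(inputs$image[i])
      out <- processOneImage(img, config)
      if (!is.null(outDir)) {
        stem <- sub("\\.[a-zA-Z]+$", "", basename(inputs$image[i]))
        writeMask(out$segmentation$candidate,
                  file.path(outDir, "masks", paste0(stem, "_candidate.png")))
        writeMask(out$confirmed,
                  file.path(outDir, "spots", paste0(stem, "_spot.png")))
        trace <- list(
          image = inputs$image[i], detected = out$detected,
          stages = lapply(out$location$state@history, function(h)
            list(bbox = h$bbox, signals = h$signals, scores = h$scores,
                 selected = h$selected)))
        jsonlite::write_json(trace,
                             file.path(outDir, "traces",
                                       paste0(stem, "_trace.json")),
                             auto_unbox = TRUE, digits = NA)
      }
      out
    }, error = function(e) {
      message("image ", inputs$image[i], " failed: ", conditionMessage(e))
      conditionMessage(e)
    })
    if (is.character(res)) {
      failures <- c(failures, sprintf("%s: %s", inputs$image[i], res))
      results[[i]] <- NULL
    } else {
      results[[i]] <- res
    }
  }
  okIdx <- which(!vapply(results, is.null, logical(1)))
  if (length(okIdx) == 0) stop("all images failed: ",
                               paste(failures, collapse = "; "))

  report <- NULL
  evalIdx <- okIdx[!is.na(inputs$mask[okIdx]) & !is.na(inputs$tumor_present[okIdx])]
  if (length(evalIdx) > 0) {
    report <- evaluateDataset(
      inputs[evalIdx, , drop = FALSE],
      predictions = lapply(results[evalIdx], function(r) r$confirmed),
      flags = vapply(results[evalIdx], function(r) r$detected, logical(1)),
      reconstructions = lapply(results[evalIdx], function(r) r$reconstruction),
      psnrMax = config$evaluation$psnr_max,
      roundingMode = config$evaluation$rounding)
  }

  record <- list(config = config, results = results, report = report,
                 failures = failures,
                 elapsedSec = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")),
                 version = as.character(utils::packageVersion("octospot")))
  class(record) <- "octospotRun"

  if (!is.null(outDir) && !is.null(report)) {
    utils::write.csv(report@perImage, file.path(outDir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(counts = as.list(report@counts),
           summary = as.list(report@summary)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  record
}

#' Human-readable and JSON summary of a pipeline run
#'
#' Prints dataset confusion metrics, mean Dice and mean area error (or
#' "n/a" when no ground truth was evaluated) and returns the identical
#' numbers as a JSON string.
#'
#' @param record an `"octospotRun"` from [runPipeline()].
#' @return Invisibly, the JSON string.
#' @export
reportSummary <- function(record) {
  stopifnot(inherits(record, "octospotRun"))
  nOk <- sum(!vapply(record$results, is.null, logical(1)))
  cat(sprintf("octospot run: %d image(s) processed, %d failure(s), %.1f s\n",
              nOk, length(record$failures), record$elapsedSec))
  if (is.null(record$report)) {
    cat("evaluation: n/a (no ground-truth masks)\n")
    payload <- list(images = nOk, failures = length(record$failures),
                    evaluation = NULL)
  } else {
    s <- record$report@summary
    cnt <- record$report@counts
    fmt <- function(x) ifelse(is.na(x), "n/a", sprintf("%.4f", x))
    cat(sprintf("  counts: tp=%d fp=%d tn=%d fn=%d\n",
                cnt["tp"], cnt["fp"], cnt["tn"], cnt["fn"]))
    cat(sprintf("  accuracy: %s  tpr: %s  tnr: %s  precision: %s\n",
                fmt(s["accuracy"]), fmt(s["tpr"]), fmt(s["tnr"]),
                fmt(s["precision"])))
    cat(sprintf("  mean dice: %s  mean area error: %s %%\n",
                fmt(s["mean_dice"]), fmt(s["mean_area_error_pct"])))
    payload <- list(images = nOk, failures = length(record$failures),
                    evaluation = c(as.list(cnt), as.list(s)))
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  invisible(as.character(json))
}
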