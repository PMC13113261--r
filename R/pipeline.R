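# End-to-end orchestration behind the command-line interface: each run*()
# function reads/writes the standard file formats, logs structured lines
# and records a manifest (command, package version, seed, parameters,
# input hashes) that makes an exact, byte-identical rerun possible.

.writeTable <- function(tab, path, doubleCols = NULL) {
  out <- as.data.frame(tab)
  if (is.null(doubleCols))
    doubleCols <- names(out)[vapply(out, is.double, logical(1))]
  for (cn in doubleCols) out[[cn]] <- .fmtNum(out[[cn]])
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

.writeManifest <- function(outDir, command, seed, params, inputs = character()) {
  manifest <- list(
    command = command,
    package = "FaceSym",
    version = as.character(utils::packageVersion("FaceSym")),
    seed = seed,
    params = params,
    input_md5 = {
      h <- tools::md5sum(inputs[file.exists(inputs)])
      names(h) <- basename(names(h))
      as.list(h)
    })
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate and write a synthetic cohort (synth command)
#'
#' Writes \code{landmarks.csv}, \code{grades.csv}, \code{truth.csv} (the
#' noise-free expected pair angles) and \code{manifest.json} to
#' \code{outDir}. Reruns with identical config produce byte-identical
#' files.
#'
#' @param config a [syntheticConfig()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, the cohort list from [generateCohort()].
#' @export
runSynth <- function(config = syntheticConfig(), outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  coh <- generateCohort(config)
  writeLandmarkFile(coh$records, file.path(outDir, "landmarks.csv"))
  writeGradeFile(coh$grades, file.path(outDir, "grades.csv"))
  .writeTable(coh$truth, file.path(outDir, "truth.csv"))
  params <- unclass(config)
  params$expressionGain <- as.data.frame(params$expressionGain)
  .writeManifest(outDir, "synth", config$seed, params)
  .fsLog("synth", "wrote %d dataset(s) to %s", length(coh$records), outDir)
  invisible(coh)
}

#' Score a cohort of landmark files (analyze command)
#'
#' Runs alignment, pair angles and subset scores for every image and
#' writes \code{scores.csv} (per image and subset, with the alignment
#' parameters rotation_deg and midline_slope), \code{angles.csv} (long
#' per-pair angle table), \code{summary.csv} (per-expression score
#' statistics) and \code{manifest.json}.
#'
#' @param landmarks path to a landmark CSV/JSON, or a list of
#'   [DatasetRecord-class].
#' @param registry registry or built-in name.
#' @param outDir output directory.
#' @param subsets subset selectors (default: full + stored + regions).
#' @param writeAngles write the long angle table (default TRUE).
#' @return Invisibly, the [analyzeCohort()] result.
#' @export
runAnalyze <- function(landmarks, registry = "dense-225", outDir,
                       subsets = NULL, writeAngles = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character()
  records <- if (is.character(landmarks)) {
    inputs <- landmarks
    readLandmarkFile(landmarks)
  } else landmarks
  registry <- loadRegistry(registry)
  res <- analyzeCohort(records, registry, subsets)
  .writeTable(res$scores, file.path(outDir, "scores.csv"))
  if (writeAngles)
    .writeTable(res$angles, file.path(outDir, "angles.csv"))
  .writeTable(expressionSummary(res$scores),
              file.path(outDir, "summary.csv"))
  .writeManifest(outDir, "analyze", NA,
                 list(registry = registryName(registry),
                      subsets = if (is.null(subsets)) "default" else subsets),
                 inputs)
  .fsLog("analyze", "scored %d dataset(s) x 9 expressions", length(records))
  invisible(res)
}

#' Select informative pairs against clinical grades (select command)
#'
#' Computes per-unit deviations, per-pair eta-squared effects, the
#' threshold sweep with Kruskal-Wallis optimization, and the Spearman
#' correlation report. Writes \code{sweep.csv} (threshold trace),
#' \code{effects.csv}, \code{chosen_subset.json},
#' \code{correlation_report.csv} and \code{manifest.json}.
#'
#' @param angles path to an angles CSV (from [runAnalyze()]) or the long
#'   angle data.frame.
#' @param grades path to a grades CSV or a grade data.frame.
#' @param registry registry or built-in name (used to resolve the region
#'   splits of the chosen subset in the correlation report).
#' @param outDir output directory.
#' @param unit aggregation unit for the ANOVA ("session" or "patient").
#' @param objective sweep objective ("sum" or "min").
#' @return Invisibly, a list with the [SweepResult-class] and the
#'   correlation report.
#' @export
runSelect <- function(angles, grades, registry = "dense-225", outDir,
                      unit = "session", objective = "sum") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character()
  if (is.character(angles)) {
    inputs <- c(inputs, angles)
    angles <- as.data.frame(data.table::fread(angles, colClasses = list(
      character = "dataset_id")))
  }
  if (is.character(grades)) {
    inputs <- c(inputs, grades)
    grades <- readGradeFile(grades)
  }
  registry <- loadRegistry(registry)
  nd <- length(unique(grades$dataset_id[grades$dataset_id %in%
                                          angles$dataset_id]))
  if (nd > 0) {
    for (cond in c("stennert_rest", "stennert_move"))
      if (length(unique(grades[[cond]])) < 2L)
        .fsStop("selection", "grade coverage needs >= 2 distinct %s levels",
                cond)
  }
  ud <- unitDeviations(angles, grades, unit)
  eff <- pairEffects(ud$dev, ud$units)
  sweep <- thresholdSweep(eff, ud$dev, ud$units, objective = objective)
  .writeTable(sweep@trace, file.path(outDir, "sweep.csv"))
  .writeTable(eff, file.path(outDir, "effects.csv"))
  jsonlite::write_json(
    list(registry = registryName(registry),
         chosen = sweep@chosenSubset,
         threshold = sweep@chosenThreshold,
         min_eta2 = sweep@minEta2,
         objective = sweep@objective,
         non_discriminative = sweep@nonDiscriminative),
    file.path(outDir, "chosen_subset.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)

  # correlation report over the chosen subset and its region splits
  region <- registryPairs(registry)$region
  chosen <- sweep@chosenSubset
  subsetList <- c(list(chosen = chosen),
                  lapply(split(chosen, region[chosen]), identity))
  scores <- .scoresFromAngles(angles, subsetList)
  report <- correlationReport(scores, grades)
  .writeTable(report, file.path(outDir, "correlation_report.csv"))
  .writeManifest(outDir, "select", NA,
                 list(registry = registryName(registry), unit = unit,
                      objective = objective), inputs)
  .fsLog("select", "chose %d pair(s) at threshold %.3f (min eta2 %.3f)",
         length(chosen), sweep@chosenThreshold, sweep@minEta2)
  invisible(list(sweep = sweep, report = report, deviations = ud,
                 effects = eff))
}

# per-image scores for arbitrary ordinal subsets from a long angle table
.scoresFromAngles <- function(angles, subsetList) {
  angles <- as.data.frame(angles)
  out <- list()
  keys <- unique(angles[, c("dataset_id", "expression_id")])
  ord <- order(keys$dataset_id, keys$expression_id)
  keys <- keys[ord, , drop = FALSE]
  wide <- tapply(angles$theta_deg,
                 list(paste(angles$dataset_id, angles$expression_id,
                            sep = "|"),
                      factor(angles$pair_ordinal)), identity)
  rows <- paste(keys$dataset_id, keys$expression_id, sep = "|")
  wide <- matrix(as.numeric(wide[rows, ]), nrow = length(rows))
  for (nm in names(subsetList)) {
    s <- subsetList[[nm]]
    out[[nm]] <- data.frame(
      dataset_id = keys$dataset_id, expression_id = keys$expression_id,
      subset_name = nm, n_pairs = length(s),
      score_deg = rowMeans(abs(wide[, s, drop = FALSE])))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Rotation-robustness protocol (robustness command)
#'
#' Writes \code{robustness.csv} (rotation_deg, mean_abs_dev,
#' median_abs_dev, n_images) and \code{manifest.json}.
#'
#' @param landmarks landmark CSV path or list of records.
#' @param registry registry or built-in name.
#' @param outDir output directory.
#' @param subset score subset selector.
#' @param grid rotation grid in degrees (default -25..25 step 1, no 0).
#' @param mode "transform" or "redetect".
#' @param noiseSd per-rotation landmark noise SD (transform mode).
#' @param seed RNG seed used when \code{noiseSd > 0}.
#' @return Invisibly, the [RobustnessReport-class].
#' @export
runRobustness <- function(landmarks, registry = "dense-225", outDir,
                          subset = NULL, grid = setdiff(-25:25, 0),
                          mode = "transform", noiseSd = 0, seed = 1) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character()
  records <- if (is.character(landmarks)) {
    inputs <- landmarks
    readLandmarkFile(landmarks)
  } else landmarks
  if (noiseSd > 0) set.seed(seed)
  rep <- rotationSweep(records, registry, subset = subset, grid = grid,
                       mode = mode, noiseSd = noiseSd)
  .writeTable(robustnessTable(rep), file.path(outDir, "robustness.csv"))
  .writeManifest(outDir, "robustness", seed,
                 list(registry = if (is.character(registry)) registry
                      else registryName(registry),
                      subset = if (is.null(subset)) "default" else subset,
                      grid = range(grid), mode = mode, noiseSd = noiseSd),
                 inputs)
  .fsLog("robustness", "overall |dev| %.4g +/- %.4g deg over %d rotations",
         rep@overallMean, rep@overallSD, nrow(rep@perRotation))
  invisible(rep)
}

#' Render angle maps for every image of a cohort (anglemap command)
#'
#' Writes one SVG per (dataset, expression) to \code{outDir} plus a
#' manifest.
#'
#' @param landmarks landmark CSV path or list of records.
#' @param registry registry or built-in name.
#' @param outDir output directory.
#' @param subset subset selector.
#' @param style a [mapStyle()].
#' @return Invisibly, the vector of written file paths.
#' @export
runAngleMap <- function(landmarks, registry = "dense-225", outDir,
                        subset = "full", style = mapStyle()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character()
  records <- if (is.character(landmarks)) {
    inputs <- landmarks
    readLandmarkFile(landmarks)
  } else landmarks
  registry <- loadRegistry(registry)
  mid <- midlineIndices(registry)
  files <- character()
  for (rec in records) {
    for (e in 1:9) {
      lm <- expressions(rec)[[as.character(e)]]
      al <- alignLandmarks(lm, mid)
      av <- pairAngles(al@aligned, registry)
      f <- file.path(outDir, sprintf("map_%s_expr%d.svg",
                                     datasetId(rec), e))
      renderAngleMap(al@aligned, av, registry, subset, style, file = f)
      files <- c(files, f)
    }
  }
  .writeManifest(outDir, "anglemap", NA,
                 list(registry = registryName(registry), subset = subset,
                      clipDeg = style$clipDeg,
                      background = style$background), inputs)
  .fsLog("anglemap", "rendered %d map(s)", length(files))
  invisible(files)
}
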