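# Rotation-robustness protocol: rotate every image in-plane over a grid of
# artificial head rotations, re-run the full pipeline (midline re-fit,
# re-alignment, pair angles, score) and measure the absolute score
# deviation from the unrotated image.

#' Score stability under artificial in-plane head rotations
#'
#' For each rotation r in \code{grid} and each (dataset, expression) image,
#' the raw landmarks are rotated by r about the image centre, the full
#' pipeline is applied, and |Score(r) - Score(0)| is recorded; deviations
#' are averaged over all images equally (mean and median per rotation plus
#' an overall mean and SD).
#'
#' In \code{"transform"} mode the rotation acts on landmark coordinates
#' analytically; alignment then undoes it exactly, so deviations measure
#' only floating-point rigidity (expected < 1e-6 degrees) unless fresh
#' landmark noise is injected per rotation via \code{noiseSd}, which
#' emulates detector re-localization error. \code{"redetect"} mode re-runs
#' a detector adapter on rotated, resampled source images and reflects true
#' detector variability; it requires an adapter and image paths.
#'
#' @param records list of [DatasetRecord-class].
#' @param registry a [PairRegistry-class] or built-in name.
#' @param subset pair-subset selector for the score (default "91" when
#'   stored, else full).
#' @param grid rotation angles in degrees; default -25..25 step 1,
#'   excluding 0.
#' @param mode "transform" (default) or "redetect".
#' @param noiseSd per-rotation landmark noise SD in pixels (transform mode
#'   only; default 0).
#' @param adapter detector adapter for redetect mode.
#' @param imagePaths function(dataset_id, expression_id) -> image path, for
#'   redetect mode.
#' @return A [RobustnessReport-class].
#' @export
rotationSweep <- function(records, registry, subset = NULL,
                          grid = setdiff(-25:25, 0),
                          mode = c("transform", "redetect"),
                          noiseSd = 0, adapter = NULL,
                          imagePaths = NULL) {
  mode <- match.arg(mode)
  registry <- loadRegistry(registry)
  if (is.null(subset))
    subset <- if ("91" %in% names(registry@subsets)) "91" else "full"
  sidx <- registrySubset(registry, subset)
  mid <- midlineIndices(registry)
  grid <- sort(unique(as.numeric(grid)))
  grid <- grid[grid != 0]
  if (mode == "redetect" && (is.null(adapter) || is.null(imagePaths)))
    .fsStop("capability",
            "redetect mode requires a detector adapter and image paths; use mode = \"transform\" for landmark-only input")

  scoreOf <- function(lm) {
    al <- alignLandmarks(lm, mid)
    mean(abs(angleValues(pairAngles(al@aligned, registry))[sidx]))
  }

  images <- list()
  for (rec in records)
    for (e in 1:9)
      images[[length(images) + 1L]] <- expressions(rec)[[as.character(e)]]
  base <- vapply(images, scoreOf, numeric(1))

  dev <- matrix(NA_real_, length(grid), length(images))
  nMissing <- 0L
  for (gi in seq_along(grid)) {
    r <- grid[gi]
    for (ii in seq_along(images)) {
      lm <- images[[ii]]
      rotated <- tryCatch({
        if (mode == "transform") {
          xy <- .rotateCoords(landmarkCoords(lm), r, .imageCenter(lm))
          if (noiseSd > 0)
            xy <- xy + stats::rnorm(length(xy), 0, noiseSd)
          landmarkSet(datasetId(lm), expressionId(lm), xy,
                      imageSize(lm)[["width"]], imageSize(lm)[["height"]])
        } else {
          detectLandmarks(imagePaths(datasetId(lm), expressionId(lm)),
                          adapter, datasetId(lm), expressionId(lm),
                          imageSize(lm)[["width"]],
                          imageSize(lm)[["height"]])
        }
      }, FaceSym_detection_error = function(err) NULL)
      if (is.null(rotated)) { nMissing <- nMissing + 1L; next }
      dev[gi, ii] <- abs(scoreOf(rotated) - base[ii])
    }
  }
  if (nMissing > 0)
    .fsLog("robustness", "%d (image, rotation) cell(s) missing after redetect failures",
           nMissing, level = "WARN")
  perRot <- data.frame(
    rotation_deg = grid,
    mean_abs_dev = rowMeans(dev, na.rm = TRUE),
    median_abs_dev = apply(dev, 1, stats::median, na.rm = TRUE),
    n_images = rowSums(!is.na(dev)))
  all <- dev[!is.na(dev)]
  new("RobustnessReport", perRotation = perRot,
      overallMean = mean(all),
      overallSD = if (length(all) > 1) stats::sd(all) else 0,
      mode = mode)
}

#' Robustness report as a data.frame
#'
#' @param report a [RobustnessReport-class].
#' @return The per-rotation table (rotation_deg, mean_abs_dev,
#'   median_abs_dev, n_images).
#' @export
robustnessTable <- function(report) {
  stopifnot(is(report, "RobustnessReport"))
  report@perRotation
}
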