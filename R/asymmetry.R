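# Angle features and asymmetry scores. For each left/right landmark pair
# the signed angle of the connecting segment against the horizontal is
# theta = (180/pi) * atan2(yR - yL, xR - xL); the asymmetry score of a pair
# subset is the mean of |theta| in degrees.

#' @describeIn pairAngles Compute the signed pair-angle feature vector of an
#'   aligned landmark set.
#'
#' Angles are meaningful only after head alignment ([alignLandmarks()]);
#' the function does not re-align. The sign convention follows the raster
#' y-down axis: positive theta means the right-side landmark sits lower in
#' the image. Coincident pair points yield theta = 0 with a logged warning
#' (the atan2(0, 0) convention), never an error.
#'
#' @param set an aligned [LandmarkSet-class].
#' @param registry a [PairRegistry-class] (or built-in name).
#' @return An [AngleVector-class] with one signed angle in degrees per
#'   registry pair, each in (-180, 180].
#' @examples
#' reg <- loadRegistry("sparse-21")
#' tpl <- makeTemplate(registry = reg)
#' all(angleValues(pairAngles(tpl, reg)) == 0)  # symmetric template
#' @export
setMethod("pairAngles", "LandmarkSet", function(set, registry) {
  registry <- loadRegistry(registry)
  xy <- landmarkCoords(set)
  if (nrow(xy) != nLandmarks(registry))
    .fsStop("argument",
            "landmark set has %d points but registry '%s' expects %d",
            nrow(xy), registryName(registry), nLandmarks(registry))
  p <- registryPairs(registry)
  dx <- xy[p$right + 1L, "x"] - xy[p$left + 1L, "x"]
  dy <- xy[p$right + 1L, "y"] - xy[p$left + 1L, "y"]
  coincident <- dx == 0 & dy == 0
  theta <- 180 / pi * atan2(dy, dx)
  if (any(coincident)) {
    theta[coincident] <- 0
    .fsWarn("coincident",
            "%d coincident landmark pair(s) in dataset '%s' expression %d; theta set to 0",
            sum(coincident), datasetId(set), expressionId(set))
  }
  new("AngleVector", datasetId = datasetId(set),
      expressionId = expressionId(set),
      registryName = registryName(registry), theta = as.numeric(theta))
})

#' Asymmetry score: mean absolute pair angle over a subset
#'
#' The global (or regional) asymmetry score of one image is
#' \deqn{Score = (1/N) \sum_{i \in S} |\theta_i|}
#' in degrees over the selected pair subset S; higher values indicate
#' greater asymmetry, 0 means every selected pair is exactly horizontal.
#'
#' @param angles an [AngleVector-class] (or plain numeric vector of angles
#'   in degrees).
#' @param subset 1-based pair ordinals into the angle vector; defaults to
#'   all pairs.
#' @param subsetName label recorded in the result.
#' @return One-row data.frame: \code{dataset_id}, \code{expression_id},
#'   \code{subset_name}, \code{n_pairs}, \code{score_deg}.
#' @examples
#' av <- new("AngleVector", datasetId = "d", expressionId = 1L,
#'           registryName = "custom", theta = c(1, -2, 3))
#' scoreAI(av)$score_deg  # 2
#' @export
scoreAI <- function(angles, subset = NULL, subsetName = "custom") {
  theta <- if (is(angles, "AngleVector")) angleValues(angles) else
    as.numeric(angles)
  if (is.null(subset)) subset <- seq_along(theta)
  subset <- as.integer(subset)
  if (length(subset) == 0L)
    .fsStop("argument", "pair subset must be non-empty")
  if (any(subset < 1L) || any(subset > length(theta)))
    .fsStop("argument", "pair ordinals out of range")
  data.frame(
    dataset_id = if (is(angles, "AngleVector")) datasetId(angles) else NA_character_,
    expression_id = if (is(angles, "AngleVector")) expressionId(angles) else NA_integer_,
    subset_name = subsetName,
    n_pairs = length(subset),
    score_deg = mean(abs(theta[subset])))
}

#' Region-wise asymmetry scores
#'
#' Splits a base pair subset by its registry region labels (eye, nose,
#' mouth) and scores each region separately. The full-subset score is the
#' pair-count-weighted mean of the region scores by construction, so
#' regional scores decompose the global one exactly.
#'
#' @param angles an [AngleVector-class].
#' @param registry the defining [PairRegistry-class].
#' @param baseSubset subset selector passed to [registrySubset()]
#'   (default the stored \code{"91"} subset when present).
#' @param regions regions to report.
#' @return data.frame with one row per region present in the base subset;
#'   regions absent from the subset are omitted with a warning.
#' @export
regionScores <- function(angles, registry, baseSubset = "91",
                         regions = c("eye", "nose", "mouth")) {
  registry <- loadRegistry(registry)
  base <- registrySubset(registry, baseSubset)
  lab <- registryPairs(registry)$region[base]
  out <- list()
  for (r in regions) {
    s <- base[lab == r]
    if (length(s) == 0L) {
      .fsWarn("region", "region '%s' absent from subset; omitted", r)
      next
    }
    out[[r]] <- scoreAI(angles, s, subsetName = r)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Analyze a cohort: align, compute angles and subset scores per image
#'
#' Runs the full per-image pipeline (midline fit, rigid alignment, pair
#' angles, subset scores) over a list of dataset records. This is the
#' engine behind the \code{analyze} command.
#'
#' @param records list of [DatasetRecord-class].
#' @param registry a [PairRegistry-class] or built-in name.
#' @param subsets character vector of subset selectors (see
#'   [registrySubset()]); default: \code{"full"}, every stored subset, and
#'   the three regions.
#' @return List with elements
#'   \item{scores}{long data.frame: patient_id, dataset_id, session_order,
#'     expression_id, subset_name, n_pairs, score_deg, rotation_deg,
#'     midline_slope;}
#'   \item{angles}{long data.frame: dataset_id, expression_id,
#'     pair_ordinal, theta_deg, region;}
#'   \item{thetaMatrix}{images x pairs matrix of signed angles, rownames
#'     \code{"<dataset>|<expression>"};}
#'   \item{imageInfo}{per-image metadata aligned with thetaMatrix rows.}
#' @export
analyzeCohort <- function(records, registry, subsets = NULL) {
  registry <- loadRegistry(registry)
  if (is.null(subsets)) {
    subsets <- c("full", names(registry@subsets))
    if (all(c("91") %in% names(registry@subsets)) ||
        any(registryPairs(registry)$region %in% c("eye", "nose", "mouth")))
      subsets <- c(subsets, intersect(
        c("eye", "nose", "mouth"),
        unique(registryPairs(registry)$region)))
  }
  subsetIdx <- lapply(subsets, function(s) registrySubset(registry, s))
  names(subsetIdx) <- subsets
  mid <- midlineIndices(registry)
  region <- registryPairs(registry)$region

  nImg <- length(records) * 9L
  theta <- matrix(NA_real_, nImg, nPairs(registry))
  info <- vector("list", nImg)
  scores <- vector("list", nImg)
  k <- 0L
  for (rec in records) {
    for (e in 1:9) {
      k <- k + 1L
      lm <- expressions(rec)[[as.character(e)]]
      al <- alignLandmarks(lm, mid)
      av <- pairAngles(al@aligned, registry)
      theta[k, ] <- angleValues(av)
      info[[k]] <- data.frame(
        patient_id = patientId(rec), dataset_id = datasetId(rec),
        session_order = sessionOrder(rec), expression_id = e,
        rotation_deg = al@rotationDeg, midline_slope = al@fit@slope)
      scores[[k]] <- do.call(rbind, lapply(names(subsetIdx), function(nm) {
        s <- subsetIdx[[nm]]
        data.frame(subset_name = nm, n_pairs = length(s),
                   score_deg = mean(abs(theta[k, s])))
      }))
    }
  }
  info <- do.call(rbind, c(info, list(make.row.names = FALSE)))
  rownames(theta) <- paste(info$dataset_id, info$expression_id, sep = "|")
  scoreTab <- do.call(rbind, Map(function(i, sc) {
    cbind(info[rep(i, nrow(sc)), c("patient_id", "dataset_id",
                                   "session_order", "expression_id")], sc,
          row.names = NULL)
  }, seq_len(nImg), scores))
  scoreTab <- scoreTab[, c("patient_id", "dataset_id", "session_order",
                           "expression_id", "subset_name", "n_pairs",
                           "score_deg")]
  scoreTab$rotation_deg <- info$rotation_deg[
    match(paste(scoreTab$dataset_id, scoreTab$expression_id),
          paste(info$dataset_id, info$expression_id))]
  scoreTab$midline_slope <- info$midline_slope[
    match(paste(scoreTab$dataset_id, scoreTab$expression_id),
          paste(info$dataset_id, info$expression_id))]
  anglesLong <- data.frame(
    dataset_id = rep(info$dataset_id, each = ncol(theta)),
    expression_id = rep(info$expression_id, each = ncol(theta)),
    pair_ordinal = rep(seq_len(ncol(theta)), times = nrow(theta)),
    theta_deg = as.vector(t(theta)),
    region = rep(region, times = nrow(theta)))
  list(scores = scoreTab, angles = anglesLong, thetaMatrix = theta,
       imageInfo = info)
}

#' Per-expression summary statistics of asymmetry scores
#'
#' Summarises a cohort's scores per expression 1-9 plus the per-dataset
#' overall average ("all" = unweighted mean of the nine expression scores
#' of a dataset): mean, sample SD (n - 1), variance, median, max, min
#' across datasets.
#'
#' @param scores data.frame with at least \code{dataset_id},
#'   \code{expression_id}, \code{score_deg}; a \code{subset_name} column,
#'   when present, is summarised per subset.
#' @return data.frame with columns subset_name (if given), expression
#'   ("1".."9", "all"), n, mean, sd, var, median, max, min.
#' @export
expressionSummary <- function(scores) {
  scores <- as.data.frame(scores)
  if (nrow(scores) == 0L)
    return(data.frame(expression = character(0), n = integer(0),
                      mean = numeric(0), sd = numeric(0), var = numeric(0),
                      median = numeric(0), max = numeric(0),
                      min = numeric(0)))
  bySubset <- "subset_name" %in% names(scores)
  groups <- if (bySubset) split(scores, scores$subset_name)
            else list(scores)
  out <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    stat1 <- function(v) {
      if (length(v) == 0L)
        return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                          var = NA_real_, median = NA_real_,
                          max = NA_real_, min = NA_real_))
      data.frame(
        n = length(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        var = if (length(v) > 1) stats::var(v) else 0,
        median = stats::median(v), max = max(v), min = min(v))
    }
    rows <- lapply(1:9, function(e) {
      v <- g$score_deg[g$expression_id == e]
      cbind(data.frame(expression = as.character(e)), stat1(v))
    })
    allPer <- tapply(g$score_deg, g$dataset_id, mean)
    rows <- c(rows, list(cbind(data.frame(expression = "all"),
                               stat1(as.numeric(allPer)))))
    res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (bySubset)
      res <- cbind(data.frame(subset_name = names(groups)[gi]), res)
    res
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
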