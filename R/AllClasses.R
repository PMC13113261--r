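#' LandmarkSet: one image's indexed 2-D facial landmarks
#'
#' Holds the detected landmarks of a single photograph in pixel coordinates
#' (x rightward, y downward, 0-based raster convention). Landmark index
#' \code{i} (0-based) lives in row \code{i + 1} of the coordinate matrix, so
#' every index in \code{0..(n-1)} appears exactly once.
#'
#' @slot datasetId character, identifier of the acquisition session.
#' @slot expressionId integer in 1..9, the standardized facial expression
#'   (1 neutral, 2 gentle eye closure, 3 forced eye closure, 4 frowning,
#'   5 nose wrinkling, 6 closed-mouth stretch, 7 mouth stretch with teeth,
#'   8 lip pursing, 9 downward mouth-corner movement).
#' @slot imageWidth,imageHeight positive image dimensions in pixels.
#' @slot coords numeric matrix with columns \code{x}, \code{y}; one row per
#'   landmark, in index order.
#'
#' @seealso [landmarkSet()] for the user constructor.
#' @export
setClass("LandmarkSet",
  slots = c(
    datasetId = "character",
    expressionId = "integer",
    imageWidth = "numeric",
    imageHeight = "numeric",
    coords = "matrix"
  )
)

setValidity("LandmarkSet", function(object) {
  msgs <- character()
  if (length(object@datasetId) != 1L)
    msgs <- c(msgs, "datasetId must be a single string")
  if (length(object@expressionId) != 1L ||
      !object@expressionId %in% 1:9)
    msgs <- c(msgs, "expressionId must be a single integer in 1..9")
  if (length(object@imageWidth) != 1L || object@imageWidth <= 0 ||
      length(object@imageHeight) != 1L || object@imageHeight <= 0)
    msgs <- c(msgs, "image dimensions must be positive")
  if (ncol(object@coords) != 2L)
    msgs <- c(msgs, "coords must have two columns (x, y)")
  if (!is.numeric(object@coords) || any(!is.finite(object@coords)))
    msgs <- c(msgs, "coords must be finite numeric")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LandmarkSet
#'
#' @param datasetId session identifier.
#' @param expressionId expression number, 1..9.
#' @param coords numeric matrix (n x 2) of pixel coordinates in landmark
#'   index order (row k holds landmark index k - 1).
#' @param imageWidth,imageHeight image dimensions in pixels.
#' @return A [LandmarkSet-class] object.
#' @examples
#' lm <- landmarkSet("d1", 1, cbind(x = c(0, 10), y = c(5, 5)), 100, 100)
#' nLandmarks(lm)
#' @export
landmarkSet <- function(datasetId, expressionId, coords,
                        imageWidth, imageHeight) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y")
  new("LandmarkSet",
      datasetId = as.character(datasetId),
      expressionId = as.integer(expressionId),
      imageWidth = as.numeric(imageWidth),
      imageHeight = as.numeric(imageHeight),
      coords = coords)
}

#' PairRegistry: left/right landmark index pairs with region labels
#'
#' A registry names, for a given landmark model (478-point dense mesh or
#' 68-point layouts), which landmark indices form mirror-corresponding
#' left/right pairs, which region each pair belongs to, and which indices
#' define the facial midline used for head alignment. Registries are data,
#' not code: they are shipped as JSON assets and every pipeline stage is
#' registry-parametric.
#'
#' @slot name registry name (e.g. \code{"dense-225"}).
#' @slot nLandmarks total landmark count of the model (478 or 68).
#' @slot pairs data.frame with columns \code{left}, \code{right} (0-based
#'   landmark indices) and \code{region} (one of eye, nose, mouth, other).
#' @slot midlineIndices 0-based indices of the central-axis landmarks used
#'   for the midline fit.
#' @slot subsets named list of stored pair-ordinal subsets (1-based ordinals
#'   into \code{pairs}), e.g. the reduced 140/91/50/21 configurations.
#'
#' @seealso [loadRegistry()], [registrySubset()]
#' @export
setClass("PairRegistry",
  slots = c(
    name = "character",
    nLandmarks = "integer",
    pairs = "data.frame",
    midlineIndices = "integer",
    subsets = "list"
  )
)

setValidity("PairRegistry", function(object) {
  msgs <- character()
  p <- object@pairs
  if (!all(c("left", "right", "region") %in% names(p)))
    return("pairs must have columns left, right, region")
  members <- c(p$left, p$right)
  if (anyDuplicated(members)) {
    dup <- unique(members[duplicated(members)])
    msgs <- c(msgs, sprintf(
      "landmark index in more than one pair position: %s",
      paste(dup, collapse = ", ")))
  }
  if (any(p$left == p$right))
    msgs <- c(msgs, "a pair may not use the same index on both sides")
  overlap <- intersect(object@midlineIndices, members)
  if (length(overlap))
    msgs <- c(msgs, sprintf("midline indices also used in pairs: %s",
                            paste(overlap, collapse = ", ")))
  allIdx <- c(members, object@midlineIndices)
  if (length(allIdx) && (min(allIdx) < 0 || max(allIdx) >= object@nLandmarks))
    msgs <- c(msgs, "landmark indices out of range for nLandmarks")
  if (!all(p$region %in% c("eye", "nose", "mouth", "other")))
    msgs <- c(msgs, "region labels must be eye/nose/mouth/other")
  for (nm in names(object@subsets)) {
    s <- object@subsets[[nm]]
    if (anyDuplicated(s) || any(s < 1L) || any(s > nrow(p)))
      msgs <- c(msgs, sprintf("subset '%s' has invalid pair ordinals", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' DatasetRecord: one acquisition session (nine expressions)
#'
#' A dataset is one patient visit: nine standardized facial photographs.
#' Sessions missing any of the nine expressions are excluded at read time,
#' so a valid record always carries the complete expression battery.
#'
#' @slot patientId patient identifier.
#' @slot datasetId session identifier (unique per visit).
#' @slot sessionOrder chronological session number within the patient (>= 1).
#' @slot expressions named list \code{"1".."9"} of [LandmarkSet-class].
#' @export
setClass("DatasetRecord",
  slots = c(
    patientId = "character",
    datasetId = "character",
    sessionOrder = "integer",
    expressions = "list"
  )
)

setValidity("DatasetRecord", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@expressions)), sort(as.character(1:9))))
    msgs <- c(msgs, "all nine expressions (1..9) must be present")
  if (!all(vapply(object@expressions, is, logical(1), "LandmarkSet")))
    msgs <- c(msgs, "expressions must be LandmarkSet objects")
  if (length(object@sessionOrder) != 1L || object@sessionOrder < 1L)
    msgs <- c(msgs, "sessionOrder must be a single integer >= 1")
  if (length(msgs)) msgs else TRUE
})

#' MidlineFit: ordinary-least-squares facial midline
#'
#' The midline is fitted as \eqn{x = a + b y} (x regressed on y): a facial
#' midline is vertical up to head tilt, which makes this orientation
#' well-posed where y-on-x would be degenerate.
#'
#' @slot intercept intercept \eqn{a} in pixels.
#' @slot slope dimensionless slope \eqn{b}.
#' @slot nPoints number of midline landmarks used.
#' @slot rss residual sum of squares in pixels^2.
#' @export
setClass("MidlineFit",
  slots = c(intercept = "numeric", slope = "numeric",
            nPoints = "integer", rss = "numeric")
)

setValidity("MidlineFit", function(object) {
  if (object@nPoints < 2L) return("nPoints must be >= 2")
  if (object@rss < 0) return("rss must be >= 0")
  TRUE
})

#' AlignmentResult: rigid head alignment of one landmark set
#'
#' @slot rotationDeg applied rotation in degrees (|rotation| < 90).
#' @slot pivot rotation centre \code{c(cx, cy)} in pixels, the image centre.
#' @slot aligned the rotated [LandmarkSet-class].
#' @slot fit the [MidlineFit-class] that determined the rotation.
#' @export
setClass("AlignmentResult",
  slots = c(rotationDeg = "numeric", pivot = "numeric",
            aligned = "LandmarkSet", fit = "MidlineFit")
)

setValidity("AlignmentResult", function(object) {
  if (abs(object@rotationDeg) >= 90) return("|rotationDeg| must be < 90")
  if (length(object@pivot) != 2L) return("pivot must be length 2")
  TRUE
})

#' AngleVector: per-pair signed asymmetry angles for one aligned image
#'
#' The asymmetry feature vector a = (theta_1, ..., theta_N): the signed
#' angle, in degrees, of each pair's left-to-right connecting segment
#' relative to the horizontal after head alignment. Positive angles mean the
#' right-side point sits lower in the image (y points down); the sign
#' encodes direction, the magnitude local asymmetry.
#'
#' @slot datasetId,expressionId provenance of the image.
#' @slot registryName name of the [PairRegistry-class] that defined the pairs.
#' @slot theta numeric vector of signed angles in degrees, one per pair,
#'   each in (-180, 180].
#' @export
setClass("AngleVector",
  slots = c(datasetId = "character", expressionId = "integer",
            registryName = "character", theta = "numeric")
)

setValidity("AngleVector", function(object) {
  th <- object@theta
  if (any(!is.finite(th))) return("theta must be finite")
  if (any(th <= -180 | th > 180)) return("theta must lie in (-180, 180]")
  TRUE
})

#' SweepResult: eta-squared threshold sweep and chosen pair subset
#'
#' @slot trace data.frame with one row per threshold: \code{threshold},
#'   \code{n_pairs}, \code{H_rest}, \code{p_rest}, \code{H_move},
#'   \code{p_move}, \code{objective}.
#' @slot effects data.frame of per-pair effect sizes (\code{pair},
#'   \code{eta2_rest}, \code{eta2_move}).
#' @slot chosenSubset pair ordinals of the selected subset.
#' @slot chosenThreshold threshold at which the subset was selected.
#' @slot minEta2 minimum eta-squared (over both conditions) within the
#'   chosen subset.
#' @slot objective name of the combination rule ("sum" or "min").
#' @slot nonDiscriminative TRUE when even the chosen subset fails to
#'   separate grades (all Kruskal-Wallis p >= 0.05).
#' @export
setClass("SweepResult",
  slots = c(trace = "data.frame", effects = "data.frame",
            chosenSubset = "integer", chosenThreshold = "numeric",
            minEta2 = "numeric", objective = "character",
            nonDiscriminative = "logical")
)

#' RobustnessReport: score stability under artificial in-plane rotations
#'
#' @slot perRotation data.frame with columns \code{rotation_deg},
#'   \code{mean_abs_dev}, \code{median_abs_dev}, \code{n_images}.
#' @slot overallMean,overallSD mean and SD of the absolute score deviation
#'   pooled over all rotations and images, in degrees.
#' @slot mode "transform" (landmark coordinates rotated analytically) or
#'   "redetect" (landmarks re-detected on resampled images via an adapter).
#' @export
setClass("RobustnessReport",
  slots = c(perRotation = "data.frame", overallMean = "numeric",
            overallSD = "numeric", mode = "character")
)

setValidity("RobustnessReport", function(object) {
  pr <- object@perRotation
  if (any(pr$mean_abs_dev < 0, na.rm = TRUE))
    return("deviations must be >= 0")
  if (!setequal(pr$rotation_deg, -pr$rotation_deg))
    return("rotation grid must be symmetric about 0")
  TRUE
})
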