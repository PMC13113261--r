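#' Accessors for FaceSym data objects
#'
#' Slot access goes through these accessors; the slot layout is not part of
#' the public interface.
#'
#' @param x a FaceSym object.
#' @return The requested component.
#' @name accessors
#' @aliases datasetId expressionId landmarkCoords nLandmarks imageSize
#'   patientId sessionOrder expressions
#' @examples
#' lm <- landmarkSet("d1", 2, cbind(x = c(0, 4), y = c(1, 1)), 64, 64)
#' datasetId(lm); expressionId(lm); nLandmarks(lm)
NULL

#' @rdname accessors
setMethod("datasetId", "LandmarkSet", function(x) x@datasetId)

#' @rdname accessors
setMethod("datasetId", "DatasetRecord", function(x) x@datasetId)

#' @rdname accessors
setMethod("datasetId", "AngleVector", function(x) x@datasetId)

#' @rdname accessors
setMethod("expressionId", "LandmarkSet", function(x) x@expressionId)

#' @rdname accessors
setMethod("expressionId", "AngleVector", function(x) x@expressionId)

#' @rdname accessors
setMethod("landmarkCoords", "LandmarkSet", function(x) x@coords)

#' @rdname accessors
setMethod("nLandmarks", "LandmarkSet", function(x) nrow(x@coords))

#' @rdname accessors
setMethod("nLandmarks", "PairRegistry", function(x) x@nLandmarks)

#' @rdname accessors
setMethod("imageSize", "LandmarkSet",
          function(x) c(width = x@imageWidth, height = x@imageHeight))

#' @rdname accessors
setMethod("patientId", "DatasetRecord", function(x) x@patientId)

#' @rdname accessors
setMethod("sessionOrder", "DatasetRecord", function(x) x@sessionOrder)

#' @rdname accessors
setMethod("expressions", "DatasetRecord", function(x) x@expressions)

#' Registry accessors
#'
#' @param x a [PairRegistry-class].
#' @param subset subset selector: \code{"full"} for all pairs, the name of a
#'   stored subset (e.g. \code{"91"}), a region name (\code{"eye"},
#'   \code{"nose"}, \code{"mouth"}, resolved within the stored \code{"91"}
#'   subset when present, otherwise within the full registry), or an integer
#'   vector of pair ordinals.
#' @return \code{registrySubset} returns 1-based pair ordinals; the others
#'   return the corresponding slot.
#' @name registry-accessors
#' @aliases registryName registryPairs nPairs midlineIndices registrySubset
#' @examples
#' reg <- loadRegistry("sparse-29")
#' nPairs(reg)
#' length(registrySubset(reg, "21"))
NULL

#' @rdname registry-accessors
setMethod("registryName", "PairRegistry", function(x) x@name)

#' @rdname registry-accessors
setMethod("registryPairs", "PairRegistry", function(x) x@pairs)

#' @rdname registry-accessors
setMethod("nPairs", "PairRegistry", function(x) nrow(x@pairs))

#' @rdname registry-accessors
setMethod("midlineIndices", "PairRegistry", function(x) x@midlineIndices)

#' @rdname registry-accessors
setMethod("registrySubset", "PairRegistry", function(x, subset = "full") {
  if (is.numeric(subset)) {
    s <- as.integer(subset)
    if (length(s) == 0L)
      .fsStop("argument", "subset must be non-empty")
    if (anyDuplicated(s) || any(s < 1L) || any(s > nPairs(x)))
      .fsStop("argument", "pair ordinals out of range for registry '%s'",
              x@name)
    return(s)
  }
  if (identical(subset, "full")) return(seq_len(nPairs(x)))
  if (subset %in% names(x@subsets)) return(as.integer(x@subsets[[subset]]))
  if (subset %in% c("eye", "nose", "mouth", "other")) {
    base <- if ("91" %in% names(x@subsets))
      as.integer(x@subsets[["91"]]) else seq_len(nPairs(x))
    s <- base[x@pairs$region[base] == subset]
    if (length(s) == 0L)
      .fsStop("argument", "no '%s' pairs in registry '%s'", subset, x@name)
    return(s)
  }
  .fsStop("argument", "unknown subset '%s' for registry '%s'",
          subset, x@name)
})

#' @rdname angles
#' @name angles
#' @title Angle vector access
#' @param x an [AngleVector-class].
#' @return Numeric vector of signed pair angles in degrees.
setMethod("angleValues", "AngleVector", function(x) x@theta)

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf(
    "LandmarkSet: dataset '%s', expression %d, %d landmarks, %gx%g px\n",
    object@datasetId, object@expressionId, nrow(object@coords),
    object@imageWidth, object@imageHeight))
})

setMethod("show", "PairRegistry", function(object) {
  cat(sprintf("PairRegistry '%s': %d landmarks, %d pairs, %d midline points\n",
              object@name, object@nLandmarks, nrow(object@pairs),
              length(object@midlineIndices)))
  if (length(object@subsets))
    cat("  stored subsets:", paste(names(object@subsets), collapse = ", "),
        "\n")
})

setMethod("show", "DatasetRecord", function(object) {
  cat(sprintf("DatasetRecord: patient '%s', dataset '%s', session %d, %d expressions\n",
              object@patientId, object@datasetId, object@sessionOrder,
              length(object@expressions)))
})

setMethod("show", "MidlineFit", function(object) {
  cat(sprintf("MidlineFit: x = %.4f + %.6f * y  (n = %d, rss = %.4g px^2)\n",
              object@intercept, object@slope, object@nPoints, object@rss))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: rotation %.4f deg about (%.1f, %.1f)\n",
              object@rotationDeg, object@pivot[1], object@pivot[2]))
})

setMethod("show", "AngleVector", function(object) {
  cat(sprintf(
    "AngleVector: dataset '%s', expression %d, %d pairs (registry '%s')\n",
    object@datasetId, object@expressionId, length(object@theta),
    object@registryName))
  cat(sprintf("  mean |theta| = %.3f deg, max |theta| = %.3f deg\n",
              mean(abs(object@theta)), max(abs(object@theta))))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf(
    "SweepResult: %d thresholds, chosen subset of %d pairs at t = %.3f\n",
    nrow(object@trace), length(object@chosenSubset),
    object@chosenThreshold))
  cat(sprintf("  min eta^2 in chosen subset = %.3f, objective = %s%s\n",
              object@minEta2, object@objective,
              if (object@nonDiscriminative) " [non-discriminative]" else ""))
})

setMethod("show", "RobustnessReport", function(object) {
  cat(sprintf(
    "RobustnessReport (%s mode): %d rotations, overall |dev| %.4g +/- %.4g deg\n",
    object@mode, nrow(object@perRotation), object@overallMean,
    object@overallSD))
})
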