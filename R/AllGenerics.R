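#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname accessors
#' @export
setGeneric("expressionId", function(x) standardGeneric("expressionId"))

#' @rdname accessors
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))

#' @rdname accessors
#' @export
setGeneric("nLandmarks", function(x) standardGeneric("nLandmarks"))

#' @rdname accessors
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("sessionOrder", function(x) standardGeneric("sessionOrder"))

#' @rdname accessors
#' @export
setGeneric("expressions", function(x) standardGeneric("expressions"))

#' @rdname registry-accessors
#' @export
setGeneric("registryName", function(x) standardGeneric("registryName"))

#' @rdname registry-accessors
#' @export
setGeneric("registryPairs", function(x) standardGeneric("registryPairs"))

#' @rdname registry-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname registry-accessors
#' @export
setGeneric("midlineIndices", function(x) standardGeneric("midlineIndices"))

#' @rdname registry-accessors
#' @export
setGeneric("registrySubset",
           function(x, subset = "full") standardGeneric("registrySubset"))

#' @rdname angles
#' @export
setGeneric("angleValues", function(x) standardGeneric("angleValues"))

#' Align a landmark set so its facial midline becomes vertical
#'
#' @param set a [LandmarkSet-class].
#' @param midlineIdx 0-based indices of the midline landmarks.
#' @return An [AlignmentResult-class].
#' @seealso [fitMidline()]
#' @export
setGeneric("alignLandmarks",
           function(set, midlineIdx) standardGeneric("alignLandmarks"))

#' Signed pair-angle feature vector of an aligned landmark set
#'
#' @param set an aligned [LandmarkSet-class].
#' @param registry a [PairRegistry-class] or built-in registry name.
#' @return An [AngleVector-class].
#' @rdname pairAngles
#' @export
setGeneric("pairAngles",
           function(set, registry) standardGeneric("pairAngles"))
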