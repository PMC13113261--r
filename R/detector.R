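# Optional landmark-detector adapters. The core pipeline has zero hard
# dependency on any detection library: an adapter is a two-method contract
# (detect, version) supplied by the user at runtime, and every analysis can
# instead start from landmark files.

#' Define a landmark-detector adapter
#'
#' An adapter isolates an external landmark detection backend (e.g. a dense
#' face-mesh model) behind a minimal contract: \code{detect(imagePath)} must
#' return an n x 2 numeric matrix of pixel coordinates (or \code{NULL} when
#' no face is found), and \code{version()} a version string so runs are
#' reproducible for a fixed image and backend version.
#'
#' @param detect function(imagePath) -> n x 2 coordinate matrix or NULL.
#' @param version function() -> single version string.
#' @return An object of class \code{"FaceSymAdapter"}.
#' @export
detectorAdapter <- function(detect, version) {
  stopifnot(is.function(detect), is.function(version))
  structure(list(detect = detect, version = version),
            class = "FaceSymAdapter")
}

#' Detect landmarks on one image through an adapter
#'
#' @param imagePath path to a JPEG/PNG photograph.
#' @param adapter a [detectorAdapter()]; without one, a capability error
#'   directs the caller to file-based landmark input.
#' @param datasetId,expressionId provenance attached to the result.
#' @param imageWidth,imageHeight image dimensions in pixels.
#' @return A [LandmarkSet-class].
#' @export
detectLandmarks <- function(imagePath, adapter = NULL,
                            datasetId = "image", expressionId = 1L,
                            imageWidth = NA, imageHeight = NA) {
  if (is.null(adapter) || !inherits(adapter, "FaceSymAdapter"))
    .fsStop("capability",
            paste0("no detector adapter configured; supply landmarks as ",
                   "CSV/JSON files (readLandmarkFile) or register an ",
                   "adapter via detectorAdapter()"))
  xy <- adapter$detect(imagePath)
  if (is.null(xy))
    .fsStop("detection", "no face detected in image '%s'", imagePath)
  xy <- as.matrix(xy)
  landmarkSet(datasetId, expressionId, xy,
              imageWidth = if (is.na(imageWidth)) max(xy[, 1]) + 1
                           else imageWidth,
              imageHeight = if (is.na(imageHeight)) max(xy[, 2]) + 1
                            else imageHeight)
}
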