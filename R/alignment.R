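# Head alignment: fit the facial midline by OLS and rigidly rotate the
# landmark set about the image centre so the midline becomes vertical.

#' Fit the facial midline by ordinary least squares
#'
#' The midline is estimated from the central-axis landmarks as
#' \eqn{x = a + b y}. Regressing x on y keeps the fit well-posed for the
#' near-vertical midline of an upright face (head tilt up to ~25 degrees),
#' where the usual y-on-x orientation would be degenerate.
#'
#' @param set a [LandmarkSet-class].
#' @param midlineIdx 0-based indices of the midline landmarks (typically
#'   \code{midlineIndices(registry)}).
#' @return A [MidlineFit-class] with intercept \eqn{a} (pixels), slope
#'   \eqn{b} (dimensionless), point count and residual sum of squares.
#' @section Errors:
#' All midline y values identical (a horizontal midline) is degenerate
#' geometry for a face and raises an error.
#' @examples
#' lm <- landmarkSet("d", 1, cbind(x = c(5, 5, 5), y = c(0, 10, 20)), 32, 32)
#' fitMidline(lm, 0:2)  # a = 5, b = 0
#' @export
fitMidline <- function(set, midlineIdx) {
  xy <- landmarkCoords(set)
  idx <- as.integer(midlineIdx) + 1L
  if (any(idx < 1L) || any(idx > nrow(xy)))
    .fsStop("argument", "midline indices out of range")
  x <- xy[idx, "x"]
  y <- xy[idx, "y"]
  if (length(unique(y)) < 2L)
    .fsStop("degenerate",
            "all midline landmarks share one y value; midline cannot be near-vertical")
  # centred normal equations: exact (slope 0) for an exactly vertical
  # midline, where QR-based solvers leave ~1e-18 residue
  my <- mean(y); mx <- mean(x)
  b <- sum((y - my) * (x - mx)) / sum((y - my)^2)
  a <- mx - b * my
  new("MidlineFit",
      intercept = a, slope = b, nPoints = length(x),
      rss = sum((x - a - b * y)^2))
}

# Rigid rotation of coordinates by alphaDeg about pivot, raster convention
# (y down; positive alpha rotates the +x axis toward +y on screen).
.rotateCoords <- function(xy, alphaDeg, pivot) {
  a <- alphaDeg * pi / 180
  dx <- xy[, 1] - pivot[1]
  dy <- xy[, 2] - pivot[2]
  cbind(x = pivot[1] + dx * cos(a) - dy * sin(a),
        y = pivot[2] + dx * sin(a) + dy * cos(a))
}

.imageCenter <- function(set) {
  sz <- imageSize(set)
  c((sz[["width"]] - 1) / 2, (sz[["height"]] - 1) / 2)
}

#' @describeIn alignLandmarks Fit the midline on \code{midlineIdx}, then
#'   rotate every landmark by \eqn{\alpha = \arctan(b)} about the image
#'   centre \eqn{((w-1)/2, (h-1)/2)}, which maps the fitted midline
#'   direction \eqn{(b, 1)} onto the vertical. The transform is rigid:
#'   inter-landmark distances are preserved to floating-point precision,
#'   and re-fitting the midline on the output yields slope ~0. Rotating
#'   landmark coordinates (rather than resampling pixels) keeps the
#'   metrology path free of interpolation noise; overlay rendering uses the
#'   same transform.
#' @examples
#' lm <- landmarkSet("d", 1, cbind(x = c(0, 10, 20), y = c(0, 10, 20)),
#'                   21, 21)
#' res <- alignLandmarks(lm, 0:2)
#' res@rotationDeg  # 45: x = y midline rotated to vertical
#' @export
setMethod("alignLandmarks", "LandmarkSet", function(set, midlineIdx) {
  fit <- fitMidline(set, midlineIdx)
  alphaDeg <- atan(fit@slope) * 180 / pi
  pivot <- .imageCenter(set)
  xy <- .rotateCoords(landmarkCoords(set), alphaDeg, pivot)
  aligned <- landmarkSet(datasetId(set), expressionId(set), xy,
                         imageSize(set)[["width"]],
                         imageSize(set)[["height"]])
  new("AlignmentResult", rotationDeg = alphaDeg, pivot = pivot,
      aligned = aligned, fit = fit)
})
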