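# Angle maps: each pair's left-right connecting segment, colour-coded by
# |theta| from blue (0 deg) to red (>= clip, default 5 deg). Rendered as
# hand-assembled SVG markup so output bytes are fully deterministic and the
# blank-background variant is privacy-preserving by construction (it never
# touches pixel data).

#' Angle-map rendering style
#'
#' @param clipDeg angle at which the colour ramp saturates to red
#'   (default 5; every |theta| >= clipDeg takes the identical red).
#' @param lineWidth segment stroke width in pixels.
#' @param background "blank" (white canvas, privacy-preserving) or "photo"
#'   (embed the photograph given in \code{photo} under the segments).
#' @param photo optional image path for background = "photo".
#' @param annotate logical: print the subset score on the map.
#' @param canvas optional c(width, height) override in pixels (default: the
#'   landmark set's image size).
#' @param lowColor,highColor ramp endpoints; the default linear-RGB
#'   blue-to-red ramp is monotone in |theta|.
#' @return A list of class \code{"FaceSymMapStyle"}.
#' @export
mapStyle <- function(clipDeg = 5, lineWidth = 2,
                     background = c("blank", "photo"), photo = NULL,
                     annotate = TRUE, canvas = NULL,
                     lowColor = "#0000FF", highColor = "#FF0000") {
  background <- match.arg(background)
  if (clipDeg <= 0) .fsStop("argument", "clipDeg must be > 0")
  if (background == "photo" && is.null(photo))
    .fsStop("argument", "background = \"photo\" needs a photo path")
  structure(list(clipDeg = clipDeg, lineWidth = lineWidth,
                 background = background, photo = photo,
                 annotate = annotate, canvas = canvas,
                 lowColor = lowColor, highColor = highColor),
            class = "FaceSymMapStyle")
}

#' Map |theta| to the blue-to-red angle-map colour
#'
#' Linear interpolation in RGB between the ramp endpoints, clipped at
#' \code{clipDeg}: 0 degrees maps to pure blue, |theta| >= clipDeg to pure
#' red, and the mapping is monotone in |theta| in between.
#'
#' @param theta signed angles in degrees.
#' @param clipDeg saturation angle (default 5).
#' @param lowColor,highColor ramp endpoints.
#' @return Character vector of "#RRGGBB" colours.
#' @examples
#' angleColor(c(0, 2.5, 5, 50))
#' @export
angleColor <- function(theta, clipDeg = 5,
                       lowColor = "#0000FF", highColor = "#FF0000") {
  t <- pmin(abs(theta), clipDeg) / clipDeg
  lo <- grDevices::col2rgb(lowColor)[, 1]
  hi <- grDevices::col2rgb(highColor)[, 1]
  rgb <- round(outer(lo, 1 - t) + outer(hi, t))
  sprintf("#%02X%02X%02X", rgb[1, ], rgb[2, ], rgb[3, ])
}

.svgOpen <- function(w, h) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="0 0 %g %g">',
            w, h, w, h))
}

.fmtCoord <- function(x) sprintf("%.3f", x)

# SVG fragment for one map, optionally offset into a grid cell.
.mapFragment <- function(set, theta, subset, style, offset = c(0, 0),
                         scale = 1) {
  xy <- landmarkCoords(set)
  sz <- imageSize(set)
  w <- sz[["width"]]; h <- sz[["height"]]
  p <- attr(theta, "pairs")
  cols <- angleColor(theta[subset], style$clipDeg, style$lowColor,
                     style$highColor)
  xl <- xy[p$left[subset] + 1L, "x"]; yl <- xy[p$left[subset] + 1L, "y"]
  xr <- xy[p$right[subset] + 1L, "x"]; yr <- xy[p$right[subset] + 1L, "y"]
  outside <- xl < 0 | xl > w - 1 | xr < 0 | xr > w - 1 |
    yl < 0 | yl > h - 1 | yr < 0 | yr > h - 1
  if (any(outside))
    .fsWarn("render", "%d segment(s) extend outside the canvas; clipped",
            sum(outside))
  frag <- sprintf('<g transform="translate(%s,%s) scale(%s)">',
                  .fmtCoord(offset[1]), .fmtCoord(offset[2]),
                  .fmtCoord(scale))
  if (style$background == "blank") {
    frag <- c(frag, sprintf('<rect x="0" y="0" width="%g" height="%g" fill="#FFFFFF"/>',
                            w, h))
  } else {
    frag <- c(frag, sprintf('<image href="%s" x="0" y="0" width="%g" height="%g"/>',
                            style$photo, w, h))
  }
  frag <- c(frag, sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%g" stroke-linecap="round"/>',
    .fmtCoord(xl), .fmtCoord(yl), .fmtCoord(xr), .fmtCoord(yr), cols,
    style$lineWidth))
  c(frag, "</g>")
}

#' Render an angle map for one aligned image
#'
#' Draws one line segment per subset pair from the left to the right
#' landmark, coloured by the clipped |theta| ramp of [angleColor()]. With
#' \code{background = "blank"} the map contains no photographic content.
#' Output bytes are deterministic for fixed inputs and style.
#'
#' @param set the aligned [LandmarkSet-class].
#' @param angles the matching [AngleVector-class].
#' @param registry the defining [PairRegistry-class] or built-in name.
#' @param subset subset selector (see [registrySubset()]).
#' @param style a [mapStyle()].
#' @param file output SVG path; when NULL the SVG text is returned.
#' @return Invisibly, the SVG text (character vector of lines).
#' @export
renderAngleMap <- function(set, angles, registry, subset = "full",
                           style = mapStyle(), file = NULL) {
  registry <- loadRegistry(registry)
  sidx <- registrySubset(registry, subset)
  theta <- angleValues(angles)
  attr(theta, "pairs") <- registryPairs(registry)
  sz <- imageSize(set)
  svg <- c(.svgOpen(sz[["width"]], sz[["height"]]),
           .mapFragment(set, theta, sidx, style))
  if (style$annotate) {
    sc <- mean(abs(theta[sidx]))
    svg <- c(svg, sprintf(
      '<text x="4" y="14" font-family="sans-serif" font-size="12" fill="#000000">Score = %.2f&#176;</text>',
      sc))
  }
  svg <- c(svg, "</svg>")
  if (!is.null(file)) writeLines(svg, file)
  invisible(svg)
}

#' Render a sessions-by-expressions grid of angle maps
#'
#' Composes one angle map per (row, expression) cell: rows are sessions in
#' chronological order (longitudinal view) or cohort percentile picks;
#' columns are the nine standardized expressions. Each row is annotated
#' with its overall subset score (mean over the nine expressions). Missing
#' cells render as labelled empty slots.
#'
#' @param records list of [DatasetRecord-class], one per grid row.
#' @param registry registry or built-in name.
#' @param subset subset selector.
#' @param style a [mapStyle()].
#' @param rowLabels optional row annotation prefixes (default dataset ids).
#' @param cellSize rendered cell width in pixels (height follows the image
#'   aspect ratio).
#' @param file output SVG path; NULL returns text only.
#' @return Invisibly, the SVG text.
#' @export
renderAngleGrid <- function(records, registry, subset = "full",
                            style = mapStyle(annotate = FALSE),
                            rowLabels = NULL, cellSize = 160,
                            file = NULL) {
  registry <- loadRegistry(registry)
  sidx <- registrySubset(registry, subset)
  p <- registryPairs(registry)
  mid <- midlineIndices(registry)
  nr <- length(records)
  if (nr == 0L) .fsStop("argument", "no records to render")
  if (is.null(rowLabels))
    rowLabels <- vapply(records, datasetId, character(1))
  header <- 18
  sz0 <- imageSize(expressions(records[[1]])[["1"]])
  aspect <- sz0[["height"]] / sz0[["width"]]
  cw <- cellSize; ch <- cellSize * aspect
  W <- 9 * cw; H <- nr * (ch + header)
  svg <- .svgOpen(W, H)
  for (ri in seq_len(nr)) {
    rec <- records[[ri]]
    y0 <- (ri - 1) * (ch + header)
    rowScores <- numeric(0)
    for (e in 1:9) {
      lm <- expressions(rec)[[as.character(e)]]
      x0 <- (e - 1) * cw
      if (is.null(lm)) {
        svg <- c(svg, sprintf(
          '<text x="%s" y="%s" font-family="sans-serif" font-size="10" fill="#888888">missing %d</text>',
          .fmtCoord(x0 + 4), .fmtCoord(y0 + header + 12), e))
        next
      }
      al <- alignLandmarks(lm, mid)
      av <- pairAngles(al@aligned, registry)
      theta <- angleValues(av)
      rowScores <- c(rowScores, mean(abs(theta[sidx])))
      attr(theta, "pairs") <- p
      scale <- cw / imageSize(lm)[["width"]]
      svg <- c(svg, .mapFragment(al@aligned, theta, sidx, style,
                                 offset = c(x0, y0 + header),
                                 scale = scale))
    }
    svg <- c(svg, sprintf(
      '<text x="4" y="%s" font-family="sans-serif" font-size="12" fill="#000000">%s: Score = %.2f&#176;</text>',
      .fmtCoord(y0 + 13), rowLabels[ri], mean(rowScores)))
  }
  svg <- c(svg, "</svg>")
  if (!is.null(file)) writeLines(svg, file)
  invisible(svg)
}

#' Pick cohort percentile datasets by overall score
#'
#' Selects the datasets whose overall ("all") score sits at the requested
#' quantiles of the cohort (default: maximum, 75th percentile, median, 25th
#' percentile, minimum) - the rows of the cohort percentile grid.
#'
#' @param scores long score table ([analyzeCohort()]\code{$scores}) for a
#'   single subset.
#' @param probs quantile probabilities, high to low.
#' @return data.frame: label, dataset_id, score (the dataset whose overall
#'   score is nearest each quantile; ties to the first in dataset order).
#' @export
percentileDatasets <- function(scores,
                               probs = c(1, 0.75, 0.5, 0.25, 0)) {
  scores <- as.data.frame(scores)
  overall <- tapply(scores$score_deg, scores$dataset_id, mean)
  q <- stats::quantile(as.numeric(overall), probs = probs, names = FALSE,
                       type = 7)
  lab <- sprintf("p%g", probs * 100)
  lab[probs == 1] <- "max"; lab[probs == 0] <- "min"
  lab[probs == 0.5] <- "median"
  idx <- vapply(q, function(x) which.min(abs(as.numeric(overall) - x)),
                integer(1))
  data.frame(label = lab, dataset_id = names(overall)[idx],
             score = as.numeric(overall)[idx])
}

#' Plot an angle map on the active graphics device
#'
#' Base-graphics companion to [renderAngleMap()] for interactive use.
#'
#' @inheritParams renderAngleMap
#' @return Invisibly, NULL.
#' @export
plotAngleMap <- function(set, angles, registry, subset = "full",
                         style = mapStyle()) {
  registry <- loadRegistry(registry)
  sidx <- registrySubset(registry, subset)
  p <- registryPairs(registry)
  xy <- landmarkCoords(set)
  sz <- imageSize(set)
  theta <- angleValues(angles)
  cols <- angleColor(theta[sidx], style$clipDeg, style$lowColor,
                     style$highColor)
  graphics::plot(NA, xlim = c(0, sz[["width"]]),
                 ylim = c(sz[["height"]], 0), asp = 1, xlab = "x [px]",
                 ylab = "y [px]",
                 main = sprintf("Score = %.2f deg", mean(abs(theta[sidx]))))
  graphics::segments(xy[p$left[sidx] + 1L, "x"], xy[p$left[sidx] + 1L, "y"],
                     xy[p$right[sidx] + 1L, "x"],
                     xy[p$right[sidx] + 1L, "y"],
                     col = cols, lwd = style$lineWidth)
  invisible(NULL)
}
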