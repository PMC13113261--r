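# Long-format landmark serialization: one row per landmark. The long format
# is landmark-model-agnostic (478-point dense mesh and 68-point layouts use
# the same schema). Coordinates are written with %.17g so the writer->reader
# round trip is bit-exact.

.landmarkCols <- c("patient_id", "dataset_id", "session_order",
                   "expression_id", "landmark_index", "x", "y",
                   "image_width", "image_height")

# %.17g round-trips IEEE doubles exactly (whole numbers print without a
# fractional part, so files stay compact).
.fmtNum <- function(x) sprintf("%.17g", x)

#' Read per-image landmark sets grouped into dataset records
#'
#' Reads a long-format landmark table (CSV or JSON; one row per landmark)
#' and assembles validated [DatasetRecord-class] objects. A dataset must
#' carry the complete nine-expression battery: datasets missing any
#' expression are excluded with a logged exclusion rather than an error,
#' mirroring the acquisition protocol's inclusion rule.
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"json"}; guessed from the file
#'   extension by default.
#' @return List of [DatasetRecord-class], ordered by dataset id.
#' @section Errors:
#' Missing columns raise a format error; duplicated
#' (dataset, expression, landmark_index) rows or index gaps raise an
#' integrity error naming the offending dataset/expression.
#' @seealso [writeLandmarkFile()]
#' @export
readLandmarkFile <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (!file.exists(path))
    .fsStop("format", "landmark file not found: %s", path)
  tab <- if (format == "csv") {
    as.data.frame(data.table::fread(path, colClasses = list(
      character = c("patient_id", "dataset_id"))))
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  miss <- setdiff(.landmarkCols, names(tab))
  if (length(miss))
    .fsStop("format", "landmark file missing columns: %s",
            paste(miss, collapse = ", "))
  tab$dataset_id <- as.character(tab$dataset_id)
  tab$patient_id <- as.character(tab$patient_id)
  .assembleRecords(tab)
}

.assembleRecords <- function(tab) {
  records <- list()
  excluded <- character()
  for (did in unique(tab$dataset_id)) {
    sub <- tab[tab$dataset_id == did, , drop = FALSE]
    exprs <- sort(unique(sub$expression_id))
    if (!identical(as.integer(exprs), 1:9)) {
      excluded <- c(excluded, did)
      next
    }
    sets <- list()
    for (e in 1:9) {
      im <- sub[sub$expression_id == e, , drop = FALSE]
      idx <- im$landmark_index
      if (anyDuplicated(idx))
        .fsStop("integrity",
                "duplicated landmark index in dataset '%s', expression %d: %s",
                did, e,
                paste(unique(idx[duplicated(idx)]), collapse = ", "))
      if (!identical(sort(as.integer(idx)), 0:(nrow(im) - 1L)))
        .fsStop("integrity",
                "landmark indices of dataset '%s', expression %d do not cover 0..%d",
                did, e, nrow(im) - 1L)
      ord <- order(idx)
      sets[[as.character(e)]] <- landmarkSet(
        did, e, cbind(x = im$x[ord], y = im$y[ord]),
        im$image_width[1], im$image_height[1])
    }
    records[[did]] <- new("DatasetRecord",
                          patientId = sub$patient_id[1],
                          datasetId = did,
                          sessionOrder = as.integer(sub$session_order[1]),
                          expressions = sets)
  }
  if (length(excluded))
    .fsLog("read", "excluded %d dataset(s) with incomplete expression battery: %s",
           length(excluded), paste(excluded, collapse = ", "),
           level = "WARN")
  if (!length(records)) return(list())
  records[order(names(records))]
}

#' Write dataset records as a long-format landmark file
#'
#' @param records list of [DatasetRecord-class].
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeLandmarkFile <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(expressions(rec), function(lm) {
      xy <- landmarkCoords(lm)
      data.frame(patient_id = patientId(rec),
                 dataset_id = datasetId(rec),
                 session_order = sessionOrder(rec),
                 expression_id = expressionId(lm),
                 landmark_index = seq_len(nrow(xy)) - 1L,
                 x = xy[, "x"], y = xy[, "y"],
                 image_width = imageSize(lm)[["width"]],
                 image_height = imageSize(lm)[["height"]])
    }))
  })
  tab <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    as.data.frame(setNames(rep(list(numeric(0)), length(.landmarkCols)),
                           .landmarkCols))
  if (format == "csv") {
    out <- tab
    if (nrow(out)) {
      out$x <- .fmtNum(out$x)
      out$y <- .fmtNum(out$y)
    }
    data.table::fwrite(out, path, quote = FALSE)
  } else {
    jsonlite::write_json(tab, path, digits = NA)
  }
  invisible(path)
}

#' Read / write the clinical grade table
#'
#' Grades follow the Stennert index: symmetry at rest on an ordinal 0-4
#' scale (0 = no asymmetry, 4 = severe asymmetry) and function during
#' voluntary movement on 0-6 (0 = normal, 6 = complete or near-complete
#' impairment). One record per dataset.
#'
#' @param path CSV path with columns \code{dataset_id}, \code{patient_id},
#'   \code{stennert_rest}, \code{stennert_move}.
#' @return \code{readGradeFile}: a validated data.frame;
#'   \code{writeGradeFile}: \code{path}, invisibly.
#' @export
readGradeFile <- function(path) {
  tab <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("dataset_id", "patient_id"))))
  miss <- setdiff(c("dataset_id", "patient_id", "stennert_rest",
                    "stennert_move"), names(tab))
  if (length(miss))
    .fsStop("format", "grade file missing columns: %s",
            paste(miss, collapse = ", "))
  validateGrades(tab)
}

#' @rdname readGradeFile
#' @param grades grade data.frame.
#' @export
writeGradeFile <- function(grades, path) {
  data.table::fwrite(validateGrades(grades), path, quote = FALSE)
  invisible(path)
}

#' @rdname readGradeFile
#' @export
validateGrades <- function(grades) {
  grades <- as.data.frame(grades)
  if (anyDuplicated(grades$dataset_id))
    .fsStop("integrity", "duplicated dataset_id in grade table")
  if (nrow(grades) &&
      (any(!grades$stennert_rest %in% 0:4) ||
       any(!grades$stennert_move %in% 0:6)))
    .fsStop("integrity",
            "Stennert grades out of range (rest 0-4, movement 0-6)")
  grades
}
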