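# Effect-size-driven landmark-pair selection against ordinal clinical
# grades: per-pair one-way-ANOVA eta-squared under both Stennert conditions,
# a systematic threshold sweep (0.001-0.400, step 0.001), Kruskal-Wallis
# separation of the resulting subset scores, and Spearman correlation
# reporting.

#' Per-unit mean absolute pair deviations
#'
#' Averages |theta| per landmark pair over all images of an analysis unit.
#' With \code{unit = "session"} the unit is one dataset (mean over its nine
#' expressions); with \code{unit = "patient"} all images of all the
#' patient's sessions are pooled, which requires the patient's grades to be
#' constant across sessions (grades can change during therapy; conflicting
#' grades raise an aggregation error directing \code{unit = "session"}).
#' Datasets without a grade record are excluded with a logged count and do
#' not contribute.
#'
#' @param angles long angle table (\code{dataset_id}, \code{expression_id},
#'   \code{pair_ordinal}, \code{theta_deg}) as produced by
#'   [analyzeCohort()]\code{$angles}.
#' @param grades grade data.frame (see [readGradeFile()]).
#' @param unit \code{"session"} (default) or \code{"patient"}.
#' @return List: \code{dev} (units x pairs matrix of mean |theta|),
#'   \code{units} (data.frame unit, stennert_rest, stennert_move).
#' @export
unitDeviations <- function(angles, grades, unit = c("session", "patient")) {
  unit <- match.arg(unit)
  angles <- as.data.frame(angles)
  grades <- validateGrades(grades)
  have <- unique(angles$dataset_id)
  graded <- intersect(have, grades$dataset_id)
  dropped <- length(have) - length(graded)
  if (dropped > 0)
    .fsLog("selection", "%d of %d dataset(s) lack grades; excluded, %d retained",
           dropped, length(have), length(graded))
  if (length(graded) == 0L)
    .fsStop("aggregation", "no graded datasets available")
  angles <- angles[angles$dataset_id %in% graded, , drop = FALSE]
  g <- grades[match(graded, grades$dataset_id), , drop = FALSE]

  keyUnit <- if (unit == "session") angles$dataset_id else
    g$patient_id[match(angles$dataset_id, g$dataset_id)]
  npair <- max(angles$pair_ordinal)
  dev <- tapply(abs(angles$theta_deg),
                list(factor(keyUnit), factor(angles$pair_ordinal,
                                             levels = seq_len(npair))),
                mean)
  dev <- matrix(as.numeric(dev), nrow = nrow(dev),
                dimnames = dimnames(dev))

  if (unit == "session") {
    units <- data.frame(unit = rownames(dev))
    m <- match(units$unit, g$dataset_id)
  } else {
    perPat <- split(g[, c("stennert_rest", "stennert_move")], g$patient_id)
    bad <- names(perPat)[vapply(perPat, function(d)
      length(unique(d$stennert_rest)) > 1 ||
      length(unique(d$stennert_move)) > 1, logical(1))]
    if (length(bad))
      .fsStop("aggregation",
              "patient(s) with conflicting grades across sessions (%s); use unit = \"session\"",
              paste(bad, collapse = ", "))
    units <- data.frame(unit = rownames(dev))
    m <- match(units$unit, g$patient_id)
  }
  units$stennert_rest <- g$stennert_rest[m]
  units$stennert_move <- g$stennert_move[m]
  list(dev = dev, units = units)
}

#' Eta-squared effect size from one-way ANOVA
#'
#' \eqn{\eta^2 = SS_{between} / SS_{total}}: the proportion of variance in
#' \code{values} explained by group membership. Returns 0 when
#' \eqn{SS_{total} = 0} (no variance to explain).
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @return Single numeric in [0, 1].
#' @examples
#' etaSquared(c(1, 2, 3, 4), c("a", "a", "b", "b"))  # 0.8
#' @export
etaSquared <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    .fsStop("degenerate", "eta-squared undefined for a single group")
  if (length(values) != length(groups) || length(values) < 3L)
    .fsStop("argument", "need >= 3 paired values/groups")
  grand <- mean(values)
  ssTot <- sum((values - grand)^2)
  if (ssTot == 0) return(0)
  gm <- tapply(values, groups, mean)
  gn <- tabulate(groups)
  ssB <- sum(gn * (gm - grand)^2)
  ssB / ssTot
}

#' Per-pair effect sizes across Stennert grades
#'
#' @param dev units x pairs deviation matrix from [unitDeviations()].
#' @param units matching unit table with \code{stennert_rest},
#'   \code{stennert_move}.
#' @return data.frame: pair, eta2_rest, eta2_move.
#' @export
pairEffects <- function(dev, units) {
  singleObs <- any(tabulate(factor(units$stennert_rest)) == 1L) ||
    any(tabulate(factor(units$stennert_move)) == 1L)
  if (singleObs)
    .fsLog("selection",
           "some grade levels have a single unit; eta-squared still defined",
           level = "WARN")
  data.frame(
    pair = seq_len(ncol(dev)),
    eta2_rest = apply(dev, 2, etaSquared, groups = units$stennert_rest),
    eta2_move = apply(dev, 2, etaSquared, groups = units$stennert_move))
}

#' Kruskal-Wallis H test across grade groups
#'
#' Tie-corrected H with a chi-square p-value on k - 1 degrees of freedom
#' (via \code{stats::kruskal.test}). All-identical values are the degenerate
#' no-information case and return H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return List: statistic, p_value, n, df, ties (logical).
#' @export
kruskalWallisH <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L)
    .fsStop("degenerate", "Kruskal-Wallis needs >= 2 groups")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1, n = length(values),
                df = nlevels(groups) - 1L, ties = TRUE))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(values), df = unname(kt$parameter),
       ties = anyDuplicated(values) > 0L)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho on average ranks (ties allowed), two-sided p via the asymptotic t
#' approximation (\code{stats::cor.test(..., exact = FALSE)}).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List: statistic (rho), p_value, n.
#' @section Errors:
#' Zero variance in either vector leaves the correlation undefined and
#' raises a degenerate-statistics error.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    .fsStop("argument", "need equal-length vectors of length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    .fsStop("degenerate", "undefined correlation: zero variance input")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(statistic = unname(ct$estimate), p_value = ct$p.value,
       n = length(x))
}

#' Sweep eta-squared thresholds and select the optimal pair subset
#'
#' For each threshold t in \code{thresholds}, the candidate subset is
#' S(t) = pairs with eta2 strictly greater than t in \emph{both} the rest
#' and the movement condition (so subset size is non-increasing in t and
#' S(t2) is nested in S(t1) for t2 > t1). Each distinct non-empty subset is
#' scored per unit (mean |theta| over its pairs) and tested by
#' Kruskal-Wallis across rest grades and across movement grades. The chosen
#' subset maximizes the combined objective (default \code{"sum"}:
#' H_rest + H_move; \code{"min"}: min(H_rest, H_move)); ties break toward
#' smaller subsets.
#'
#' @param effects per-pair effect table from [pairEffects()].
#' @param dev,units deviation matrix and unit table from
#'   [unitDeviations()].
#' @param objective \code{"sum"} (default) or \code{"min"}.
#' @param thresholds threshold grid (default 0.001..0.400 step 0.001).
#' @return A [SweepResult-class]. The chosen subset is flagged
#'   non-discriminative when its Kruskal-Wallis p-values are all >= 0.05.
#' @section Errors:
#' If no threshold yields a non-empty subset, a selection error is raised.
#' @export
thresholdSweep <- function(effects, dev, units,
                           objective = c("sum", "min"),
                           thresholds = seq(0.001, 0.400, by = 0.001)) {
  objective <- match.arg(objective)
  thresholds <- round(thresholds, 6)
  subs <- lapply(thresholds, function(t)
    which(effects$eta2_rest > t & effects$eta2_move > t))
  sizes <- lengths(subs)
  if (all(sizes == 0L))
    .fsStop("selection", "no threshold yields a non-empty pair subset")

  key <- vapply(subs, paste, character(1), collapse = ",")
  cache <- list()
  evalSubset <- function(s) {
    sc <- rowMeans(dev[, s, drop = FALSE])
    kr <- kruskalWallisH(sc, units$stennert_rest)
    km <- kruskalWallisH(sc, units$stennert_move)
    c(H_rest = kr$statistic, p_rest = kr$p_value,
      H_move = km$statistic, p_move = km$p_value)
  }
  trace <- data.frame(threshold = thresholds, n_pairs = sizes,
                      H_rest = NA_real_, p_rest = NA_real_,
                      H_move = NA_real_, p_move = NA_real_)
  for (i in seq_along(thresholds)) {
    if (sizes[i] == 0L) next
    k <- key[i]
    if (is.null(cache[[k]])) cache[[k]] <- evalSubset(subs[[i]])
    trace[i, c("H_rest", "p_rest", "H_move", "p_move")] <- cache[[k]]
  }
  trace$objective <- if (objective == "sum") trace$H_rest + trace$H_move
                     else pmin(trace$H_rest, trace$H_move)

  ok <- which(!is.na(trace$objective))
  best <- ok[order(-trace$objective[ok], trace$n_pairs[ok],
                   trace$threshold[ok])][1]
  chosen <- subs[[best]]
  minEta2 <- min(c(effects$eta2_rest[chosen], effects$eta2_move[chosen]))
  nonDisc <- trace$p_rest[best] >= 0.05 && trace$p_move[best] >= 0.05
  if (nonDisc)
    .fsLog("selection",
           "chosen subset is non-discriminative (all p >= 0.05)",
           level = "WARN")
  new("SweepResult", trace = trace, effects = effects,
      chosenSubset = as.integer(chosen),
      chosenThreshold = thresholds[best], minEta2 = minEta2,
      objective = objective, nonDiscriminative = nonDisc)
}

#' Spearman correlation report between scores and clinical grades
#'
#' For each pair subset, Stennert condition (rest, movement) and expression
#' (1-9 plus the per-dataset overall "all"), reports Spearman's rho and its
#' p-value between the asymmetry score and the clinical grade over graded
#' datasets. Cells with degenerate input (e.g. constant scores) are
#' reported as NA with a warning rather than failing the report.
#'
#' @param scores long score table ([analyzeCohort()]\code{$scores}).
#' @param grades grade data.frame.
#' @param subsets subset names to report (default: those present in
#'   \code{scores}).
#' @return data.frame: subset_name, condition, expression, rho, p_value, n.
#' @export
correlationReport <- function(scores, grades, subsets = NULL) {
  scores <- as.data.frame(scores)
  grades <- validateGrades(grades)
  if (is.null(subsets)) subsets <- unique(scores$subset_name)
  scores <- scores[scores$dataset_id %in% grades$dataset_id &
                     scores$subset_name %in% subsets, , drop = FALSE]
  out <- list()
  for (sn in subsets) {
    sub <- scores[scores$subset_name == sn, , drop = FALSE]
    perAll <- tapply(sub$score_deg, sub$dataset_id, mean)
    cells <- c(as.list(1:9), list("all"))
    for (cond in c("rest", "move")) {
      gcol <- paste0("stennert_", cond)
      for (e in cells) {
        if (identical(e, "all")) {
          ids <- names(perAll); v <- as.numeric(perAll)
        } else {
          sel <- sub$expression_id == e
          ids <- sub$dataset_id[sel]; v <- sub$score_deg[sel]
        }
        gr <- grades[[gcol]][match(ids, grades$dataset_id)]
        res <- tryCatch(spearmanRho(v, gr), FaceSym_degenerate_error =
          function(err) {
            .fsWarn("report", "undefined correlation for subset %s/%s/expr %s",
                    sn, cond, as.character(e))
            list(statistic = NA_real_, p_value = NA_real_, n = length(v))
          })
        out[[length(out) + 1L]] <- data.frame(
          subset_name = sn, condition = cond,
          expression = as.character(e), rho = res$statistic,
          p_value = res$p_value, n = res$n)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
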