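# Synthetic cohort generator: a bilaterally symmetric schematic face
# template plus grade-dependent, region-localized vertical droop of the
# affected side, patient-level severity spread, landmark noise and random
# in-plane head tilt. Gives every pipeline stage a download-free,
# statistically controlled test bed with a known ground truth.

#' Synthetic cohort configuration
#'
#' Defaults describe a realistic outpatient cohort: 60 patients, one
#' session each, the 478-point dense registry, a droop of 0.8 degrees of
#' pair angle per Stennert movement grade concentrated in the registry's
#' stored 91-pair subset, 1 px isotropic landmark noise (typical detector
#' jitter at portrait resolutions) and head tilt uniform in +/-10 degrees.
#' Movement-dependent asymmetry is modelled by a region x expression gain:
#' eye pairs are amplified during the eye/brow expressions (2-4), nose
#' pairs during nose wrinkling (5), mouth pairs during the mouth
#' expressions (6, 7, 9), and the neutral expression (1) is damped.
#'
#' @param nPatients number of patients.
#' @param sessionsPerPatient sessions (datasets) per patient.
#' @param registry registry or built-in name the cohort targets.
#' @param droopPerGrade expected |theta| in degrees per unit movement grade
#'   for informative pairs (>= 0).
#' @param informativePairs pair ordinals carrying grade-dependent droop;
#'   default: the registry's stored "91" subset (else all pairs).
#' @param expressionGain 9 x 4 matrix (rows = expressions, columns = eye,
#'   nose, mouth, other) of droop multipliers, or a length-9 vector applied
#'   to all regions.
#' @param landmarkNoiseSd isotropic landmark noise SD in pixels (>= 0).
#' @param severitySpread half-width (in grade units, < 0.5) of the uniform
#'   latent-severity deviation around the movement grade: the droop of
#'   patient p is driven by a continuous latent severity
#'   \code{x_p = max(0, move_p + U(-severitySpread, severitySpread))},
#'   so patients sharing a clinical grade differ in impairment, as ordinal
#'   grading coarsens a continuous quantity, while distinct grades occupy
#'   disjoint severity bands. Part of the generator's noise model; 0
#'   disables it (then \code{x_p = move_p} exactly).
#' @param baselineAsymDeg SD (degrees) of a patient's shared baseline
#'   asymmetry: a persistent signed angle offset c_p ~ N(0, sd) applied
#'   identically to every pair, constant across sessions and expressions.
#'   It models global craniofacial/postural asymmetry, a person-level trait
#'   independent of palsy grade; healthy faces are not perfectly
#'   symmetric. 0 disables it.
#' @param localAsymDeg SD (degrees) of per-pair local baseline asymmetry:
#'   persistent, independent offsets per (patient, pair) on top of the
#'   shared component, modelling idiosyncratic local feature asymmetry.
#'   0 disables it.
#' @param headTiltRange head tilt range in degrees: scalar r for
#'   uniform(-r, r) or c(lo, hi); must lie within [-25, 25]. A fixed tilt
#'   is c(t, t).
#' @param imageSizePx canvas side length in pixels.
#' @param seed RNG seed; a fixed seed makes the cohort fully reproducible.
#' @return Validated config list of class \code{"FaceSymSynthConfig"}.
#' @export
syntheticConfig <- function(nPatients = 60, sessionsPerPatient = 2,
                            registry = "dense-225", droopPerGrade = 0.8,
                            informativePairs = NULL,
                            expressionGain = NULL, landmarkNoiseSd = 1,
                            severitySpread = 0.3, baselineAsymDeg = 0.05,
                            localAsymDeg = 0.1, headTiltRange = 10,
                            imageSizePx = 512, seed = 1) {
  reg <- loadRegistry(registry)
  if (is.null(informativePairs))
    informativePairs <- if ("91" %in% names(reg@subsets))
      registrySubset(reg, "91") else seq_len(nPairs(reg))
  informativePairs <- registrySubset(reg, informativePairs)
  if (is.null(expressionGain)) {
    expressionGain <- matrix(1, 9, 4,
                             dimnames = list(NULL, c("eye", "nose",
                                                     "mouth", "other")))
    expressionGain[1, ] <- 0.5
    expressionGain[2:4, "eye"] <- 1.5
    expressionGain[5, "nose"] <- 1.5
    expressionGain[c(6, 7, 9), "mouth"] <- 1.5
  } else if (is.null(dim(expressionGain))) {
    expressionGain <- matrix(rep(as.numeric(expressionGain), 4), 9, 4,
                             dimnames = list(NULL, c("eye", "nose",
                                                     "mouth", "other")))
  }
  if (length(headTiltRange) == 1L)
    headTiltRange <- c(-abs(headTiltRange), abs(headTiltRange))
  bad <- character()
  if (droopPerGrade < 0) bad <- c(bad, "droopPerGrade must be >= 0")
  if (landmarkNoiseSd < 0) bad <- c(bad, "landmarkNoiseSd must be >= 0")
  if (severitySpread < 0 || severitySpread >= 0.5)
    bad <- c(bad, "severitySpread must be in [0, 0.5)")
  if (baselineAsymDeg < 0) bad <- c(bad, "baselineAsymDeg must be >= 0")
  if (localAsymDeg < 0) bad <- c(bad, "localAsymDeg must be >= 0")
  if (headTiltRange[1] > headTiltRange[2] ||
      headTiltRange[1] < -25 || headTiltRange[2] > 25)
    bad <- c(bad, "headTiltRange must lie within [-25, 25]")
  if (nPatients < 0 || sessionsPerPatient < 1)
    bad <- c(bad, "nPatients >= 0 and sessionsPerPatient >= 1 required")
  if (nrow(expressionGain) != 9L)
    bad <- c(bad, "expressionGain must have 9 rows")
  if (length(bad))
    .fsStop("config", paste(bad, collapse = "; "))
  structure(list(nPatients = as.integer(nPatients),
                 sessionsPerPatient = as.integer(sessionsPerPatient),
                 registry = registryName(reg),
                 droopPerGrade = droopPerGrade,
                 informativePairs = informativePairs,
                 expressionGain = expressionGain,
                 landmarkNoiseSd = landmarkNoiseSd,
                 severitySpread = severitySpread,
                 baselineAsymDeg = baselineAsymDeg,
                 localAsymDeg = localAsymDeg,
                 headTiltRange = headTiltRange,
                 imageSizePx = imageSizePx, seed = as.integer(seed)),
            class = "FaceSymSynthConfig")
}

#' Bilaterally symmetric schematic face template
#'
#' Lays out a parametric schematic face for a registry: midline landmarks
#' exactly on the vertical axis, every pair (L, R) mirrored across it (so
#' every pair angle is exactly 0 and any subset scores 0), with pair
#' positions grouped into eye/nose/mouth/contour clusters. The template is
#' a deterministic function of the registry; it deliberately reproduces no
#' specific detector's mesh topology, only its bilateral structure.
#'
#' @param registry a [PairRegistry-class] or built-in name.
#' @param imageSizePx canvas side length in pixels.
#' @return A [LandmarkSet-class] (dataset id "template", expression 1).
#' @export
makeTemplate <- function(registry = "dense-225", imageSizePx = 512) {
  reg <- loadRegistry(registry)
  n <- nLandmarks(reg)
  w <- imageSizePx
  cx <- (w - 1) / 2
  xy <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  p <- registryPairs(reg)

  # region layout in unit canvas fractions: (half-width, y) as a function
  # of within-region rank t in (0, 1)
  layout <- list(
    eye = function(t) c(dx = (0.12 + 0.13 * t) * w,
                        y = (0.30 + 0.10 * t + 0.02 * sin(6 * pi * t)) * w),
    nose = function(t) c(dx = (0.06 + 0.07 * t) * w,
                         y = (0.42 + 0.14 * t) * w),
    mouth = function(t) c(dx = (0.08 + 0.14 * t) * w,
                          y = (0.62 + 0.10 * t + 0.02 * sin(4 * pi * t)) * w),
    other = function(t) {
      phi <- (0.15 + 0.70 * t) * pi
      c(dx = 0.34 * w * sin(phi), y = cx - 0.40 * w * cos(phi))
    })
  for (r in names(layout)) {
    ord <- which(p$region == r)
    m <- length(ord)
    for (k in seq_len(m)) {
      pos <- layout[[r]](k / (m + 1))
      i <- ord[k]
      xy[p$left[i] + 1L, ] <- c(cx - pos[["dx"]], pos[["y"]])
      xy[p$right[i] + 1L, ] <- c(cx + pos[["dx"]], pos[["y"]])
    }
  }
  mid <- midlineIndices(reg)
  xy[mid + 1L, "x"] <- cx
  xy[mid + 1L, "y"] <- seq(0.15 * w, 0.82 * w, length.out = length(mid))
  rest <- which(is.na(xy[, 1])) # unpaired non-midline (mouth-axis) points
  if (length(rest)) {
    xy[rest, "x"] <- cx
    xy[rest, "y"] <- seq(0.66 * w, 0.72 * w, length.out = length(rest))
  }
  landmarkSet("template", 1L, xy, w, w)
}

#' Generate a synthetic patient cohort with known ground truth
#'
#' Per patient, a Stennert movement grade is drawn uniformly from 0-6, a
#' continuous latent severity \code{x_p} within that grade's band (see
#' \code{severitySpread}), the deterministic companion rest grade
#' \code{clip(round(move * 4/6), 0, 4)} (both scales coarsen the same
#' underlying impairment, so they are positively associated as in clinical
#' grading), and an affected side. Per image, the informative pairs'
#' affected-side landmarks are displaced vertically so the pair angle
#' equals \code{droopPerGrade * x_p * gain[expression, region]} exactly
#' before noise; all landmarks then receive isotropic Gaussian noise and a
#' random in-plane head tilt. All pairs additionally carry the patient's
#' persistent baseline asymmetry offsets (shared plus local, see
#' \code{baselineAsymDeg} and \code{localAsymDeg}); non-informative pairs
#' have no grade-dependent component. With the noise model disabled
#' (\code{landmarkNoiseSd}, \code{severitySpread}, \code{baselineAsymDeg},
#' \code{localAsymDeg}, \code{headTiltRange} all 0) the construction is
#' exact: informative-pair angles equal \code{droopPerGrade * move * gain}
#' and all other pairs are exactly horizontal.
#'
#' @param config a [syntheticConfig()].
#' @return List: \code{records} (list of [DatasetRecord-class]),
#'   \code{grades} (data.frame), \code{truth} (data.frame dataset_id,
#'   expression_id, pair_ordinal, region, expected_theta_deg with the
#'   signed noise-free angle), \code{informativePairs}, \code{config}.
#' @examples
#' cfg <- syntheticConfig(nPatients = 2, registry = "sparse-29",
#'                        landmarkNoiseSd = 0, headTiltRange = 0, seed = 7)
#' coh <- generateCohort(cfg)
#' length(coh$records)
#' @export
generateCohort <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "FaceSymSynthConfig"))
  reg <- loadRegistry(config$registry)
  tpl <- makeTemplate(reg, config$imageSizePx)
  base <- landmarkCoords(tpl)
  p <- registryPairs(reg)
  w <- config$imageSizePx
  pivot <- c((w - 1) / 2, (w - 1) / 2)
  info <- config$informativePairs
  infoRegion <- p$region[info]

  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, .GlobalEnv), add = TRUE)
  set.seed(config$seed)

  records <- list()
  grades <- list()
  truth <- list()
  for (pNo in seq_len(config$nPatients)) {
    pid <- sprintf("P%03d", pNo)
    move <- sample(0:6, 1)
    x <- if (config$severitySpread > 0)
      max(0, move + stats::runif(1, -config$severitySpread,
                                 config$severitySpread)) else move
    rest <- max(0L, min(4L, as.integer(round(move * 4 / 6))))
    side <- sample(c(-1, 1), 1)
    shared <- if (config$baselineAsymDeg > 0)
      stats::rnorm(1, 0, config$baselineAsymDeg) else 0
    baseline <- shared + (if (config$localAsymDeg > 0)
      stats::rnorm(nPairs(reg), 0, config$localAsymDeg)
      else numeric(nPairs(reg)))
    for (si in seq_len(config$sessionsPerPatient)) {
      did <- sprintf("%s_S%d", pid, si)
      sets <- list()
      for (e in 1:9) {
        gain <- config$expressionGain[e, infoRegion]
        th <- baseline
        th[info] <- th[info] + side * config$droopPerGrade * x * gain
        xy <- base
        lidx <- p$left + 1L
        ridx <- p$right + 1L
        dx <- xy[ridx, "x"] - xy[lidx, "x"]
        xy[ridx, "y"] <- xy[lidx, "y"] + tan(th * pi / 180) * dx
        if (config$landmarkNoiseSd > 0)
          xy <- xy + stats::rnorm(length(xy), 0, config$landmarkNoiseSd)
        tilt <- stats::runif(1, config$headTiltRange[1],
                             config$headTiltRange[2])
        if (tilt != 0) xy <- .rotateCoords(xy, tilt, pivot)
        sets[[as.character(e)]] <- landmarkSet(did, e, xy, w, w)
        truth[[length(truth) + 1L]] <- data.frame(
          dataset_id = did, expression_id = e,
          pair_ordinal = seq_len(nPairs(reg)), region = p$region,
          expected_theta_deg = th)
      }
      records[[did]] <- new("DatasetRecord", patientId = pid,
                            datasetId = did, sessionOrder = si,
                            expressions = sets)
      grades[[length(grades) + 1L]] <- data.frame(
        dataset_id = did, patient_id = pid, stennert_rest = rest,
        stennert_move = move)
    }
  }
  list(records = records,
       grades = if (length(grades)) do.call(rbind, grades) else
         data.frame(dataset_id = character(0), patient_id = character(0),
                    stennert_rest = integer(0), stennert_move = integer(0)),
       truth = if (length(truth))
         do.call(rbind, c(truth, list(make.row.names = FALSE))) else
         data.frame(dataset_id = character(0),
                    expression_id = integer(0),
                    pair_ordinal = integer(0), region = character(0),
                    expected_theta_deg = numeric(0)),
       informativePairs = info, config = config)
}
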