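test_that("the template is bilaterally symmetric with a vertical midline", {
  for (rn in c("dense-225", "sparse-29")) {
    reg <- loadRegistry(rn)
    tpl <- makeTemplate(reg, 512)
    av <- pairAngles(tpl, reg)
    expect_true(all(angleValues(av) == 0))
    expect_equal(scoreAI(av)$score_deg, 0)
    fit <- fitMidline(tpl, midlineIndices(reg))
    expect_equal(fit@slope, 0)
    expect_equal(alignLandmarks(tpl, midlineIndices(reg))@rotationDeg, 0)
    # reflection across the vertical axis maps the landmark cloud onto itself
    xy <- landmarkCoords(tpl)
    cx <- (512 - 1) / 2
    refl <- cbind(2 * cx - xy[, 1], xy[, 2])
    key <- function(m) sort(paste(round(m[, 1], 9), round(m[, 2], 9)))
    expect_identical(key(refl), key(xy))
  }
})

test_that("noise-free construction realizes the expected angles exactly", {
  cfg <- syntheticConfig(nPatients = 4, sessionsPerPatient = 1,
                         landmarkNoiseSd = 0, severitySpread = 0,
                         baselineAsymDeg = 0, localAsymDeg = 0,
                         headTiltRange = 0, seed = 9)
  coh <- quietly(generateCohort(cfg))
  reg <- loadRegistry(cfg$registry)
  info <- coh$informativePairs
  for (did in names(coh$records)) {
    g <- coh$grades$stennert_move[coh$grades$dataset_id == did]
    for (e in c(1, 5, 7)) {
      lm <- expressions(coh$records[[did]])[[as.character(e)]]
      th <- angleValues(pairAngles(lm, reg))
      gain <- cfg$expressionGain[e, registryPairs(reg)$region[info]]
      expect_equal(abs(th[info]), unname(cfg$droopPerGrade * g * gain),
                   tolerance = 1e-12)
      expect_true(all(th[-info] == 0))
    }
  }
})

test_that("zero-droop cohorts score exactly zero under every subset", {
  cfg <- syntheticConfig(nPatients = 2, sessionsPerPatient = 1,
                         droopPerGrade = 0, landmarkNoiseSd = 0,
                         severitySpread = 0, baselineAsymDeg = 0,
                         localAsymDeg = 0, headTiltRange = 0, seed = 2)
  coh <- quietly(generateCohort(cfg))
  res <- quietly(analyzeCohort(coh$records, "dense-225"))
  expect_true(all(res$scores$score_deg == 0))
})

test_that("head tilt alone does not change pipeline scores", {
  base <- quietly(generateCohort(syntheticConfig(
    nPatients = 2, sessionsPerPatient = 1, landmarkNoiseSd = 0,
    headTiltRange = 0, seed = 3)))
  tilted <- quietly(generateCohort(syntheticConfig(
    nPatients = 2, sessionsPerPatient = 1, landmarkNoiseSd = 0,
    headTiltRange = c(17, 17), seed = 3)))
  reg <- loadRegistry("dense-225")
  s91 <- registrySubset(reg, "91")
  for (did in names(base$records)) {
    for (e in c(2, 6)) {
      s0 <- alignLandmarks(expressions(base$records[[did]])[[as.character(e)]],
                           midlineIndices(reg))
      s1 <- alignLandmarks(expressions(tilted$records[[did]])[[as.character(e)]],
                           midlineIndices(reg))
      expect_lt(abs(scoreAI(pairAngles(s1@aligned, reg), s91)$score_deg -
                    scoreAI(pairAngles(s0@aligned, reg), s91)$score_deg),
                1e-6)
    }
  }
})

test_that("cohorts are reproducible for a fixed seed and change with it", {
  c1 <- smallCohort(nPatients = 2, seed = 5)
  c2 <- smallCohort(nPatients = 2, seed = 5)
  c3 <- smallCohort(nPatients = 2, seed = 6)
  xy1 <- landmarkCoords(expressions(c1$records[[1]])[["4"]])
  xy2 <- landmarkCoords(expressions(c2$records[[1]])[["4"]])
  xy3 <- landmarkCoords(expressions(c3$records[[1]])[["4"]])
  expect_identical(xy1, xy2)
  expect_false(identical(xy1, xy3))
  expect_identical(c1$grades, c2$grades)
})

test_that("estimated droop slope recovers the configured value within 10%", {
  cfg <- syntheticConfig(seed = 12)  # default cohort, 60 patients
  coh <- quietly(generateCohort(cfg))
  res <- quietly(analyzeCohort(coh$records, "dense-225", subsets = "91"))
  # per-unit mean |theta| over informative pairs vs movement grade
  ud <- quietly(unitDeviations(res$angles, coh$grades))
  info <- coh$informativePairs
  y <- rowMeans(ud$dev[, info])
  g <- ud$units$stennert_move
  slope <- coef(lm(y ~ g))[["g"]]
  regions <- registryPairs(loadRegistry("dense-225"))$region[info]
  gbar <- mean(colMeans(cfg$expressionGain)[regions])
  expect_lt(abs(slope - cfg$droopPerGrade * gbar),
            0.1 * cfg$droopPerGrade * gbar)
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(droopPerGrade = -1),
               class = "FaceSym_config_error")
  expect_error(syntheticConfig(headTiltRange = 30),
               class = "FaceSym_config_error")
  expect_error(syntheticConfig(landmarkNoiseSd = -0.1),
               class = "FaceSym_config_error")
})
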