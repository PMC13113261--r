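test_that("eta-squared matches hand values and the ANOVA oracle", {
  expect_equal(etaSquared(c(1, 2, 3, 4), c("a", "a", "b", "b")), 0.8)
  # equal group means, within-group variance > 0
  expect_equal(etaSquared(c(1, 3, 1, 3), c("a", "a", "b", "b")), 0)
  # groups of distinct constants: all variance between groups
  expect_equal(etaSquared(c(2, 2, 5, 5, 9), c("a", "a", "b", "b", "c")), 1)
  # zero total variance
  expect_equal(etaSquared(rep(3, 6), rep(c("a", "b"), 3)), 0)
  expect_error(etaSquared(1:5, rep("a", 5)),
               class = "FaceSym_degenerate_error")

  set.seed(101)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    k <- sample(2:4, 1)
    g <- sample(k, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    v <- rnorm(n) + 0.5 * g
    expect_lt(abs(etaSquared(v, g) - oracleEta2(v, g)), 1e-12)
  }
})

test_that("Kruskal-Wallis H matches the rank-sum oracle and handles degeneracy", {
  r <- kruskalWallisH(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r$statistic, 2.4, tolerance = 1e-12)
  expect_equal(r$df, 1L)

  # all-identical values: H = 0, p = 1
  r0 <- kruskalWallisH(rep(2, 8), rep(c("a", "b"), 4))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # strongly separated groups
  expect_lt(kruskalWallisH(c(1:10, 101:110),
                           rep(c("a", "b"), each = 10))$p_value, 0.001)

  set.seed(102)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    k <- sample(2:4, 1)
    g <- rep(seq_len(k), length.out = n)
    v <- rnorm(n)  # continuous, no ties
    expect_lt(abs(kruskalWallisH(v, g)$statistic - oracleH(v, g)), 1e-12)
    # invariance under strictly monotone transforms
    expect_lt(abs(kruskalWallisH(exp(v), g)$statistic -
                  kruskalWallisH(v, g)$statistic), 1e-12)
  }
  # tie correction agrees with the oracle on tied data
  set.seed(103)
  for (i in 1:20) {
    v <- sample(1:5, 30, replace = TRUE)
    g <- rep(1:3, each = 10)
    expect_lt(abs(kruskalWallisH(v, g)$statistic - oracleH(v, g)), 1e-12)
  }
})

test_that("Spearman rho equals Pearson-of-ranks and flags degenerate input", {
  expect_equal(spearmanRho(1:3, 4:6)$statistic, 1)
  expect_equal(spearmanRho(1:3, c(6, 5, 4))$statistic, -1)
  expect_error(spearmanRho(1:5, rep(2, 5)),
               class = "FaceSym_degenerate_error")
  set.seed(104)
  for (i in 1:100) {
    x <- sample(10)
    y <- sample(10)
    expect_lt(abs(spearmanRho(x, y)$statistic - oracleRho(x, y)), 1e-12)
  }
  # ties use average ranks
  x <- c(1, 1, 2, 3); y <- c(2, 3, 3, 5)
  expect_equal(spearmanRho(x, y)$statistic, oracleRho(x, y),
               tolerance = 1e-12)
})

test_that("unit deviations average correctly per session and per patient", {
  # one dataset, pair 1 with |theta| = 1..9 across expressions
  ang <- data.frame(dataset_id = "d1", expression_id = 1:9,
                    pair_ordinal = 1L, theta_deg = c(1, -2, 3, -4, 5, -6, 7, -8, 9))
  gr <- data.frame(dataset_id = "d1", patient_id = "p1",
                   stennert_rest = 1L, stennert_move = 2L)
  ud <- quietly(unitDeviations(ang, gr))
  expect_equal(unname(ud$dev[1, 1]), 5)

  # patient pooling over two sessions with equal grades: pooled mean
  ang2 <- rbind(
    data.frame(dataset_id = "d1", expression_id = 1:9, pair_ordinal = 1L,
               theta_deg = 2),
    data.frame(dataset_id = "d2", expression_id = 1:9, pair_ordinal = 1L,
               theta_deg = -4))
  gr2 <- data.frame(dataset_id = c("d1", "d2"), patient_id = "p1",
                    stennert_rest = 1L, stennert_move = 2L)
  ud2 <- quietly(unitDeviations(ang2, gr2, unit = "patient"))
  expect_equal(unname(ud2$dev[1, 1]), 3)
  expect_identical(nrow(ud2$dev), 1L)

  # conflicting grades under the strict patient reducer
  gr3 <- gr2; gr3$stennert_move <- c(2L, 3L)
  expect_error(quietly(unitDeviations(ang2, gr3, unit = "patient")),
               class = "FaceSym_aggregation_error")

  # ungraded datasets are excluded with a logged count: D - k units remain
  ang4 <- do.call(rbind, lapply(sprintf("d%d", 1:10), function(d)
    data.frame(dataset_id = d, expression_id = 1:9, pair_ordinal = 1L,
               theta_deg = 1)))
  gr4 <- data.frame(dataset_id = sprintf("d%d", 1:6),
                    patient_id = sprintf("p%d", 1:6),
                    stennert_rest = rep(0:1, 3), stennert_move = 1L)
  expect_message(ud4 <- unitDeviations(ang4, gr4), "4 of 10")
  expect_identical(nrow(ud4$dev), 6L)
})

test_that("threshold sweep subsets are nested and non-increasing in threshold", {
  set.seed(105)
  dev <- matrix(runif(40 * 12), 40, 12)
  # plant signal in pairs 1-4
  gmove <- sample(0:6, 40, replace = TRUE)
  grest <- pmin(4L, pmax(0L, as.integer(round(gmove * 4 / 6))))
  for (j in 1:4) dev[, j] <- dev[, j] + 0.8 * gmove
  units <- data.frame(unit = sprintf("u%d", 1:40), stennert_rest = grest,
                      stennert_move = gmove)
  eff <- pairEffects(dev, units)
  sw <- quietly(thresholdSweep(eff, dev, units))
  expect_true(all(diff(sw@trace$n_pairs) <= 0))
  # nesting: recompute subsets at two thresholds
  s1 <- which(eff$eta2_rest > 0.05 & eff$eta2_move > 0.05)
  s2 <- which(eff$eta2_rest > 0.20 & eff$eta2_move > 0.20)
  expect_true(all(s2 %in% s1))
  expect_equal(sw@minEta2,
               min(c(eff$eta2_rest[sw@chosenSubset],
                     eff$eta2_move[sw@chosenSubset])))
})

test_that("a null cohort is flagged non-discriminative and empty sweeps error", {
  set.seed(106)
  dev <- matrix(runif(30 * 8), 30, 8)
  units <- data.frame(unit = sprintf("u%d", 1:30),
                      stennert_rest = sample(0:4, 30, replace = TRUE),
                      stennert_move = sample(0:6, 30, replace = TRUE))
  eff <- pairEffects(dev, units)
  sw <- quietly(thresholdSweep(eff, dev, units))
  expect_identical(sw@nonDiscriminative,
                   sw@trace$p_rest[match(sw@chosenThreshold,
                                         sw@trace$threshold)] >= 0.05 &&
                   sw@trace$p_move[match(sw@chosenThreshold,
                                         sw@trace$threshold)] >= 0.05)

  effZero <- data.frame(pair = 1:8, eta2_rest = 0, eta2_move = 0)
  expect_error(quietly(thresholdSweep(effZero, dev, units)),
               class = "FaceSym_selection_error")
})

test_that("correlation report covers expressions, conditions and degenerate cells", {
  set.seed(107)
  ids <- sprintf("d%d", 1:30)
  gmove <- sample(0:6, 30, replace = TRUE)
  gr <- data.frame(dataset_id = ids, patient_id = ids,
                   stennert_rest = pmin(4L, as.integer(round(gmove * 4 / 6))),
                   stennert_move = gmove)
  sc <- do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(dataset_id = ids[i], expression_id = 1:9,
               subset_name = "chosen", n_pairs = 10L,
               score_deg = 0.5 * gmove[i] + runif(9, 0, 0.3))))
  rep <- correlationReport(sc, gr)
  expect_identical(nrow(rep), 20L)  # (9 expressions + all) x 2 conditions
  expect_true(all(rep$rho[rep$condition == "move"] > 0.5))
  # degenerate constant scores become NA cells with a warning
  scc <- sc; scc$score_deg <- 1
  w <- capture_warnings(repc <- correlationReport(scc, gr))
  expect_true(any(grepl("undefined", w)))
  expect_true(all(is.na(repc$rho)))
})

test_that("shuffled grades drive correlations to the null level", {
  set.seed(108)
  ids <- sprintf("d%d", 1:60)
  gmove <- sample(0:6, 60, replace = TRUE)
  sc <- data.frame(dataset_id = ids, expression_id = 1L,
                   subset_name = "s", n_pairs = 5L,
                   score_deg = 0.6 * gmove + rnorm(60, 0, 0.2))
  hits <- 0; reps <- 300
  for (i in seq_len(reps)) {
    r <- spearmanRho(sc$score_deg, sample(gmove))
    if (r$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)
})
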