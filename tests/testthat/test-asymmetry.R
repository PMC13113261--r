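test_that("pair angles follow the atan2 closed form and sign convention", {
  reg <- tinyRegistry()
  # pairs are landmarks (2,3), (4,5), (6,7); midline 0,1 at x = 0
  s <- makeSet(x = c(0, 0,  0, 10,  0, 10,  0, 0),
               y = c(0, 10, 0, 0,   0, 10,  0, 10))
  av <- pairAngles(s, reg)
  expect_equal(angleValues(av), c(0, 45, 90))  # horizontal, diagonal, vertical

  # random pairs match atan2 exactly
  set.seed(10)
  xl <- runif(3, 0, 50); yl <- runif(3, 0, 50)
  xr <- runif(3, 0, 50); yr <- runif(3, 0, 50)
  s2 <- makeSet(x = c(0, 0, xl[1], xr[1], xl[2], xr[2], xl[3], xr[3]),
                y = c(0, 10, yl[1], yr[1], yl[2], yr[2], yl[3], yr[3]))
  expect_equal(angleValues(pairAngles(s2, reg)),
               180 / pi * atan2(yr - yl, xr - xl), tolerance = 1e-15)
})

test_that("coincident pair points yield theta 0 with a warning, not an error", {
  reg <- tinyRegistry()
  s <- makeSet(x = c(0, 0, 5, 5, 0, 10, 0, 10),
               y = c(0, 10, 5, 5, 0, 0, 0, 0))
  expect_warning(av <- pairAngles(s, reg), "coincident")
  expect_equal(angleValues(av)[1], 0)
})

test_that("the asymmetry score is the mean absolute angle over the subset", {
  av <- new("AngleVector", datasetId = "d", expressionId = 1L,
            registryName = "tiny", theta = c(1, -2, 3))
  expect_equal(scoreAI(av)$score_deg, 2)
  expect_equal(scoreAI(av, 2)$score_deg, 2)           # singleton |theta_i|
  zero <- new("AngleVector", datasetId = "d", expressionId = 1L,
              registryName = "tiny", theta = rep(0, 5))
  expect_equal(scoreAI(zero)$score_deg, 0)
  set.seed(3)
  th <- runif(20, -90, 90)
  avr <- new("AngleVector", datasetId = "d", expressionId = 1L,
             registryName = "r", theta = th)
  i <- sample(20, 1)
  expect_equal(scoreAI(avr, i)$score_deg, abs(th[i]))
  expect_error(scoreAI(avr, integer(0)), class = "FaceSym_argument_error")
})

test_that("region scores decompose the 91-pair score exactly", {
  reg <- loadRegistry("dense-225")
  set.seed(21)
  th <- runif(225, -10, 10)
  av <- new("AngleVector", datasetId = "d", expressionId = 1L,
            registryName = "dense-225", theta = th)
  rs <- regionScores(av, reg, "91")
  expect_identical(rs$n_pairs[match(c("eye", "nose", "mouth"),
                                    rs$subset_name)],
                   c(24L, 23L, 44L))
  s91 <- scoreAI(av, registrySubset(reg, "91"))$score_deg
  weighted <- sum(rs$n_pairs * rs$score_deg) / sum(rs$n_pairs)
  expect_equal(weighted, s91, tolerance = 1e-12)

  # localized signal: mouth-only asymmetry stays in the mouth score
  th2 <- rep(0, 225)
  mouth <- registrySubset(reg, "mouth")
  th2[mouth] <- 5
  av2 <- new("AngleVector", datasetId = "d", expressionId = 1L,
             registryName = "dense-225", theta = th2)
  rs2 <- regionScores(av2, reg, "91")
  expect_equal(rs2$score_deg[rs2$subset_name == "mouth"], 5)
  expect_equal(rs2$score_deg[rs2$subset_name == "eye"], 0)
  expect_equal(rs2$score_deg[rs2$subset_name == "nose"], 0)
})

test_that("mirror reflection with swapped pair roles negates angles, score unchanged", {
  reg <- tinyRegistry()
  set.seed(4)
  x <- runif(8, 0, 100); y <- runif(8, 0, 100)
  x[1:2] <- 50  # vertical midline at x = 50
  s <- makeSet(x, y)
  th <- angleValues(pairAngles(s, reg))
  # reflect across x = 50 and swap left/right members of each pair
  xr <- 100 - x
  swap <- c(1, 2, 4, 3, 6, 5, 8, 7)
  s2 <- makeSet(xr[swap], y[swap])
  th2 <- angleValues(pairAngles(s2, reg))
  expect_equal(th2, -th, tolerance = 1e-12)
  expect_equal(scoreAI(th2)$score_deg, scoreAI(th)$score_deg)
})

test_that("expression summary reports the documented statistics and the 'all' column", {
  # constant cohort
  sc <- expand.grid(dataset_id = c("a", "b", "c"), expression_id = 1:9)
  sc$score_deg <- 2.5
  su <- expressionSummary(sc)
  expect_equal(unique(su$mean), 2.5)
  expect_equal(unique(su$sd), 0)
  expect_equal(unique(su$median), 2.5)

  # hand case: {1,2,3} for one expression (sample variance)
  sc2 <- data.frame(dataset_id = c("a", "b", "c"), expression_id = 1,
                    score_deg = c(1, 2, 3))
  su2 <- expressionSummary(sc2)
  r <- su2[su2$expression == "1", ]
  expect_equal(r$mean, 2); expect_equal(r$var, 1); expect_equal(r$median, 2)

  # "all" = mean of the nine per-expression scores of a dataset
  sc3 <- data.frame(dataset_id = "a", expression_id = 1:9,
                    score_deg = 1:9)
  su3 <- expressionSummary(sc3)
  expect_equal(su3$mean[su3$expression == "all"], 5)

  expect_identical(nrow(expressionSummary(sc3[0, ])), 0L)
})

test_that("pipeline score is invariant under moderate head tilt", {
  reg <- loadRegistry("sparse-29")
  tpl <- makeTemplate(reg, 256)
  xy <- landmarkCoords(tpl)
  # droop one mouth pair so the score is non-trivial
  p <- registryPairs(reg)
  i <- which(p$region == "mouth")[1]
  xy[p$right[i] + 1, 2] <- xy[p$right[i] + 1, 2] +
    tan(3 * pi / 180) * (xy[p$right[i] + 1, 1] - xy[p$left[i] + 1, 1])
  s <- makeSet(xy[, 1], xy[, 2], w = 256, h = 256)
  base <- alignLandmarks(s, midlineIndices(reg))
  ref <- scoreAI(pairAngles(base@aligned, reg))$score_deg
  for (beta in c(-25, -10, 17, 25)) {
    rot <- FaceSym:::.rotateCoords(xy, beta, c(127.5, 127.5))
    sr <- makeSet(rot[, 1], rot[, 2], w = 256, h = 256)
    al <- alignLandmarks(sr, midlineIndices(reg))
    expect_lt(abs(scoreAI(pairAngles(al@aligned, reg))$score_deg - ref),
              1e-6)
  }
})
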