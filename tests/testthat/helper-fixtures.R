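# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored binary fixtures.

# A hand-checkable registry: 8 landmarks, 2 midline points, 3 pairs.
tinyRegistry <- function() {
  pairRegistry("tiny", 8L,
               data.frame(left = c(2L, 4L, 6L), right = c(3L, 5L, 7L),
                          region = c("eye", "nose", "mouth")),
               midlineIndices = 0:1)
}

# LandmarkSet from explicit coordinates (x, y per landmark index order).
makeSet <- function(x, y, w = 100, h = 100, dataset = "d1", expr = 1L) {
  landmarkSet(dataset, expr, cbind(x = x, y = y), w, h)
}

# --- independent oracles -----------------------------------------------------

# eta-squared via stats::aov sums of squares (independent of the package's
# direct SS arithmetic).
oracleEta2 <- function(values, groups) {
  fit <- stats::aov(values ~ factor(groups))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  ss[1] / sum(ss)
}

# Kruskal-Wallis H from the rank-sum formula with tie correction,
# independently of stats::kruskal.test.
oracleH <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Spearman rho as Pearson correlation of average ranks.
oracleRho <- function(x, y) stats::cor(rank(x), rank(y))

# Quiet structured logging during tests unless a test asserts on it.
quietly <- function(expr) withr::with_options(list(FaceSym.quiet = TRUE),
                                              expr)

# Small default-structure cohort for pipeline tests.
smallCohort <- function(nPatients = 3, seed = 11, ...) {
  quietly(generateCohort(syntheticConfig(nPatients = nPatients,
                                         seed = seed, ...)))
}
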