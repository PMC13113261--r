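test_that("landmark file writer -> reader round trip is bit-exact", {
  coh <- smallCohort(nPatients = 2, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLandmarkFile(coh$records, f)
  back <- readLandmarkFile(f)
  expect_length(back, length(coh$records))
  for (did in names(coh$records)) {
    for (e in 1:9) {
      a <- landmarkCoords(expressions(coh$records[[did]])[[as.character(e)]])
      b <- landmarkCoords(expressions(back[[did]])[[as.character(e)]])
      expect_identical(unname(a), unname(b))
    }
  }
  # JSON mirror round-trips too
  fj <- withr::local_tempfile(fileext = ".json")
  writeLandmarkFile(coh$records, fj, format = "json")
  backj <- readLandmarkFile(fj)
  expect_equal(
    landmarkCoords(expressions(backj[[1]])[["3"]]),
    landmarkCoords(expressions(coh$records[[1]])[["3"]]))
})

test_that("datasets with an incomplete expression battery are excluded, not fatal", {
  coh <- smallCohort(nPatients = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLandmarkFile(coh$records, f)
  tab <- read.csv(f, colClasses = c(patient_id = "character",
                                    dataset_id = "character"))
  drop <- tab$dataset_id == tab$dataset_id[1] & tab$expression_id == 7
  write.csv(tab[!drop, ], f, row.names = FALSE, quote = FALSE)
  expect_message(back <- readLandmarkFile(f), "excluded 1 dataset")
  expect_length(back, length(coh$records) - 1L)
  expect_false(tab$dataset_id[1] %in% names(back))
})

test_that("duplicate and gapped landmark indices raise integrity errors naming the image", {
  coh <- smallCohort(nPatients = 1, seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLandmarkFile(coh$records, f)
  tab <- read.csv(f, colClasses = c(patient_id = "character",
                                    dataset_id = "character"))
  bad <- tab
  i <- which(bad$expression_id == 2 & bad$landmark_index == 1)[1]
  bad$landmark_index[i] <- 0L  # duplicates index 0, gaps index 1
  write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(readLandmarkFile(f), class = "FaceSym_integrity_error")
  expect_error(readLandmarkFile(f), "expression 2")
})

test_that("missing columns raise a format error", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = "p", dataset_id = "d"), f,
            row.names = FALSE)
  expect_error(readLandmarkFile(f), class = "FaceSym_format_error")
})

test_that("built-in registries satisfy the published structural counts", {
  dense <- loadRegistry("dense-225")
  expect_identical(nPairs(dense), 225L)
  expect_length(midlineIndices(dense), 20L)
  expect_identical(nLandmarks(dense), 478L)
  # 225 pairs + 20 midline + 8 mouth-axis landmarks account for all 478
  used <- c(registryPairs(dense)$left, registryPairs(dense)$right,
            midlineIndices(dense))
  expect_identical(478L - length(used), 8L)
  expect_identical(lengths(dense@subsets[c("140", "91", "50", "21")]),
                   c(`140` = 140L, `91` = 91L, `50` = 50L, `21` = 21L))
  s91 <- registrySubset(dense, "91")
  expect_identical(as.vector(table(registryPairs(dense)$region[s91])),
                   c(24L, 44L, 23L))  # eye, mouth, nose (alphabetical)

  s29 <- loadRegistry("sparse-29")
  expect_identical(nPairs(s29), 29L)
  expect_length(midlineIndices(s29), 6L)
  expect_identical(nLandmarks(s29), 68L)
  expect_length(registrySubset(s29, "21"), 21L)
  s21 <- loadRegistry("sparse-21")
  expect_identical(nPairs(s21), 21L)
  expect_false(any(registryPairs(s21)$region == "other"))
})

test_that("registry invariant violations raise registry errors listing indices", {
  expect_error(
    pairRegistry("bad", 20L,
                 data.frame(left = c(10L, 10L), right = c(11L, 12L),
                            region = c("eye", "eye")),
                 midlineIndices = 0:1),
    class = "FaceSym_registry_error")
  expect_error(
    pairRegistry("bad", 20L,
                 data.frame(left = 10L, right = 11L, region = "eye"),
                 midlineIndices = c(0L, 10L)),
    "midline")
  # registry JSON round trip preserves structure
  reg <- tinyRegistry()
  f <- withr::local_tempfile(fileext = ".json")
  writeRegistry(reg, f)
  back <- readRegistry(f)
  expect_identical(registryPairs(back), registryPairs(reg))
  expect_identical(midlineIndices(back), midlineIndices(reg))
})

test_that("detector adapter contract is enforced and errors are typed", {
  expect_error(detectLandmarks("img.png"),
               class = "FaceSym_capability_error")
  fake <- detectorAdapter(
    detect = function(path) cbind(c(1, 2, 3), c(4, 5, 6)),
    version = function() "fake-1.0")
  lm <- detectLandmarks("img.png", fake, "d1", 2L, 10, 10)
  expect_s4_class(lm, "LandmarkSet")
  expect_identical(nLandmarks(lm), 3L)
  blank <- detectorAdapter(detect = function(path) NULL,
                           version = function() "fake-1.0")
  expect_error(detectLandmarks("img.png", blank),
               class = "FaceSym_detection_error")
})

test_that("grade table validation enforces the Stennert ranges", {
  ok <- data.frame(dataset_id = c("a", "b"), patient_id = c("p", "q"),
                   stennert_rest = c(0L, 4L), stennert_move = c(0L, 6L))
  expect_silent(validateGrades(ok))
  bad <- ok; bad$stennert_move[1] <- 7L
  expect_error(validateGrades(bad), class = "FaceSym_integrity_error")
  dup <- ok; dup$dataset_id <- "a"
  expect_error(validateGrades(dup), class = "FaceSym_integrity_error")
})
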