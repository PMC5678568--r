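test_that("scene rendering is deterministic and respects separation", {
  spec <- smallSpec(seed = 5L, n = 2L)
  sc1 <- renderScene(spec)
  sc2 <- renderScene(spec)
  expect_identical(sc1$image, sc2$image)
  expect_identical(sc1$groundTruth, sc2$groundTruth)
  expect_equal(nrow(sc1$groundTruth), 2L)

  # brute-force pairwise separation on a denser scene
  sc <- renderScene(SceneSpec(nStomata = 10L, seed = 9L))
  ctr <- as.matrix(sc$groundTruth[, c("row", "col")])
  d <- as.matrix(dist(ctr)); diag(d) <- Inf
  expect_true(all(d >= 110))
})

test_that("a stoma-free spec renders background only", {
  spec <- smallSpec(seed = 2L, n = 0L)
  sc <- renderScene(spec)
  expect_equal(nrow(sc$groundTruth), 0L)
  expect_equal(dim(sc$image), c(320L, 320L))
})

test_that("impossible placement errors and names the separation", {
  spec <- SceneSpec(widthPx = 320L, heightPx = 320L, nStomata = 10L,
                    minSeparationPx = 400, seed = 1L)
  expect_error(renderScene(spec), "minSeparationPx")
})

test_that("renderStoma is deterministic and checks canvas bounds", {
  cv <- matrix(0.72, 120, 120)
  gt <- list(row = 60, col = 60, semiMajor = 20, semiMinor = 12,
             orientationDeg = 40, completeness = 0.8, gapStart = 0.3)
  expect_identical(renderStoma(gt, cv), renderStoma(gt, cv))
  gt$row <- 5
  expect_error(renderStoma(gt, cv), "bounds")
})

test_that("a complete boundary encloses the pore interior at the planted area", {
  # noise-free, blur-free rendering: the thresholded interior is one
  # connected region whose pixel count is within 3% of pi * sa * sb
  cv <- matrix(0.72, 101, 101)
  sa <- 22; sb <- 13
  gt <- list(row = 50, col = 50, semiMajor = sa, semiMinor = sb,
             orientationDeg = 25, completeness = 1, gapStart = 0)
  img <- renderStoma(gt, cv)
  bin <- binarizeROI(img, PoreConfig(sharpenAmount = 0))
  regions <- findRegions(bin)
  containing <- Filter(function(r) {
    any(r$coords[, 1] == 50 & r$coords[, 2] == 50)
  }, regions)
  expect_length(containing, 1L)
  expect_lt(abs(containing[[1]]$area - pi * sa * sb) / (pi * sa * sb), 0.03)
})

test_that("boundary gap geometry follows completeness", {
  # on a circle, arc-length fraction equals angular fraction: completeness
  # 0.7 leaves a single contiguous gap subtending 0.3 * 360 = 108 degrees
  cv <- matrix(0.72, 101, 101)
  gt <- list(row = 50, col = 50, semiMajor = 30, semiMinor = 30,
             orientationDeg = 0, completeness = 0.7, gapStart = 0.1)
  img <- renderStoma(gt, cv)
  dark <- which(img < 0.3, arr.ind = TRUE)
  ang <- sort(atan2(dark[, 1] - 51, dark[, 2] - 51) %% (2 * pi))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_equal(max(gaps) * 180 / pi, 108, tolerance = 0.05)
  # the remaining gaps are pixel-level
  expect_lt(sort(gaps, decreasing = TRUE)[2] * 180 / pi, 10)
})

test_that("rendered boundary arc length is proportional to completeness", {
  cv <- matrix(0.72, 121, 121)
  base <- list(row = 60, col = 60, semiMajor = 30, semiMinor = 15,
               orientationDeg = 15, gapStart = 0.2)
  nDark <- vapply(c(0.5, 0.75, 1), function(cc) {
    g <- base; g$completeness <- cc
    sum(renderStoma(g, cv) < 0.3)
  }, numeric(1))
  expect_equal(nDark[1] / nDark[3], 0.5, tolerance = 0.04)
  expect_equal(nDark[2] / nDark[3], 0.75, tolerance = 0.04)
})

test_that("training sets have centered positives and stoma-free negatives", {
  spec <- SceneSpec(seed = 31L)
  ts <- makeTrainingSet(spec, nPos = 3L, nNeg = 2L)
  expect_length(ts$positives, 3L)
  expect_length(ts$negatives, 2L)
  # ground-truth center within 1 px of the patch center
  ctr <- (96 - 1) / 2
  expect_true(all(abs(ts$positiveTruth$row - ctr) <= 1))
  expect_true(all(abs(ts$positiveTruth$col - ctr) <= 1))
  # negatives are rendered from stoma-free scenes: no generator record
  # places a stoma center in any negative patch
  negSpec <- spec
  expect_true(all(vapply(ts$negatives, function(m) is.matrix(m), logical(1))))
  # determinism of the whole set
  ts2 <- makeTrainingSet(spec, nPos = 3L, nNeg = 2L)
  expect_identical(ts$positives, ts2$positives)
  expect_identical(ts$negatives, ts2$negatives)
})

test_that("scene PNG and ground-truth CSV round-trip", {
  sc <- renderScene(smallSpec(seed = 12L))
  png <- tempfile(fileext = ".png")
  writeScenePNG(sc$image, png)
  back <- readMicrograph(png)
  expect_equal(dim(back), dim(sc$image))
  expect_lt(max(abs(back - sc$image)), 1 / 254)  # 8-bit quantization only

  csv <- tempfile(fileext = ".csv")
  writeGroundTruth(sc$groundTruth, csv, sceneId = "s1")
  gt <- readGroundTruth(csv)
  expect_equal(gt$row, sc$groundTruth$row)
  expect_equal(gt$semi_major_px, sc$groundTruth$semi_major_px)
  expect_equal(unique(gt$scene_id), "s1")
})
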