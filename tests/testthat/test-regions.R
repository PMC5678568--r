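test_that("binarization conventions", {
  expect_false(any(binarizeROI(matrix(0.5, 40, 40))))
  # exact two-level image: exact two-class partition
  img <- matrix(0, 40, 40); img[, 21:40] <- 1
  bin <- binarizeROI(img, PoreConfig(sharpenAmount = 0))
  expect_identical(bin, img == 1)
})

test_that("region labeling follows the configured connectivity", {
  expect_length(findRegions(matrix(FALSE, 10, 10)), 0L)
  b <- matrix(FALSE, 10, 10)
  b[2:4, 2:4] <- TRUE; b[7:9, 7:9] <- TRUE
  regs <- findRegions(b)
  expect_length(regs, 2L)
  expect_equal(sort(vapply(regs, function(r) r$area, numeric(1))), c(9, 9))
  # diagonal pixel pair: one region under 8-connectivity, two under 4
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_length(findRegions(d, 8L), 1L)
  expect_length(findRegions(d, 4L), 2L)
})

test_that("pore-region selection applies the area window before distance", {
  cfg <- PoreConfig(areaMaxPx = 100, areaMinPx = 5)
  center <- c(50, 50)
  expect_null(selectPoreRegion(list(), center, cfg))
  mk <- function(n, at) {
    s <- ceiling(sqrt(n))
    g <- expand.grid(r = at[1] + 0:(s - 1), c = at[2] + 0:(s - 1))
    stomataMorph:::regionFromCoords(cbind(g$r, g$c)[seq_len(n), , drop = FALSE])
  }
  small <- mk(50, c(48, 48))
  expect_identical(selectPoreRegion(list(small), center, cfg), small)
  # a large centered region above the limit loses to a small off-center one
  big <- mk(400, c(40, 40))
  off <- mk(50, c(10, 10))
  expect_identical(selectPoreRegion(list(big, off), center, cfg), off)
  # noise floor: tiny specks are never selected
  speck <- mk(2, c(50, 50))
  expect_null(selectPoreRegion(list(speck, big), center, cfg))
  # NA limit resolves to 20% of the ROI area (default noise floor is 60 px^2)
  mid <- mk(120, c(44, 44))
  expect_error(selectPoreRegion(list(mid), center, PoreConfig()), "roiDim")
  expect_identical(
    selectPoreRegion(list(mid), center, PoreConfig(), roiDim = c(96, 96)),
    mid)
  # centrality requirement: a lone qualifying fragment far from the ROI
  # center (e.g. cut off in a corner by a vein) is not the pore
  corner <- mk(120, c(2, 80))
  expect_null(
    selectPoreRegion(list(corner), center, PoreConfig(), roiDim = c(96, 96)))
  expect_identical(
    selectPoreRegion(list(corner, mid), center, PoreConfig(),
                     roiDim = c(96, 96)),
    mid)
})

test_that("region morphometry matches rasterization oracles", {
  # single pixel: area 1, eccentricity 0, a = b = sqrt(1/pi)
  r1 <- stomataMorph:::regionFromCoords(cbind(5, 5))
  m1 <- measureRegion(r1, pixelScale = 1)
  expect_equal(poreArea(m1), 1)
  expect_equal(poreEccentricity(m1), 0)
  expect_equal(unname(poreAxes(m1)), rep(sqrt(1 / pi), 2))

  # disc of radius 20: area within 2% of 400*pi, eccentricity <= 0.1
  disc <- rasterEllipse(61, 61, c(30, 30), 20, 20)
  rd <- findRegions(disc)[[1]]
  md <- measureRegion(rd, pixelScale = 1)
  expect_lt(abs(poreArea(md) - 400 * pi) / (400 * pi), 0.02)
  expect_lte(poreEccentricity(md), 0.1)

  # 40/20 ellipse: E within 0.03 of sqrt(1 - 0.25)
  ell <- rasterEllipse(101, 121, c(50, 60), 40, 20, 30)
  re <- findRegions(ell)[[1]]
  me <- measureRegion(re, pixelScale = 1)
  expect_lt(abs(poreEccentricity(me) - sqrt(0.75)), 0.03)

  # pixel scale converts areas to um^2
  m2 <- measureRegion(re, pixelScale = 8.6)
  expect_equal(poreArea(m2, "um"), poreArea(m2) / 8.6^2)
})

test_that("moment eccentricity agrees with an independent implementation", {
  ell <- rasterEllipse(101, 121, c(50, 60), 35, 18, 70)
  re <- findRegions(ell)[[1]]
  ours <- poreEccentricity(measureRegion(re, pixelScale = 1))
  f <- EBImage::computeFeatures.moment(matrix(as.integer(ell), nrow(ell)))
  expect_equal(ours, unname(f[1, "m.eccentricity"]), tolerance = 0.02)
})

test_that("axis lengths from area and eccentricity obey the identities", {
  expect_equal(unname(axesFromAreaEcc(pi, 0)), c(1, 1))
  ab <- axesFromAreaEcc(pi, sqrt(3) / 2)
  expect_equal(unname(ab), c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)
  set.seed(10)
  A <- exp(runif(200, -2, 8)); E <- runif(200, 0, 0.999)
  for (i in seq_len(200)) {
    ab <- axesFromAreaEcc(A[i], E[i])
    expect_lt(abs(pi * ab["a"] * ab["b"] - A[i]) / A[i], 1e-9)
    expect_lt(abs(ab["b"] / ab["a"] - sqrt(1 - E[i]^2)), 1e-9)
  }
  expect_error(axesFromAreaEcc(-1, 0), "area")
  expect_error(axesFromAreaEcc(1, 1), "eccentricity")
  expect_error(axesFromAreaEcc(1, 1.2), "eccentricity")
})
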