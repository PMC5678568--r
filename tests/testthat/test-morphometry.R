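# End-to-end behaviour of the two-path measurement engine on generated
# stomata with known geometry.

renderOneStoma <- function(seed, completeness, size = 96L) {
  spec <- SceneSpec(seed = seed, pComplete = ifelse(completeness >= 1, 1, 0),
                    completenessRange = rep(max(completeness, 0.05), 2))
  stomataMorph:::renderPositivePatch(seed, spec, size, stomaPalette())
}

test_that("complete boundaries take the segmentation path", {
  p <- renderOneStoma(1, 1)
  pm <- measurePore(p$image)
  expect_equal(measurementStatus(pm), "measured")
  expect_equal(measurementMethod(pm), "segmentation")
  expect_gt(nrow(poreBoundary(pm)), 20)
})

test_that("incomplete boundaries fall through to the skeleton path", {
  p <- renderOneStoma(2, 0.75)
  pm <- measurePore(p$image)
  expect_equal(measurementStatus(pm), "measured")
  expect_equal(measurementMethod(pm), "skeleton")
})

test_that("a blank ROI is discarded", {
  pm <- measurePore(matrix(0.5, 96, 96))
  expect_equal(measurementStatus(pm), "discarded")
  expect_true(all(is.na(c(poreArea(pm), poreEccentricity(pm)))))
})

test_that("measured records satisfy the axis-area identities exactly", {
  for (seed in 1:4) {
    pm <- measurePore(renderOneStoma(seed, ifelse(seed %% 2, 1, 0.8))$image)
    if (measurementStatus(pm) != "measured") next
    ax <- poreAxes(pm)
    expect_lt(abs(pi * ax["a"] * ax["b"] - poreArea(pm)) / poreArea(pm), 1e-9)
    expect_lt(abs(ax["b"] / ax["a"] - sqrt(1 - poreEccentricity(pm)^2)), 1e-9)
  }
})

test_that("the skeleton path only runs when segmentation found nothing", {
  cfg <- PoreConfig()
  for (seed in 11:25) {
    p <- renderOneStoma(seed, ifelse(seed %% 2, 1, 0.75))
    pm <- measurePore(p$image, cfg)
    if (measurementMethod(pm) == "skeleton") {
      bin <- binarizeROI(p$image, cfg)
      sel <- selectPoreRegion(findRegions(bin, cfg@connectivity),
                              (dim(p$image) - 1) / 2, cfg,
                              roiDim = dim(p$image))
      expect_null(sel)
    }
  }
})

test_that("segmentation path recovers planted pore parameters", {
  aErr <- eErr <- numeric(0)
  for (seed in 101:150) {
    p <- renderOneStoma(seed, 1)
    g <- p$groundTruth
    pm <- measurePore(p$image)
    expect_equal(measurementMethod(pm), "segmentation")
    At <- pi * g$semi_major_px * g$semi_minor_px
    Et <- sqrt(1 - (g$semi_minor_px / g$semi_major_px)^2)
    aErr <- c(aErr, abs(poreArea(pm) - At) / At)
    eErr <- c(eErr, abs(poreEccentricity(pm) - Et))
  }
  expect_lte(mean(aErr), 0.05)
  expect_lte(mean(eErr), 0.05)
})

test_that("skeleton path recovers planted parameters for 65-85% boundaries", {
  aErr <- eErr <- numeric(0)
  nSkel <- 0L
  set.seed(300)
  cs <- runif(50, 0.65, 0.85)
  for (k in seq_len(50)) {
    p <- renderOneStoma(200 + k, cs[k])
    g <- p$groundTruth
    pm <- measurePore(p$image)
    if (measurementStatus(pm) != "measured" ||
        measurementMethod(pm) != "skeleton") next
    nSkel <- nSkel + 1L
    At <- pi * g$semi_major_px * g$semi_minor_px
    Et <- sqrt(1 - (g$semi_minor_px / g$semi_major_px)^2)
    aErr <- c(aErr, abs(poreArea(pm) - At) / At)
    eErr <- c(eErr, abs(poreEccentricity(pm) - Et))
  }
  expect_gte(nSkel, 30L)  # most incomplete stomata are measured
  expect_lte(mean(aErr), 0.15)
  expect_lte(mean(eErr), 0.05)
})

test_that("boundaries at or below 50% completeness are mostly discarded", {
  discarded <- 0L
  for (k in seq_len(25)) {
    p <- renderOneStoma(400 + k, 0.45)
    pm <- measurePore(p$image)
    if (measurementStatus(pm) == "discarded") discarded <- discarded + 1L
  }
  expect_gte(discarded, ceiling(0.8 * 25))
})

test_that("mask-and-measure handles simple and empty masks", {
  bin <- matrix(FALSE, 60, 60)
  bin[rasterEllipse(60, 60, c(30, 30), 12, 8)] <- TRUE
  ell <- list(center = c(row = 30, col = 30), semiMajor = 16, semiMinor = 12,
              orientationDeg = 0)
  pm <- maskAndMeasure(ell, bin, pixelScale = 1)
  expect_equal(measurementStatus(pm), "measured")
  expect_equal(measurementMethod(pm), "skeleton")
  expect_equal(poreArea(pm), sum(bin), tolerance = 0.01)

  pmEmpty <- maskAndMeasure(ell, matrix(FALSE, 60, 60), 1)
  expect_equal(measurementStatus(pmEmpty), "discarded")
  expect_match(pmEmpty@reason, "empty_mask")
})
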