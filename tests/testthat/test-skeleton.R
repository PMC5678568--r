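test_that("thinning is idempotent on 1-px-wide curves", {
  h <- matrix(FALSE, 10, 30); h[5, 3:27] <- TRUE
  sk <- skeletonizeRegions(h)
  expect_length(sk, 1L)
  expect_equal(sk[[1]]$length, 25L)
  expect_setequal(sk[[1]]$coords[, 1], 4)

  d <- matrix(FALSE, 25, 25); for (i in 3:22) d[i, i] <- TRUE
  sk <- skeletonizeRegions(d)
  expect_equal(sk[[1]]$length, 20L)

  expect_length(skeletonizeRegions(matrix(FALSE, 10, 10)), 0L)
})

test_that("a filled rectangle thins to its central medial segment", {
  for (wh in list(c(41, 11), c(30, 10), c(25, 7))) {
    b <- matrix(FALSE, wh[2] + 10, wh[1] + 10)
    b[6:(5 + wh[2]), 6:(5 + wh[1])] <- TRUE
    sk <- skeletonizeRegions(b)
    expect_length(sk, 1L)
    expect_lte(abs(sk[[1]]$length - (wh[1] - wh[2] + 1)), 2)
  }
})

test_that("short spurs are pruned, long branches kept", {
  # a 30-px horizontal bar with a 3-px stub must lose the stub
  b <- matrix(FALSE, 20, 40)
  b[10, 5:34] <- TRUE
  b[7:9, 20] <- TRUE
  pruned <- pruneSpurs(which(b, arr.ind = TRUE) - 1, maxLen = 5L)
  expect_equal(nrow(pruned), 30L)
  expect_true(all(pruned[, 1] == 9))
  # a long branch survives
  b[3:9, 20] <- TRUE
  kept <- pruneSpurs(which(b, arr.ind = TRUE) - 1, maxLen = 5L)
  expect_equal(nrow(kept), 37L)
  # open curves without branch points are untouched
  curve <- cbind(5, 2:20)
  expect_identical(pruneSpurs(curve, maxLen = 5L), curve)
})

test_that("skeleton selection filters by length then picks the nearest", {
  cfg <- PoreConfig(skeletonLengthBounds = c(10, 60))
  expect_null(selectSkeleton(list(), c(50, 50), cfg))
  mk <- function(row, cols) {
    coords <- cbind(row, cols)
    list(coords = coords, length = nrow(coords), centroid = colMeans(coords))
  }
  near <- mk(48, 30:59)   # length 30, centroid (48, 44.5)
  far <- mk(10, 30:59)
  short <- mk(50, 49:52)  # below the length floor
  long <- mk(52, 1:90)    # above the ceiling
  expect_identical(selectSkeleton(list(near), c(50, 50), cfg), near)
  expect_identical(selectSkeleton(list(far, near), c(50, 50), cfg), near)
  expect_null(selectSkeleton(list(short, long), c(50, 50), cfg))
  # with the ROI size known, remnants far from the center do not qualify
  expect_null(selectSkeleton(list(far), c(50, 50), cfg, roiDim = c(100, 100)))
  expect_identical(selectSkeleton(list(far, near), c(50, 50), cfg,
                                  roiDim = c(100, 100)), near)
})
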