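test_that("noiseless points on a full ellipse are recovered exactly", {
  pts <- ellipseArcPoints(c(40, 80), 30, 15, 30, n = 20)
  f <- fitEllipse(pts)
  expect_equal(f$semiMajor, 30, tolerance = 1e-6)
  expect_equal(f$semiMinor, 15, tolerance = 1e-6)
  expect_equal(unname(f$center), c(40, 80), tolerance = 1e-6)
  expect_equal(f$orientationDeg, 30, tolerance = 1e-4)
  # coverage needs dense points (as skeleton pixels are); 20 sparse points
  # leave gaps wider than the coverage tolerance
  dense <- fitEllipse(ellipseArcPoints(c(40, 80), 30, 15, 30, n = 120))
  expect_gt(dense$coverage, 0.95)
})

test_that("degenerate inputs raise fit errors instead of returning garbage", {
  expect_error(fitEllipse(cbind(c(1, 2, 3, 4), c(2, 3, 1, 4))), "at least 5")
  expect_error(fitEllipse(cbind(1:9, 2 * (1:9) + 3)), class = "ellipseFitError")
  expect_error(fitEllipse(cbind(rep(1, 6), rep(2, 6))),
               class = "ellipseFitError")
})

test_that("a 65% arc still recovers the semi-axes within 5%", {
  set.seed(21)
  for (k in 1:5) {
    sa <- runif(1, 15, 30); sb <- sa * runif(1, 0.45, 0.8)
    pts <- ellipseArcPoints(c(0, 0), sa, sb, runif(1, 0, 180), n = 40,
                            arcFraction = 0.65, startFraction = runif(1))
    f <- fitEllipse(pts)
    expect_lt(abs(f$semiMajor - sa) / sa, 0.05)
    expect_lt(abs(f$semiMinor - sb) / sb, 0.05)
  }
})

test_that("arcs under 50% fail the completeness gate", {
  set.seed(22)
  fails <- 0L
  n <- 20L
  for (k in seq_len(n)) {
    sa <- runif(1, 15, 30); sb <- sa * runif(1, 0.45, 0.8)
    pts <- ellipseArcPoints(c(0, 0), sa, sb, runif(1, 0, 180), n = 30,
                            arcFraction = 0.45, startFraction = runif(1))
    r <- tryCatch(fitEllipse(pts, minArcFraction = 0.6),
                  ellipseFitError = function(e) "failed")
    if (identical(r, "failed")) fails <- fails + 1L
  }
  expect_gte(fails, ceiling(0.8 * n))
})

test_that("perimeter coverage measures boundary completeness", {
  full <- ellipseArcPoints(c(0, 0), 25, 14, 40, n = 80)
  part <- ellipseArcPoints(c(0, 0), 25, 14, 40, n = 60, arcFraction = 0.7,
                           startFraction = 0.25)
  fFull <- fitEllipse(full)
  expect_gt(fFull$coverage, 0.97)
  cov <- stomataMorph:::ellipseCoverage(part, fFull)
  expect_equal(cov, 0.7, tolerance = 0.08)
})
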