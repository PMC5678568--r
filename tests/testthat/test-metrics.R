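test_that("matching handles the base cases", {
  empty <- data.frame(row0 = numeric(0), col0 = numeric(0), row1 = numeric(0),
                      col1 = numeric(0))
  expect_equal(matchDetections(empty, matrix(numeric(0), 0, 2)),
               c(TP = 0L, FP = 0L, FN = 0L))
  one <- data.frame(row0 = 0, col0 = 0, row1 = 10, col1 = 10)
  expect_equal(matchDetections(one, cbind(5, 5)), c(TP = 1L, FP = 0L, FN = 0L))
  # one box containing two centers: one-to-one matching leaves one FN
  expect_equal(matchDetections(one, rbind(c(4, 4), c(6, 6))),
               c(TP = 1L, FP = 0L, FN = 1L))
  # a center on the half-open upper edge is outside
  expect_equal(matchDetections(one, cbind(10, 5)), c(TP = 0L, FP = 1L, FN = 1L))
})

test_that("counts are conserved on random scenes", {
  set.seed(17)
  for (k in 1:25) {
    nd <- sample(0:8, 1); ng <- sample(0:8, 1)
    det <- data.frame(row0 = runif(nd, 0, 80), col0 = runif(nd, 0, 80))
    det$row1 <- det$row0 + runif(nd, 10, 40)
    det$col1 <- det$col0 + runif(nd, 10, 40)
    ctr <- cbind(runif(ng, 0, 100), runif(ng, 0, 100))
    cc <- matchDetections(det, ctr)
    expect_equal(cc[["TP"]] + cc[["FP"]], nd)
    expect_equal(cc[["TP"]] + cc[["FN"]], ng)
    if (sum(cc) > 0) {
      m <- detectionMetrics(cc)
      expect_true(all(m[c("precision", "recall", "accuracy")] >= 0 &
                      m[c("precision", "recall", "accuracy")] <= 100))
      expect_lte(m[["accuracy"]], min(m[["precision"]], m[["recall"]]) + 1e-12)
    }
  }
})

test_that("greedy matching agrees with exhaustive optimal assignment", {
  set.seed(18)
  for (k in 1:40) {
    nd <- sample(1:6, 1); ng <- sample(1:6, 1)
    det <- data.frame(row0 = runif(nd, 0, 60), col0 = runif(nd, 0, 60))
    det$row1 <- det$row0 + runif(nd, 15, 45)
    det$col1 <- det$col0 + runif(nd, 15, 45)
    ctr <- cbind(runif(ng, 0, 80), runif(ng, 0, 80))
    greedy <- matchDetections(det, ctr)[["TP"]]
    expect_equal(greedy, maxMatchingSize(det, ctr))
  }
})

test_that("metric arithmetic reproduces reference confusion tables", {
  m <- detectionMetrics(c(TP = 1597, FP = 145, FN = 415))
  expect_equal(round(unname(m), 2), c(91.68, 79.37, 74.04, 0.85))
  m2 <- detectionMetrics(c(TP = 746, FP = 652, FN = 1266))
  expect_equal(round(unname(m2), 2), c(53.36, 37.08, 28.00, 0.44))
  # zero-TP convention
  m3 <- detectionMetrics(c(TP = 0, FP = 0, FN = 5))
  expect_equal(unname(m3), c(0, 0, 0, 0))
  expect_warning(detectionMetrics(c(TP = 0, FP = 0, FN = 0)), "metrics")
})

test_that("measurement agreement is the complement of relative error", {
  expect_equal(measurementAgreement(100, 100)$relative_error_pct, 0)
  expect_equal(measurementAgreement(100, 100)$agreement_pct, 100)
  expect_equal(measurementAgreement(2, 1)$relative_error_pct, 50)
  r <- measurementAgreement(100, 110)
  expect_equal(r$relative_error_pct, 10)
  expect_equal(r$agreement_pct, 90)
  expect_error(measurementAgreement(0, 1), "non-zero")
  v <- measurementAgreement(c(10, 20), c(11, 18))
  expect_equal(v$relative_error_pct, c(10, 10))
})

test_that("pore identification rate", {
  expect_equal(round(poreIdentificationRate(1093, 174), 2), 86.27)
  expect_equal(poreIdentificationRate(1, 0), 100)
  expect_equal(poreIdentificationRate(0, 7), 0)
  expect_error(poreIdentificationRate(0, 0), "identification")
})
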