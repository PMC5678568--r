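test_that("a separable problem is solved by a single stump", {
  pos <- matrix(seq(2, 3, length.out = 20), 20, 1)
  neg <- matrix(seq(-3, -2, length.out = 20), 20, 1)
  st <- trainStage(pos, neg)
  expect_equal(nrow(st$learners), 1L)
  expect_equal(st$tpr, 1)
  expect_equal(st$fpr, 0)
})

test_that("indistinguishable classes yield no discrimination, not an error", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  st <- trainStage(X, X, stageTPRMin = 0.995, stageFPRMax = 0.5,
                   maxWeakLearners = 5L)
  # identical feature sets: whatever passes the threshold on positives
  # passes identically on negatives
  expect_gte(st$tpr, 0.995)
  expect_equal(st$fpr, st$tpr)
})

test_that("threshold adjustment accepts the required fraction of positives", {
  set.seed(5)
  pos <- matrix(rnorm(200, 0.5), 100, 2)
  neg <- matrix(rnorm(200, -0.5), 100, 2)
  st <- trainStage(pos, neg, stageTPRMin = 0.98)
  accepted <- sum(stomataMorph:::stageScores(st, pos) >= st$threshold)
  expect_gte(accepted, ceiling(0.98 * 100))
  expect_error(trainStage(pos[0, , drop = FALSE], neg), "positive")
  expect_error(trainStage(pos, neg[0, , drop = FALSE]), "negative")
})

test_that("cascade training requires both classes", {
  expect_error(trainCascade(list(), list(matrix(0, 96, 96))), "positive")
  expect_error(trainCascade(list(matrix(0, 96, 96)), list()), "negative")
})

test_that("a trained cascade keeps its training positives", {
  tc <- getTestCascade()
  model <- tc$model
  expect_lte(nStages(model), 4L)
  res <- vapply(tc$trainingSet$positives,
                function(p) classifyWindow(model, p)$accepted, logical(1))
  # training-set recall bound: product of per-stage minimum hit rates
  expect_gte(mean(res), 0.995^nStages(model))
})

test_that("cascade semantics: early exit, monotonicity, conjunction", {
  tc <- getTestCascade()
  model <- tc$model
  sc <- renderScene(smallSpec(seed = 55L, n = 1L))
  raw <- detectStomata(model, sc$image, stridePx = 16L, scaleFactors = 1,
                       rawWindows = TRUE)
  expect_lte(nrow(raw), 1000L)

  # early-exit equivalence: exhaustive evaluation gives the same decisions
  win <- model@hog@windowPx[1]
  ex <- stomataMorph:::cpp_scan(sc$image, model@hog@cellPx,
    model@hog@blockCells, model@hog@nOrientationBins,
    model@hog@normalizationEpsilon, win, 16L, model@stages, FALSE)
  expect_equal(raw$accepted, unname(ex[, "accepted"] == 1))
  expect_equal(raw$score[raw$accepted],
               unname(ex[ex[, "accepted"] == 1, "score"]))
  # rejected windows stop at their first failing stage
  expect_true(all(raw$stages_evaluated[!raw$accepted] <= nStages(model)))
  expect_true(all(ex[, "stages_evaluated"] == nStages(model)))

  # acceptance equals the conjunction of independent per-stage decisions
  idx <- head(order(-raw$score), 40)
  for (i in idx) {
    patch <- sc$image[raw$row0[i] + seq_len(win), raw$col0[i] + seq_len(win)]
    x <- matrix(computeHOG(patch, model@hog), 1)
    perStage <- vapply(model@stages, function(st)
      stomataMorph:::stageScores(st, x) >= st$threshold, logical(1))
    expect_equal(classifyWindow(model, patch)$accepted, all(perStage))
  }

  # appending a stage never increases the accepted set
  for (k in seq_len(nStages(model) - 1)) {
    m1 <- new("CascadeModel", hog = model@hog, stages = model@stages[1:k])
    m2 <- new("CascadeModel", hog = model@hog, stages = model@stages[1:(k + 1)])
    r1 <- detectStomata(m1, sc$image, stridePx = 16L, scaleFactors = 1,
                        rawWindows = TRUE)
    r2 <- detectStomata(m2, sc$image, stridePx = 16L, scaleFactors = 1,
                        rawWindows = TRUE)
    expect_true(all(r1$accepted | !r2$accepted))
  }
})

test_that("coarser strides are a subset of stride-1 raw windows", {
  tc <- getTestCascade()
  img <- renderScene(smallSpec(seed = 66L, n = 1L))$image[1:140, 1:140]
  r1 <- detectStomata(tc$model, img, stridePx = 1L, scaleFactors = 1,
                      rawWindows = TRUE)
  r4 <- detectStomata(tc$model, img, stridePx = 4L, scaleFactors = 1,
                      rawWindows = TRUE)
  key1 <- paste(r1$row0, r1$col0, r1$accepted, signif(r1$score, 12))
  key4 <- paste(r4$row0, r4$col0, r4$accepted, signif(r4$score, 12))
  expect_true(all(key4 %in% key1))
})

test_that("detection on degenerate images", {
  tc <- getTestCascade()
  expect_equal(nrow(detectStomata(tc$model, matrix(0.5, 200, 200))), 0L)
  expect_warning(det <- detectStomata(tc$model, matrix(0.5, 40, 40)),
                 "smaller than the detection window")
  expect_equal(nrow(det), 0L)
})

test_that("non-maximum suppression follows the greedy rule", {
  empty <- data.frame(row0 = numeric(0), col0 = numeric(0), row1 = numeric(0),
                      col1 = numeric(0), score = numeric(0))
  expect_equal(nrow(nonMaxSuppression(empty, 0.3)), 0L)
  disjoint <- data.frame(row0 = c(0, 50), col0 = c(0, 50), row1 = c(10, 60),
                         col1 = c(10, 60), score = c(1, 2))
  expect_equal(nrow(nonMaxSuppression(disjoint, 0.3)), 2L)
  dup <- data.frame(row0 = c(0, 0), col0 = c(0, 0), row1 = c(10, 10),
                    col1 = c(10, 10), score = c(2, 1))
  kept <- nonMaxSuppression(dup, 0.3)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 2)
  # surviving pairs are below the IoU threshold
  set.seed(8)
  boxes <- data.frame(row0 = runif(40, 0, 80), col0 = runif(40, 0, 80))
  boxes$row1 <- boxes$row0 + 20; boxes$col1 <- boxes$col0 + 20
  boxes$score <- runif(40)
  surv <- nonMaxSuppression(boxes, 0.3)
  if (nrow(surv) > 1) {
    m <- as.matrix(surv[, 1:4])
    for (i in seq_len(nrow(surv) - 1)) {
      iou <- stomataMorph:::boxIoU(m[i, ], m[-(1:i), , drop = FALSE])
      expect_true(all(iou < 0.3))
    }
  }
  # deterministic tie-break: equal scores keep the smaller (row0, col0)
  tie <- data.frame(row0 = c(5, 0), col0 = c(5, 0), row1 = c(15, 10),
                    col1 = c(15, 10), score = c(1, 1))
  expect_equal(nonMaxSuppression(tie, 0.1)$row0, 0)
})

test_that("model JSON serialization round-trips byte-identically", {
  tc <- getTestCascade()
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  saveCascade(tc$model, f1)
  back <- readCascade(f1)
  saveCascade(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and the loaded model behaves identically
  img <- renderScene(smallSpec(seed = 13L, n = 1L))$image
  expect_identical(detectStomata(tc$model, img), detectStomata(back, img))
  tmp <- tempfile()
  jsonlite::write_json(list(a = 1), tmp)
  expect_error(readCascade(tmp), "not a cascade")
})
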