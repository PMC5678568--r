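# Boosted-stage training and sliding-window detection.

# Weighted vote of a stage's stumps on a feature matrix (rows = samples).
stageScores <- function(stage, X) {
  L <- stage$learners
  s <- numeric(nrow(X))
  for (i in seq_len(nrow(L))) {
    v <- X[, L[i, 1]]
    h <- if (L[i, 3] > 0) v >= L[i, 2] else v < L[i, 2]
    s <- s + L[i, 4] * (2 * h - 1)
  }
  s
}

# Evaluate a full stage list on a feature matrix; returns logical acceptance.
cascadeAccept <- function(stages, X) {
  ok <- rep(TRUE, nrow(X))
  for (st in stages) {
    if (!any(ok)) break
    idx <- which(ok)
    ok[idx] <- stageScores(st, X[idx, , drop = FALSE]) >= st$threshold
  }
  ok
}

#' Train one boosted stage of the cascade
#'
#' Runs discrete adaptive boosting of depth-1 decision stumps on single HOG
#' components, then lowers the stage acceptance threshold until the training
#' true-positive rate reaches \code{stageTPRMin} (the attentional-cascade
#' threshold adjustment: a stage must pass almost every true stoma and is
#' only asked to reject a fraction of the negatives). Stumps are added until
#' the false-positive rate at the adjusted threshold drops to
#' \code{stageFPRMax} or \code{maxWeakLearners} is reached.
#'
#' @param posFeatures,negFeatures numeric feature matrices (rows = samples).
#' @param stageTPRMin minimum training true-positive rate per stage.
#' @param stageFPRMax target training false-positive rate per stage.
#' @param maxWeakLearners cap on stumps per stage.
#' @param minWeakLearners minimum stumps per stage unless the classes are
#'   already perfectly separated; a stage that stops at the first stump to
#'   scrape under the false-positive target generalizes poorly beyond its
#'   mined negatives, so stages are trained to at least this strength.
#' @return A stage: list with \code{learners} (matrix with columns
#'   \code{feature}, \code{threshold}, \code{polarity}, \code{weight}),
#'   \code{threshold}, and achieved training \code{tpr} and \code{fpr}.
#' @examples
#' pos <- matrix(rnorm(40, 2), 20, 2)
#' neg <- matrix(rnorm(40, -2), 20, 2)
#' st <- trainStage(pos, neg)
#' st$fpr
#' @export
trainStage <- function(posFeatures, negFeatures, stageTPRMin = 0.995,
                       stageFPRMax = 0.5, maxWeakLearners = 25L,
                       minWeakLearners = 6L) {
  if (!nrow(posFeatures)) stop("no positive samples")
  if (!nrow(negFeatures)) stop("no negative samples")
  np <- nrow(posFeatures); nn <- nrow(negFeatures)
  X <- rbind(posFeatures, negFeatures)
  y <- c(rep(1L, np), rep(-1L, nn))
  w <- c(rep(1 / (2 * np), np), rep(1 / (2 * nn), nn))
  ord <- cpp_stump_order(X)
  learners <- matrix(numeric(0), 0, 4,
                     dimnames = list(NULL, c("feature", "threshold",
                                             "polarity", "weight")))
  scores <- numeric(np + nn)
  for (t in seq_len(maxWeakLearners)) {
    st <- cpp_best_stump(X, ord, w / sum(w), y)
    err <- min(max(st$error, 1e-12), 1 - 1e-12)
    alpha <- 0.5 * log((1 - err) / err)
    v <- X[, st$feature]
    h <- if (st$polarity > 0) v >= st$threshold else v < st$threshold
    h <- 2 * h - 1
    learners <- rbind(learners, c(st$feature, st$threshold, st$polarity, alpha))
    scores <- scores + alpha * h
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
    # threshold adjustment: accept at least ceil(stageTPRMin * np) positives
    ps <- sort(scores[seq_len(np)])
    k <- floor((1 - stageTPRMin) * np)
    thr <- ps[k + 1]
    fpr <- mean(scores[np + seq_len(nn)] >= thr)
    if (fpr == 0) break  # perfect separation: nothing left to learn
    if ((fpr <= stageFPRMax && t >= minWeakLearners) ||
        st$error >= 0.5 - 1e-12) break
  }
  tpr <- mean(scores[seq_len(np)] >= thr)
  structure(list(learners = learners, threshold = thr, tpr = tpr, fpr = fpr),
            class = "BoostedStage")
}

# Mine hard-negative windows: positions in the negative images, across the
# same image pyramid the detector scans, that the current cascade still
# accepts. The scan stride is refined (halved down to 1 px) until enough
# windows survive, so late stages still find the rare false positives they
# must learn to reject.
mineNegatives <- function(negatives, stages, hog, negPerStage, minNegPool,
                          startStridePx = 16L, scales = c(1, 0.8, 1.25)) {
  win <- hog@windowPx[1]
  scaled <- function(img, s) {
    if (s == 1) return(img)
    EBImage::imageData(EBImage::resize(img, w = round(nrow(img) * s),
                                       h = round(ncol(img) * s)))
  }
  stride <- as.integer(startStridePx)
  pool <- NULL
  repeat {
    pool <- do.call(rbind, unlist(lapply(seq_along(negatives), function(k) {
      lapply(seq_along(scales), function(si) {
        img <- scaled(negatives[[k]], scales[si])
        if (nrow(img) < win || ncol(img) < win) return(NULL)
        sc <- cpp_scan(img, hog@cellPx, hog@blockCells, hog@nOrientationBins,
                       hog@normalizationEpsilon, win, stride, stages, TRUE)
        acc <- sc[sc[, "accepted"] == 1, c("r0", "c0"), drop = FALSE]
        if (!nrow(acc)) return(NULL)
        cbind(img = k, scale = si, acc)
      })
    }), recursive = FALSE))
    if ((!is.null(pool) && nrow(pool) >= negPerStage) || stride == 1L) break
    stride <- max(1L, stride %/% 2L)
  }
  if (is.null(pool) || nrow(pool) < minNegPool)
    return(list(features = NULL, stride = stride))
  if (nrow(pool) > negPerStage)
    pool <- pool[sample.int(nrow(pool), negPerStage), , drop = FALSE]
  feats <- matrix(0, nrow(pool), hogFeatureLength(hog))
  for (grp in split(seq_len(nrow(pool)),
                    pool[, "img"] * 10 + pool[, "scale"])) {
    img <- scaled(negatives[[pool[grp[1], "img"]]],
                  scales[pool[grp[1], "scale"]])
    for (i in grp) {
      r0 <- pool[i, "r0"]; c0 <- pool[i, "c0"]
      feats[i, ] <- computeHOG(img[r0 + seq_len(win), c0 + seq_len(win)], hog)
    }
  }
  list(features = feats, stride = stride)
}

#' Train an attentional cascade detector
#'
#' Stages are trained sequentially. Stage k is trained on the positives that
#' survive stages 1..k-1 and on hard negatives: windows from the negative
#' images that the current cascade still accepts (false positives of stages
#' 1..k-1). Because each stage passes nearly all positives while rejecting
#' about half of its negatives, the cascade's overall false-positive rate
#' shrinks geometrically with depth. Training halts early with a warning if
#' the negative pool is exhausted, returning fewer stages.
#'
#' @param positives list of window-sized patches (matrices), one stoma each;
#'   patches of other sizes are resampled to the window.
#' @param negatives list of stoma-free images (each at least window-sized)
#'   from which negative windows are mined.
#' @param nStages number of stages to train.
#' @param stageTPRMin,stageFPRMax,maxWeakLearners,minWeakLearners per-stage
#'   targets, see \code{\link{trainStage}}.
#' @param hog a \code{\link{HOGParams}} object.
#' @param negPerStage negative windows mined per stage (default
#'   \code{max(800, 2 * length(positives))}).
#' @param minNegPool minimum mined windows required to train a stage.
#' @param mineStridePx stride used when mining negative windows.
#' @param seed seed for the subsampling of mined windows.
#' @param verbose print per-stage progress.
#' @return A \code{\link{CascadeModel-class}} object with at most
#'   \code{nStages} stages.
#' @export
trainCascade <- function(positives, negatives, nStages = 8L,
                         stageTPRMin = 0.995, stageFPRMax = 0.5,
                         maxWeakLearners = 25L, minWeakLearners = 6L,
                         hog = HOGParams(), negPerStage = NULL,
                         minNegPool = 8L, mineStridePx = 16L, seed = 1L,
                         verbose = FALSE) {
  if (!length(positives)) stop("no positive samples")
  if (!length(negatives)) stop("no negative samples")
  win <- hog@windowPx[1]
  posF <- t(vapply(positives, function(p) {
    if (!all(dim(p) == win))
      p <- EBImage::imageData(EBImage::resize(p, w = win, h = win))
    computeHOG(p, hog)
  }, numeric(hogFeatureLength(hog))))
  if (is.null(negPerStage)) negPerStage <- max(800L, 2L * nrow(posF))
  # augment the negative pool with flipped copies (still stoma-free imagery)
  negatives <- c(negatives,
                 lapply(negatives, function(m) m[nrow(m):1, , drop = FALSE]),
                 lapply(negatives, function(m) m[, ncol(m):1, drop = FALSE]),
                 lapply(negatives, function(m) m[nrow(m):1, ncol(m):1,
                                                 drop = FALSE]))
  stages <- list()
  alive <- rep(TRUE, nrow(posF))
  mineStride <- as.integer(mineStridePx)
  withLocalSeed(seed, {
    for (k in seq_len(nStages)) {
      mined <- mineNegatives(negatives, stages, hog, negPerStage, minNegPool,
                             startStridePx = mineStride)
      mineStride <- mined$stride  # finer strides stay fine for later stages
      negF <- mined$features
      if (is.null(negF)) {
        warning(sprintf(
          "negative pool exhausted after %d stages; returning a %d-stage cascade",
          k - 1L, k - 1L))
        break
      }
      st <- trainStage(posF[alive, , drop = FALSE], negF, stageTPRMin,
                       stageFPRMax, maxWeakLearners, minWeakLearners)
      stages[[k]] <- st
      alive[alive] <- stageScores(st, posF[alive, , drop = FALSE]) >= st$threshold
      if (verbose)
        message(sprintf("stage %d: %d stumps, tpr %.3f, fpr %.3f, %d positives alive",
                        k, nrow(st$learners), st$tpr, st$fpr, sum(alive)))
      if (!any(alive)) break
    }
  })
  new("CascadeModel", hog = hog, stages = stages)
}

#' Classify a single window with the cascade
#'
#' The window is rejected at the first stage whose weighted stump vote falls
#' below the stage threshold; later stages are not evaluated. The score is
#' the sum of stage margins (vote minus threshold) over the stages passed.
#'
#' @param model a \code{\link{CascadeModel-class}}.
#' @param patch numeric matrix; resampled to the model window if needed.
#' @return List with \code{accepted} (logical), \code{score} (numeric) and
#'   \code{stagesEvaluated} (integer).
#' @export
classifyWindow <- function(model, patch) {
  win <- model@hog@windowPx[1]
  if (!all(dim(patch) == win))
    patch <- EBImage::imageData(EBImage::resize(patch, w = win, h = win))
  x <- matrix(computeHOG(patch, model@hog), 1)
  score <- 0; neval <- 0L
  for (st in model@stages) {
    m <- stageScores(st, x) - st$threshold
    neval <- neval + 1L
    if (m < 0)
      return(list(accepted = FALSE, score = score, stagesEvaluated = neval))
    score <- score + m
  }
  list(accepted = TRUE, score = score, stagesEvaluated = neval)
}

#' Detect stomata by sliding the cascade over a micrograph
#'
#' The window slides at \code{stridePx} over the image at each pyramid scale;
#' accepted windows are mapped back to original-image coordinates and merged
#' with \code{\link{nonMaxSuppression}}. Boxes are 0-based, half-open
#' \code{(row0, col0, row1, col1)}.
#'
#' @param model a \code{\link{CascadeModel-class}}.
#' @param image numeric matrix (intensities in [0, 1]) or RGB array.
#' @param stridePx sliding-window stride in px.
#' @param scaleFactors image pyramid scales (a factor < 1 finds stomata
#'   larger than the window).
#' @param nmsIoU IoU threshold for non-maximum suppression.
#' @param rawWindows if TRUE, return every window with its score and
#'   acceptance instead of the suppressed detection list (for diagnostics).
#' @return A data frame with columns \code{row0}, \code{col0}, \code{row1},
#'   \code{col1}, \code{score} (plus \code{scale}, \code{accepted},
#'   \code{stages_evaluated} when \code{rawWindows}).
#' @export
detectStomata <- function(model, image, stridePx = 8L,
                          scaleFactors = c(0.8, 1, 1.25), nmsIoU = 0.3,
                          rawWindows = FALSE) {
  image <- toGray(image)
  win <- model@hog@windowPx[1]
  out <- list()
  anyScale <- FALSE
  for (s in scaleFactors) {
    nr <- round(nrow(image) * s); nc <- round(ncol(image) * s)
    if (nr < win || nc < win) next
    anyScale <- TRUE
    img <- if (s == 1) image else
      EBImage::imageData(EBImage::resize(image, w = nr, h = nc))
    sc <- cpp_scan(img, model@hog@cellPx, model@hog@blockCells,
                   model@hog@nOrientationBins, model@hog@normalizationEpsilon,
                   win, as.integer(stridePx), model@stages, !rawWindows)
    if (!nrow(sc)) next
    df <- data.frame(row0 = sc[, "r0"] / s, col0 = sc[, "c0"] / s,
                     row1 = (sc[, "r0"] + win) / s,
                     col1 = (sc[, "c0"] + win) / s,
                     score = sc[, "score"], scale = s,
                     accepted = sc[, "accepted"] == 1,
                     stages_evaluated = sc[, "stages_evaluated"])
    out[[length(out) + 1]] <- df
  }
  if (!anyScale)
    warning("image smaller than the detection window at every scale")
  dets <- if (length(out)) do.call(rbind, out) else
    data.frame(row0 = numeric(0), col0 = numeric(0), row1 = numeric(0),
               col1 = numeric(0), score = numeric(0), scale = numeric(0),
               accepted = logical(0), stages_evaluated = numeric(0))
  if (rawWindows) return(dets)
  dets <- dets[dets$accepted, c("row0", "col0", "row1", "col1", "score")]
  rownames(dets) <- NULL
  nonMaxSuppression(dets, nmsIoU)
}

boxIoU <- function(a, b) {
  ri <- pmax(0, pmin(a[3], b[, 3]) - pmax(a[1], b[, 1]))
  ci <- pmax(0, pmin(a[4], b[, 4]) - pmax(a[2], b[, 2]))
  inter <- ri * ci
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (areaA + areaB - inter)
}

#' Greedy non-maximum suppression
#'
#' Detections are visited in order of descending score (ties broken by
#' smaller \code{(row0, col0)} for determinism); each kept box suppresses all
#' remaining boxes whose intersection-over-union with it reaches
#' \code{iouThreshold}.
#'
#' @param detections data frame with columns \code{row0}, \code{col0},
#'   \code{row1}, \code{col1}, \code{score}.
#' @param iouThreshold IoU at or above which the lower-scoring box is
#'   suppressed.
#' @return The surviving detections; every surviving pair has IoU below
#'   \code{iouThreshold}.
#' @examples
#' d <- data.frame(row0 = c(0, 0), col0 = c(0, 0), row1 = c(10, 10),
#'                 col1 = c(10, 10), score = c(2, 1))
#' nonMaxSuppression(d, 0.3)
#' @export
nonMaxSuppression <- function(detections, iouThreshold = 0.3) {
  stopifnot(iouThreshold >= 0, iouThreshold <= 1)
  if (!nrow(detections)) return(detections)
  ord <- order(-detections$score, detections$row0, detections$col0)
  d <- detections[ord, ]
  m <- as.matrix(d[, c("row0", "col0", "row1", "col1")])
  keep <- logical(nrow(d))
  active <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!active[i]) next
    keep[i] <- TRUE
    if (i < nrow(d)) {
      j <- (i + 1):nrow(d)
      jj <- j[active[j]]
      if (length(jj)) {
        iou <- boxIoU(m[i, ], m[jj, , drop = FALSE])
        active[jj[iou >= iouThreshold]] <- FALSE
      }
    }
  }
  out <- d[keep, ]
  rownames(out) <- NULL
  out
}

#' Save / load a cascade model as versioned JSON
#'
#' The JSON file stores the HOG parameters and every stage's stumps and
#' threshold at full double precision; write -> read -> write round-trips
#' are byte-identical.
#'
#' @param model a \code{\link{CascadeModel-class}}.
#' @param path JSON file path.
#' @return \code{saveCascade}: the path, invisibly; \code{readCascade}: the
#'   model.
#' @export
saveCascade <- function(model, path) {
  obj <- list(
    format = "stomataMorph-cascade", version = "1.0",
    hog = list(window_px = model@hog@windowPx, cell_px = model@hog@cellPx,
               block_cells = model@hog@blockCells,
               n_orientation_bins = model@hog@nOrientationBins,
               normalization_epsilon = model@hog@normalizationEpsilon),
    stages = lapply(model@stages, function(st) list(
      threshold = st$threshold,
      tpr = if (is.null(st$tpr)) NA else st$tpr,
      fpr = if (is.null(st$fpr)) NA else st$fpr,
      learners = list(feature = st$learners[, 1], threshold = st$learners[, 2],
                      polarity = st$learners[, 3], weight = st$learners[, 4])))
  )
  # 17 significant digits: doubles survive the write -> read round trip
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname saveCascade
#' @export
readCascade <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(obj$format, "stomataMorph-cascade"))
    stop("not a cascade model file")
  hog <- HOGParams(windowPx = obj$hog$window_px, cellPx = obj$hog$cell_px,
                   blockCells = obj$hog$block_cells,
                   nOrientationBins = obj$hog$n_orientation_bins,
                   normalizationEpsilon = obj$hog$normalization_epsilon)
  stages <- lapply(obj$stages, function(st) {
    L <- cbind(feature = st$learners$feature, threshold = st$learners$threshold,
               polarity = st$learners$polarity, weight = st$learners$weight)
    structure(list(learners = L, threshold = st$threshold,
                   tpr = if (is.null(st$tpr) || is.na(st$tpr)) NULL else st$tpr,
                   fpr = if (is.null(st$fpr) || is.na(st$fpr)) NULL else st$fpr),
              class = "BoostedStage")
  })
  new("CascadeModel", hog = hog, stages = stages)
}
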