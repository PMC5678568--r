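# Shared fixtures, all generated in code.

# Small, fast scene spec for pipeline-level tests.
smallSpec <- function(seed = 1L, n = 2L, ...) {
  SceneSpec(widthPx = 320L, heightPx = 320L, nStomata = n, nVeins = 2L,
            nDust = 8L, minSeparationPx = 120, seed = seed, ...)
}

# Rasterize a filled ellipse as a logical matrix (axis-aligned unless
# rotated), pixel centers at integer coordinates.
rasterEllipse <- function(nr, nc, center, sa, sb, thetaDeg = 0) {
  rows <- matrix(seq_len(nr) - 1, nr, nc)
  cols <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  th <- thetaDeg * pi / 180
  dy <- rows - center[1]; dx <- cols - center[2]
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  (xr / sa)^2 + (yr / sb)^2 <= 1
}

# A small trained cascade, built once per test run and reused.
.cascadeCache <- new.env(parent = emptyenv())
getTestCascade <- function() {
  if (is.null(.cascadeCache$model)) {
    ts <- makeTrainingSet(SceneSpec(seed = 101L), nPos = 40L, nNeg = 15L)
    .cascadeCache$model <- suppressWarnings(
      trainCascade(ts$positives, ts$negatives, nStages = 4L, seed = 7L))
    .cascadeCache$trainingSet <- ts
  }
  list(model = .cascadeCache$model, trainingSet = .cascadeCache$trainingSet)
}

# Exhaustive maximum bipartite matching between detections and centers
# (center-in-box edges); oracle for the greedy matcher on tiny instances.
maxMatchingSize <- function(detections, centers) {
  nd <- nrow(detections); ng <- nrow(centers)
  edge <- matrix(FALSE, nd, ng)
  for (i in seq_len(nd))
    edge[i, ] <- centers[, 1] >= detections$row0[i] &
      centers[, 1] < detections$row1[i] &
      centers[, 2] >= detections$col0[i] &
      centers[, 2] < detections$col1[i]
  best <- 0L
  recurse <- function(i, usedG, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    recurse(i + 1L, usedG, count)  # leave detection i unmatched
    for (j in which(edge[i, ] & !usedG)) {
      usedG[j] <- TRUE
      recurse(i + 1L, usedG, count + 1L)
      usedG[j] <- FALSE
    }
  }
  if (nd > 0 && ng > 0) recurse(1L, logical(ng), 0L) else best <- 0L
  best
}
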