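#' Intensity palette of the synthetic epidermis renderer
#'
#' The generator follows the dark-boundaries-on-light-background appearance of
#' epidermal imprint micrographs: pore boundaries and veins are dark, the
#' pore interior and the background are light, guard-cell rings are slightly
#' brighter than the background. All values are intensities in [0, 1].
#'
#' @param background mean background intensity.
#' @param mottleSd sd of the low-frequency background mottle.
#' @param wall intensity of epidermal cell-wall lines.
#' @param vein intensity of vein ridges.
#' @param dust intensity of dust blobs.
#' @param poreInterior intensity inside the pore.
#' @param poreBoundary intensity of the pore-boundary ring.
#' @param guardRing intensity of the guard-cell ring.
#' @param ringThicknessPx radial thickness of the pore-boundary ring (px).
#' @param guardWidthPx radial width of the guard-cell ring (px).
#' @return Named list of rendering constants.
#' @export
stomaPalette <- function(background = 0.72, mottleSd = 0.03, wall = 0.66,
                         vein = 0.25, dust = 0.2, poreInterior = 0.8,
                         poreBoundary = 0.15, guardRing = 0.84,
                         ringThicknessPx = 2.5, guardWidthPx = 6) {
  list(background = background, mottleSd = mottleSd, wall = wall, vein = vein,
       dust = dust, poreInterior = poreInterior, poreBoundary = poreBoundary,
       guardRing = guardRing, ringThicknessPx = ringThicknessPx,
       guardWidthPx = guardWidthPx)
}

# Fraction of the ellipse perimeter (by arc length) accumulated up to
# parametric angle phi, as a lookup table.
arcLengthTable <- function(sa, sb, n = 2048L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)
  mid <- (phi[-1] + phi[-(n + 1L)]) / 2
  dl <- sqrt((sa * sin(mid))^2 + (sb * cos(mid))^2)
  cf <- c(0, cumsum(dl))
  list(phi = phi, frac = cf / cf[n + 1L])
}

#' Render a single stoma onto a canvas
#'
#' Draws one stoma: a bright guard-cell ring, a light pore interior, and a
#' dark pore-boundary ring along the ellipse with semi-axes
#' (\code{semiMajor}, \code{semiMinor}). When \code{completeness < 1} the
#' boundary carries a single contiguous gap: the rendered arc covers exactly
#' the fraction \code{completeness} of the boundary's arc length, starting at
#' perimeter fraction \code{gapStart + (1 - completeness)}. Rendering is
#' deterministic: the same ground truth on the same canvas yields a
#' bit-identical patch.
#'
#' @param gt list (or one-row data frame) with fields \code{row}, \code{col}
#'   (0-based pixel coordinates of the pore center), \code{semiMajor},
#'   \code{semiMinor} (px), \code{orientationDeg}, \code{completeness} in
#'   (0, 1], and \code{gapStart} in [0, 1) (perimeter fraction where the gap
#'   begins).
#' @param canvas numeric matrix (intensities in [0, 1]) to draw on.
#' @param palette rendering constants, see \code{\link{stomaPalette}}.
#' @return The canvas with the stoma drawn.
#' @examples
#' cv <- matrix(0.72, 96, 96)
#' gt <- list(row = 47.5, col = 47.5, semiMajor = 20, semiMinor = 12,
#'            orientationDeg = 30, completeness = 1, gapStart = 0)
#' patch <- renderStoma(gt, cv)
#' @export
renderStoma <- function(gt, canvas, palette = stomaPalette()) {
  gt <- as.list(gt)
  sa <- gt$semiMajor; sb <- gt$semiMinor
  stopifnot(sa >= sb, sb > 0)
  t0 <- palette$ringThicknessPx; gw <- palette$guardWidthPx
  outer <- sa + t0 + gw
  nr <- nrow(canvas); nc <- ncol(canvas)
  if (gt$row - outer < 0 || gt$row + outer > nr - 1 ||
      gt$col - outer < 0 || gt$col + outer > nc - 1)
    stop("stoma ellipse exceeds canvas bounds")
  rows <- (floor(gt$row - outer) + 1):(ceiling(gt$row + outer) + 1)
  cols <- (floor(gt$col - outer) + 1):(ceiling(gt$col + outer) + 1)
  dy <- outer(rows - 1 - gt$row, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - 1 - gt$col)
  th <- gt$orientationDeg * pi / 180
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  Q <- function(s) (xr / (sa + s))^2 + (yr / (sb + s))^2
  q0 <- Q(0); qt <- Q(t0); qg <- Q(t0 + gw)
  sub <- canvas[rows, cols]
  sub[qt > 1 & qg <= 1] <- palette$guardRing
  sub[q0 <= 1] <- palette$poreInterior
  ring <- q0 > 1 & qt <= 1
  cpl <- gt$completeness
  if (cpl >= 0.995) {
    sub[ring] <- palette$poreBoundary
  } else {
    tab <- arcLengthTable(sa, sb)
    phi <- atan2(yr[ring] / sb, xr[ring] / sa) %% (2 * pi)
    frac <- approx(tab$phi, tab$frac, phi, rule = 2)$y
    inGap <- ((frac - gt$gapStart) %% 1) < (1 - cpl)
    idx <- which(ring)[!inGap]
    sub[idx] <- palette$poreBoundary
  }
  canvas[rows, cols] <- sub
  canvas
}

# Low-frequency mottle + epidermal cell-wall line texture.
backgroundTexture <- function(nr, nc, palette) {
  cv <- matrix(palette$background, nr, nc)
  gr <- max(2L, ceiling(nr / 16)); gc <- max(2L, ceiling(nc / 16))
  coarse <- matrix(rnorm(gr * gc, 0, palette$mottleSd), gr, gc)
  mott <- EBImage::resize(coarse, w = nr, h = nc)
  cv <- cv + EBImage::imageData(mott)
  nWalls <- round(nr * nc / 4000)
  for (i in seq_len(nWalls)) {
    p1 <- c(runif(1, 0, nr - 1), runif(1, 0, nc - 1))
    ang <- runif(1, 0, pi); len <- runif(1, 15, 50)
    p2 <- p1 + len * c(sin(ang), cos(ang))
    cv <- stampSegment(cv, p1, p2, width = 1.4, value = palette$wall)
  }
  cv
}

# Draw a straight segment of given width (assignment, not blending).
stampSegment <- function(canvas, p1, p2, width, value) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r0 <- max(1, floor(min(p1[1], p2[1]) - width)); r1 <- min(nr, ceiling(max(p1[1], p2[1]) + width) + 1)
  c0 <- max(1, floor(min(p1[2], p2[2]) - width)); c1 <- min(nc, ceiling(max(p1[2], p2[2]) + width) + 1)
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  py <- outer(rows - 1 - p1[1], rep(1, length(cols)))
  px <- outer(rep(1, length(rows)), cols - 1 - p1[2])
  v <- p2 - p1; L2 <- sum(v^2)
  tt <- if (L2 > 0) pmin(pmax((py * v[1] + px * v[2]) / L2, 0), 1) else 0
  d2 <- (py - tt * v[1])^2 + (px - tt * v[2])^2
  sub <- canvas[rows, cols]
  sub[d2 <= (width / 2)^2] <- value
  canvas[rows, cols] <- sub
  canvas
}

# Stamp a filled disc.
stampDisc <- function(canvas, center, radius, value) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r0 <- max(1, floor(center[1] - radius)); r1 <- min(nr, ceiling(center[1] + radius) + 1)
  c0 <- max(1, floor(center[2] - radius)); c1 <- min(nc, ceiling(center[2] + radius) + 1)
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - 1 - center[1])^2, rep(1, length(cols))) +
    outer(rep(1, length(rows)), (cols - 1 - center[2])^2)
  sub <- canvas[rows, cols]
  sub[d2 <= radius^2] <- value
  canvas[rows, cols] <- sub
  canvas
}

# A vein: quadratic Bezier between two border points, stamped as discs.
veinPath <- function(nr, nc) {
  borderPoint <- function(side) {
    switch(side,
      c(0, runif(1, 0, nc - 1)), c(nr - 1, runif(1, 0, nc - 1)),
      c(runif(1, 0, nr - 1), 0), c(runif(1, 0, nr - 1), nc - 1))
  }
  sides <- sample(1:4, 2)
  p0 <- borderPoint(sides[1]); p2 <- borderPoint(sides[2])
  p1 <- c(runif(1, 0, nr - 1), runif(1, 0, nc - 1))
  tt <- seq(0, 1, length.out = 4 * max(nr, nc))
  cbind((1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1],
        (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2])
}

# Place n points with minimum pairwise separation inside a margin.
placeCenters <- function(n, nr, nc, margin, minSep) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  if (nr - 1 - 2 * margin <= 0 || nc - 1 - 2 * margin <= 0)
    stop("canvas too small for the requested stoma geometry")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (try in seq_len(4000L * n)) {
    p <- c(runif(1, margin, nr - 1 - margin), runif(1, margin, nc - 1 - margin))
    if (placed == 0L || all(distToPoint(centers[seq_len(placed), , drop = FALSE], p) >= minSep)) {
      placed <- placed + 1L
      centers[placed, ] <- p
      if (placed == n) return(centers)
    }
  }
  stop(sprintf("unable to place %d stomata at minSeparationPx = %g", n, minSep))
}

# Draw per-stoma geometry from a SceneSpec.
drawStomaParams <- function(spec, n) {
  sa <- runif(n, spec@poreSemiAxisRange[1], spec@poreSemiAxisRange[2])
  aspect <- runif(n, spec@aspectRange[1], spec@aspectRange[2])
  complete <- runif(n) < spec@pComplete
  cpl <- ifelse(complete, 1,
                runif(n, spec@completenessRange[1], spec@completenessRange[2]))
  data.frame(semi_major_px = sa, semi_minor_px = sa * aspect,
             orientation_deg = runif(n, 0, 180), completeness = cpl,
             gap_start = runif(n))
}

#' Render a synthetic epidermis micrograph
#'
#' Produces a full scene: background cell-mosaic texture, \code{nStomata}
#' stomata separated by at least \code{minSeparationPx}, vein-like dark
#' curvilinear ridges, dust blobs, then Gaussian blur and additive Gaussian
#' noise. Veins and dust are kept away from stoma centers so each planted
#' stoma's ground truth stays clean. Fully deterministic given the spec.
#'
#' @param spec a \code{\link{SceneSpec}}.
#' @param palette rendering constants, see \code{\link{stomaPalette}}.
#' @return A list with elements \code{image} (numeric matrix, intensities in
#'   [0, 1], indexed [row, col]) and \code{groundTruth} (data frame with
#'   columns \code{stoma_id}, \code{row}, \code{col} (0-based),
#'   \code{semi_major_px}, \code{semi_minor_px}, \code{orientation_deg},
#'   \code{completeness}, \code{gap_start}).
#' @examples
#' sc <- renderScene(SceneSpec(widthPx = 256L, heightPx = 256L,
#'                             nStomata = 2L, nVeins = 1L, seed = 3L))
#' dim(sc$image)
#' sc$groundTruth
#' @export
renderScene <- function(spec, palette = stomaPalette()) {
  validObject(spec)
  withLocalSeed(spec@seed, {
    nr <- spec@heightPx; nc <- spec@widthPx
    cv <- backgroundTexture(nr, nc, palette)
    margin <- spec@poreSemiAxisRange[2] + palette$ringThicknessPx +
      palette$guardWidthPx + 4
    centers <- placeCenters(spec@nStomata, nr, nc, margin, spec@minSeparationPx)
    # veins avoid stomata so planted ground truth stays uncorrupted
    keepAway <- function(path, dist) {
      spec@nStomata == 0 ||
        all(apply(centers, 1, function(p) min(distToPoint(path, p))) >= dist)
    }
    for (i in seq_len(spec@nVeins)) {
      for (try in seq_len(80)) {
        path <- veinPath(nr, nc)
        if (keepAway(path, margin + 18)) {
          step <- max(1L, nrow(path) %/% (2 * max(nr, nc)))
          pts <- path[seq(1, nrow(path), by = step), , drop = FALSE]
          for (k in seq_len(nrow(pts)))
            cv <- stampDisc(cv, pts[k, ], 1.5, palette$vein)
          break
        }
      }
    }
    for (i in seq_len(spec@nDust)) {
      for (try in seq_len(80)) {
        p <- c(runif(1, 0, nr - 1), runif(1, 0, nc - 1))
        if (spec@nStomata == 0 ||
            min(distToPoint(centers, p)) >= margin + 12) {
          cv <- stampDisc(cv, p, runif(1, 1, 3), palette$dust)
          break
        }
      }
    }
    gt <- drawStomaParams(spec, spec@nStomata)
    if (spec@nStomata > 0) {
      gt <- cbind(data.frame(stoma_id = seq_len(spec@nStomata),
                             row = centers[, 1], col = centers[, 2]), gt)
      for (i in seq_len(spec@nStomata)) {
        cv <- renderStoma(list(row = gt$row[i], col = gt$col[i],
                               semiMajor = gt$semi_major_px[i],
                               semiMinor = gt$semi_minor_px[i],
                               orientationDeg = gt$orientation_deg[i],
                               completeness = gt$completeness[i],
                               gapStart = gt$gap_start[i]), cv, palette)
      }
    } else {
      gt <- cbind(data.frame(stoma_id = integer(0), row = numeric(0),
                             col = numeric(0)), gt)
    }
    if (spec@blurSigmaPx > 0)
      cv <- EBImage::imageData(EBImage::gblur(cv, sigma = spec@blurSigmaPx))
    if (spec@noiseSd > 0)
      cv <- cv + matrix(rnorm(nr * nc, 0, spec@noiseSd), nr, nc)
    list(image = clamp01(cv), groundTruth = gt)
  })
}

# One window-sized patch with a single centered stoma (training positive).
renderPositivePatch <- function(seed, spec, windowPx, palette) {
  withLocalSeed(seed, {
    cv <- backgroundTexture(windowPx, windowPx, palette)
    maxSa <- (windowPx - 1) / 2 - palette$ringThicknessPx -
      palette$guardWidthPx - 2
    par <- drawStomaParams(spec, 1L)
    par$semi_major_px <- min(par$semi_major_px, maxSa)
    par$semi_minor_px <- min(par$semi_minor_px, par$semi_major_px)
    ctr <- (windowPx - 1) / 2 + runif(2, -1, 1)
    gt <- cbind(data.frame(stoma_id = 1L, row = ctr[1], col = ctr[2]), par)
    cv <- renderStoma(list(row = gt$row, col = gt$col,
                           semiMajor = gt$semi_major_px,
                           semiMinor = gt$semi_minor_px,
                           orientationDeg = gt$orientation_deg,
                           completeness = gt$completeness,
                           gapStart = gt$gap_start), cv, palette)
    if (spec@blurSigmaPx > 0)
      cv <- EBImage::imageData(EBImage::gblur(cv, sigma = spec@blurSigmaPx))
    if (spec@noiseSd > 0)
      cv <- cv + matrix(rnorm(windowPx^2, 0, spec@noiseSd), windowPx, windowPx)
    list(image = clamp01(cv), groundTruth = gt)
  })
}

#' Build a training set of positive and negative samples
#'
#' Positives are window-sized patches each containing exactly one stoma
#' centered to within 1 px, drawn with the spec's geometry and completeness
#' mix. Negatives are stoma-free images (background texture, veins and dust)
#' from which the cascade trainer mines windows. The defaults of 550
#' positives and 210 negatives mirror the sample sizes a detector of this
#' design is typically trained with.
#'
#' @param spec a \code{\link{SceneSpec}}; its seed drives all draws.
#' @param nPos,nNeg numbers of positive patches and negative images.
#' @param windowPx side of the square positive patches.
#' @param negSizePx side of the square negative images.
#' @param palette rendering constants.
#' @return A list with \code{positives} (list of matrices),
#'   \code{positiveTruth} (data frame, one row per positive, coordinates
#'   relative to the patch), and \code{negatives} (list of matrices).
#' @examples
#' ts <- makeTrainingSet(SceneSpec(seed = 11L), nPos = 2, nNeg = 1)
#' length(ts$positives)
#' @export
makeTrainingSet <- function(spec, nPos = 550L, nNeg = 210L, windowPx = 96L,
                            negSizePx = 192L, palette = stomaPalette()) {
  stopifnot(nPos > 0, nNeg > 0)
  positives <- vector("list", nPos)
  truths <- vector("list", nPos)
  for (i in seq_len(nPos)) {
    p <- renderPositivePatch(childSeed(spec@seed, i), spec, windowPx, palette)
    positives[[i]] <- p$image
    truths[[i]] <- p$groundTruth
  }
  negSpec <- spec
  negSpec@widthPx <- as.integer(negSizePx)
  negSpec@heightPx <- as.integer(negSizePx)
  negSpec@nStomata <- 0L
  negSpec@nVeins <- 2L
  negSpec@nDust <- 8L
  negatives <- vector("list", nNeg)
  for (i in seq_len(nNeg)) {
    negSpec@seed <- as.integer(childSeed(spec@seed, 100000L + i))
    negatives[[i]] <- renderScene(negSpec, palette)$image
  }
  posTruth <- do.call(rbind, truths)
  posTruth$stoma_id <- seq_len(nPos)
  list(positives = positives, positiveTruth = posTruth, negatives = negatives)
}

#' Write a micrograph as an 8-bit grayscale PNG
#'
#' @param image numeric matrix in [0, 1], indexed [row, col].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeScenePNG <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(clamp01(image))), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' Read a micrograph image
#'
#' Reads PNG/TIFF (color images are converted to luminance) and returns a
#' numeric matrix in [0, 1] indexed [row, col].
#'
#' @param path image file path.
#' @return Numeric matrix.
#' @export
readMicrograph <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3) {
    a <- aperm(EBImage::imageData(img), c(2, 1, 3))
    toGray(a)
  } else {
    t(EBImage::imageData(img))
  }
}

#' Write / read ground-truth stomata tables
#'
#' CSV with columns \code{scene_id}, \code{stoma_id}, \code{row}, \code{col},
#' \code{semi_major_px}, \code{semi_minor_px}, \code{orientation_deg},
#' \code{completeness}. Coordinates are 0-based (row, col) pixel positions,
#' stated in the file header.
#'
#' @param gt ground-truth data frame from \code{\link{renderScene}}.
#' @param path CSV path.
#' @param sceneId scene identifier stored in the \code{scene_id} column.
#' @return \code{writeGroundTruth}: the path, invisibly;
#'   \code{readGroundTruth}: the data frame.
#' @export
writeGroundTruth <- function(gt, path, sceneId = "scene1") {
  out <- data.frame(scene_id = rep(sceneId, nrow(gt)),
                    gt[, c("stoma_id", "row", "col", "semi_major_px",
                           "semi_minor_px", "orientation_deg", "completeness")])
  con <- file(path, "w")
  writeLines("# coordinates: 0-based (row, col) pixel positions", con)
  write.csv(out, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  read.csv(path, comment.char = "#")
}
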