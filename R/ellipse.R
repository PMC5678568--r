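# Direct least-squares ellipse fitting (numerically stable formulation)
# and the boundary-completeness confidence gate.

ellipseFitError <- function(msg) {
  stop(structure(class = c("ellipseFitError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Fit an ellipse to a point set by direct least squares
#'
#' Fits the conic \eqn{ax^2 + bxy + cy^2 + dx + ey + f = 0} minimizing the
#' algebraic distance subject to the ellipse constraint
#' \eqn{4ac - b^2 = 1}, using the numerically stable block decomposition of
#' the classical direct least-squares formulation. The fit is
#' ellipse-specific by construction: degenerate inputs (fewer than 5 points,
#' collinear points, or a best-fit conic that is not an ellipse) raise an
#' error of class \code{ellipseFitError} rather than returning garbage.
#'
#' When \code{minArcFraction > 0}, the fit is additionally rejected unless
#' the input points cover at least that fraction of the fitted ellipse's
#' perimeter (each of 360 equally spaced perimeter points is "covered" when
#' an input point lies within \code{coverageTolPx}). This is the confidence
#' gate for partially visible pore boundaries: with the default engine
#' setting of 0.6, remnants covering less than ~60\% of the boundary are
#' discarded.
#'
#' @param points n x 2 matrix of (row, col) coordinates, n >= 5.
#' @param minArcFraction minimum perimeter coverage in [0, 1); 0 disables
#'   the gate.
#' @param coverageTolPx distance within which a perimeter sample counts as
#'   covered.
#' @return List with \code{center} (0-based (row, col)), \code{semiMajor},
#'   \code{semiMinor} (px), \code{orientationDeg} (major-axis angle from the
#'   column axis, in degrees), and \code{coverage} (perimeter fraction
#'   covered by the input points).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' pts <- cbind(10 + 15 * sin(th), 20 + 30 * cos(th))
#' fitEllipse(pts)[c("semiMajor", "semiMinor")]
#' @export
fitEllipse <- function(points, minArcFraction = 0, coverageTolPx = 2.5) {
  points <- as.matrix(points)
  if (nrow(points) < 5)
    ellipseFitError("ellipse fit needs at least 5 points")
  # x = col, y = row; center the data for conditioning
  mx <- mean(points[, 2]); my <- mean(points[, 1])
  x <- points[, 2] - mx; y <- points[, 1] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    ellipseFitError("degenerate point configuration"))
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  ev <- Re(eg$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  ok <- which(cond > 0 & abs(Im(eg$values)) < 1e-8)
  if (!length(ok))
    ellipseFitError("best-fit conic is not an ellipse")
  a1 <- ev[, ok[1]]
  conic <- c(a1, as.vector(T1 %*% a1))  # A B C D E F on centered coords
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5]; F <- conic[6]
  det0 <- 4 * A * C - B^2
  if (det0 <= 0) ellipseFitError("best-fit conic is not an ellipse")
  cx <- (B * E - 2 * C * D) / det0
  cy <- (B * D - 2 * A * E) / det0
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values  # ascending? eigen returns decreasing
  if (any(lam * (-Fc) <= 0))
    ellipseFitError("best-fit conic is not an ellipse")
  ax <- sqrt(-Fc / lam)  # semi-axes; larger value from smaller eigenvalue
  iMaj <- which.max(ax)
  semiMajor <- ax[iMaj]; semiMinor <- min(ax)
  vMaj <- eq$vectors[, iMaj]  # (x, y) components
  orientationDeg <- (atan2(vMaj[2], vMaj[1]) * 180 / pi) %% 180
  out <- list(center = c(row = cy + my, col = cx + mx),
              semiMajor = semiMajor, semiMinor = semiMinor,
              orientationDeg = orientationDeg)
  out$coverage <- ellipseCoverage(points, out, tol = coverageTolPx)
  if (minArcFraction > 0 && out$coverage < minArcFraction)
    ellipseFitError(sprintf(
      "boundary remnant covers only %.0f%% of the fitted ellipse (< %.0f%% required)",
      100 * out$coverage, 100 * minArcFraction))
  out
}

# Fraction of the fitted ellipse's perimeter (arc length) lying within `tol`
# of an input point; measures boundary completeness.
ellipseCoverage <- function(points, ell, tol = 2.5, nSamples = 360L) {
  tab <- arcLengthTable(ell$semiMajor, ell$semiMinor)
  # arc-length-uniform parametric angles
  target <- seq(0, 1, length.out = nSamples + 1L)[-(nSamples + 1L)]
  phi <- approx(tab$frac, tab$phi, target, rule = 2, ties = "ordered")$y
  th <- ell$orientationDeg * pi / 180
  ex <- ell$semiMajor * cos(phi); ey <- ell$semiMinor * sin(phi)
  sx <- ell$center["col"] + ex * cos(th) - ey * sin(th)
  sy <- ell$center["row"] + ex * sin(th) + ey * cos(th)
  covered <- vapply(seq_len(nSamples), function(i) {
    min((points[, 1] - sy[i])^2 + (points[, 2] - sx[i])^2) <= tol^2
  }, logical(1))
  mean(covered)
}

#' Points on an ellipse
#'
#' Samples points on an ellipse arc, uniformly in arc length. Used to build
#' test geometries and overlay traces.
#'
#' @param center (row, col) center.
#' @param semiMajor,semiMinor semi-axis lengths.
#' @param orientationDeg major-axis angle from the column axis (degrees).
#' @param n number of points.
#' @param arcFraction fraction of the perimeter to cover, starting at
#'   \code{startFraction}.
#' @param startFraction perimeter fraction at which the arc starts.
#' @return n x 2 matrix of (row, col) coordinates.
#' @export
ellipseArcPoints <- function(center, semiMajor, semiMinor, orientationDeg = 0,
                             n = 100L, arcFraction = 1, startFraction = 0) {
  tab <- arcLengthTable(semiMajor, semiMinor)
  target <- (startFraction + seq(0, arcFraction, length.out = n)) %% 1
  phi <- approx(tab$frac, tab$phi, target, rule = 2, ties = "ordered")$y
  th <- orientationDeg * pi / 180
  ex <- semiMajor * cos(phi); ey <- semiMinor * sin(phi)
  cbind(row = center[1] + ex * sin(th) + ey * cos(th),
        col = center[2] + ex * cos(th) - ey * sin(th))
}
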