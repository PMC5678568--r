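# Binary segmentation path: threshold, label, select, measure.

#' Binarize a stoma ROI
#'
#' Applies unsharp-mask sharpening, converts color images to luminance, and
#' thresholds with Otsu's method. Foreground is the bright phase (pore
#' interior and background plateaus); dark structures -- pore boundaries,
#' veins, dust -- become background. A complete pore boundary therefore
#' encloses the pore interior as an independent foreground region, while a
#' boundary gap merges the interior with the surrounding background; the
#' skeletonization path inverts this binary to recover the dark boundary
#' structures themselves. A (near-)constant ROI yields an all-background
#' binary.
#'
#' @param roi numeric matrix or RGB array, intensities in [0, 1].
#' @param config a \code{\link{PoreConfig}}.
#' @return Logical matrix; TRUE = foreground (bright phase).
#' @export
binarizeROI <- function(roi, config = PoreConfig()) {
  img <- toGray(roi)
  if (config@sharpenAmount > 0) {
    blur <- EBImage::imageData(EBImage::gblur(img, sigma = config@sharpenSigma))
    img <- clamp01(img + config@sharpenAmount * (img - blur))
  }
  if (diff(range(img)) < 1e-6)
    return(matrix(FALSE, nrow(img), ncol(img)))
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  img > thr
}

#' Connected foreground regions of a binary image
#'
#' Connected-component labeling under the configured connectivity. Each
#' region carries its pixel coordinates, area, centroid and second central
#' moments (population covariance of the pixel coordinates plus the 1/12
#' pixel-square term, i.e. the moments of the union of unit squares).
#'
#' @param binary logical matrix.
#' @param connectivity 4 or 8.
#' @return List of regions, each a list with \code{coords} (n x 2 matrix of
#'   0-based (row, col)), \code{area}, \code{centroid} (0-based (row, col)),
#'   and \code{cov} (2 x 2 second central moment matrix).
#' @examples
#' b <- matrix(FALSE, 5, 5); b[2:3, 2:3] <- TRUE
#' findRegions(b)[[1]]$area
#' @export
findRegions <- function(binary, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  if (!any(binary)) return(list())
  lab <- cpp_label(binary, as.integer(connectivity))
  idx <- which(lab > 0)
  n <- max(lab)
  rows <- (idx - 1L) %% nrow(lab)
  cols <- (idx - 1L) %/% nrow(lab)
  lapply(seq_len(n), function(k) {
    sel <- lab[idx] == k
    coords <- cbind(row = rows[sel], col = cols[sel])
    regionFromCoords(coords)
  })
}

regionFromCoords <- function(coords) {
  n <- nrow(coords)
  ctr <- colMeans(coords)
  cv <- if (n > 1) cov(coords) * (n - 1) / n else matrix(0, 2, 2)
  cv <- cv + diag(1 / 12, 2)
  list(coords = coords, area = n, centroid = ctr, cov = cv)
}

#' Select the candidate pore region
#'
#' Implements the two selection assumptions of the segmentation path: the
#' pore is (a) close to the ROI center and (b) smaller than a predefined
#' area upper limit. Among regions whose area lies within
#' \code{[areaMinPx, areaMaxPx]} (the lower bound is a noise floor) and
#' whose centroid lies within \code{maxCenterDistFrac} of the smaller ROI
#' dimension from the center (assumption (a) is a requirement, not just a
#' ranking: a lone bright fragment in an ROI corner is not the pore), the
#' region nearest \code{roiCenter} is returned; the area filter precedes
#' the distance ranking. \code{NULL} when no region qualifies -- the ROI is
#' then handed to the skeletonization path.
#'
#' @param regions list from \code{\link{findRegions}}.
#' @param roiCenter 0-based (row, col) of the ROI center.
#' @param config a \code{\link{PoreConfig}}; an \code{NA} area limit
#'   resolves to 20\% of the ROI area, which requires \code{roiDim}.
#' @param roiDim ROI dimensions c(rows, cols), used to resolve the default
#'   area limit and the centrality cap; without it the cap is not applied.
#' @return A region, or \code{NULL}.
#' @export
selectPoreRegion <- function(regions, roiCenter, config = PoreConfig(),
                             roiDim = NULL) {
  areaMax <- config@areaMaxPx
  if (is.na(areaMax)) {
    if (is.null(roiDim))
      stop("roiDim is required to resolve the default area limit")
    areaMax <- 0.2 * prod(roiDim)
  }
  distCap <- if (is.null(roiDim)) Inf else
    config@maxCenterDistFrac * min(roiDim)
  ok <- vapply(regions, function(r)
    r$area <= areaMax && r$area >= config@areaMinPx &&
      sqrt(sum((r$centroid - roiCenter)^2)) <= distCap, logical(1))
  if (!any(ok)) return(NULL)
  cand <- regions[ok]
  d <- vapply(cand, function(r)
    sqrt(sum((r$centroid - roiCenter)^2)), numeric(1))
  cand[[which.min(d)]]
}

#' Semi-axis lengths from area and eccentricity
#'
#' For an ellipse of area \eqn{A} and eccentricity \eqn{E}, the semi-axis
#' lengths are
#' \deqn{a = \sqrt{A / (\pi \sqrt{1 - E^2})}, \qquad
#'       b = \sqrt{A \sqrt{1 - E^2} / \pi},}
#' which satisfy \eqn{\pi a b = A} and \eqn{b/a = \sqrt{1 - E^2}} exactly.
#'
#' @param A area (px^2 or any squared unit), > 0.
#' @param E eccentricity in [0, 1).
#' @return Named numeric vector \code{c(a, b)} in the unit of
#'   \code{sqrt(A)}.
#' @examples
#' axesFromAreaEcc(pi, 0)            # unit circle: a = b = 1
#' axesFromAreaEcc(pi, sqrt(3) / 2)  # a = sqrt(2), b = 1/sqrt(2)
#' @export
axesFromAreaEcc <- function(A, E) {
  if (any(A <= 0)) stop("area must be positive")
  if (any(E < 0 | E >= 1)) stop("eccentricity must lie in [0, 1)")
  s <- sqrt(1 - E^2)
  c(a = sqrt(A / (pi * s)), b = sqrt(A * s / pi))
}

# Outline pixels of a region: coords with fewer than 4 of their 4-neighbors
# inside the region.
regionBoundary <- function(coords) {
  key <- coords[, 1] * 2^26 + coords[, 2]
  inside <- rep(TRUE, nrow(coords))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nk <- (coords[, 1] + d[1]) * 2^26 + (coords[, 2] + d[2])
    inside <- inside & (nk %in% key)
  }
  coords[!inside, , drop = FALSE]
}

#' Measure a region's pore morphology
#'
#' The area is the pixel count (converted to um^2 through the pixel scale);
#' the eccentricity comes from the region's second-central-moment equivalent
#' ellipse (a single-pixel region has eccentricity 0); the semi-axis lengths
#' are then recomputed from (area, eccentricity) via
#' \code{\link{axesFromAreaEcc}} so that the record's algebraic identities
#' hold to machine precision.
#'
#' @param region a region from \code{\link{findRegions}}.
#' @param pixelScale pixels per micrometer (default 8.6).
#' @param method path tag stored in the record.
#' @return A \code{\link{PoreMeasurement-class}} with
#'   \code{status = "measured"}.
#' @export
measureRegion <- function(region, pixelScale = 8.6, method = "segmentation") {
  A <- region$area
  ev <- sort(eigen(region$cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  E <- if (A <= 1 || ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  E <- min(E, 1 - 1e-12)
  ax <- axesFromAreaEcc(A, E)
  newMeasured(method, areaPx2 = A, areaUm2 = A / pixelScale^2,
              a = unname(ax["a"]), b = unname(ax["b"]), E = E,
              boundary = regionBoundary(region$coords))
}
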