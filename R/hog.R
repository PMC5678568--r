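#' Length of the HOG descriptor
#'
#' @param params a \code{\link{HOGParams}} object.
#' @return Integer descriptor length:
#'   \code{nBlocks^2 * blockCells^2 * nOrientationBins} with
#'   \code{nBlocks = windowPx/cellPx - blockCells + 1}.
#' @export
hogFeatureLength <- function(params) {
  wc <- params@windowPx %/% params@cellPx
  nb <- wc - params@blockCells + 1L
  as.integer(prod(nb) * params@blockCells^2 * params@nOrientationBins)
}

#' Compute the HOG descriptor of a window-sized patch
#'
#' Gradients are central differences with edge replication; unsigned
#' orientations in [0, 180) degrees are hard-binned into
#' \code{nOrientationBins} bins per cell, weighted by gradient magnitude.
#' Overlapping blocks of \code{blockCells^2} cells are L2-normalized:
#' \code{v / sqrt(sum(v^2) + eps^2)}. Feature order: blocks row-major, cells
#' within a block row-major, then bins.
#'
#' @param patch numeric matrix whose dimensions equal \code{params@windowPx}.
#' @param params a \code{\link{HOGParams}} object.
#' @return Non-negative numeric vector of length
#'   \code{\link{hogFeatureLength}(params)}. A constant-intensity patch maps
#'   to the zero vector.
#' @examples
#' p <- HOGParams(windowPx = 32L)
#' v <- computeHOG(matrix(runif(32 * 32), 32), p)
#' length(v) == hogFeatureLength(p)
#' @export
computeHOG <- function(patch, params = HOGParams()) {
  if (!is.matrix(patch) || nrow(patch) != params@windowPx[1] ||
      ncol(patch) != params@windowPx[2])
    stop(sprintf("patch must be %d x %d", params@windowPx[1],
                 params@windowPx[2]))
  cpp_hog(patch, params@cellPx, params@blockCells, params@nOrientationBins,
          params@normalizationEpsilon)
}
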