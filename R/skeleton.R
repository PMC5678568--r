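# Skeletonization path: thinning, spur pruning, remnant selection.

#' Skeletonize the foreground of a binary image
#'
#' Zhang-Suen homotopy-preserving thinning reduces each connected foreground
#' component to a 1-px-wide skeletal remnant (its medial axis); a 1-px-wide
#' open curve is its own skeleton. Branches shorter than \code{spurLengthPx}
#' are pruned afterwards (thinning artifacts at corners and ragged edges).
#' The caller is responsible for any inversion: the pore-measurement engine
#' inverts the segmentation binary so that the dark boundary structures are
#' the foreground being thinned.
#'
#' @param binary logical matrix; TRUE = foreground to thin.
#' @param connectivity connectivity used to split remnants (4 or 8).
#' @param spurLengthPx branches shorter than this are removed.
#' @return List of skeletons, each a list with \code{coords} (n x 2, 0-based
#'   (row, col)), \code{length} (pixel count) and \code{centroid}.
#' @examples
#' b <- matrix(FALSE, 9, 9); b[3:7, 2:8] <- TRUE
#' sk <- skeletonizeRegions(b)
#' sk[[1]]$length
#' @export
skeletonizeRegions <- function(binary, connectivity = 8L, spurLengthPx = 5L) {
  if (!any(binary)) return(list())
  thin <- cpp_thin(matrix(as.integer(binary), nrow(binary)))
  lab <- cpp_label(thin > 0, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab)
  cols <- (idx - 1L) %/% nrow(lab)
  out <- list()
  for (k in seq_len(n)) {
    sel <- lab[idx] == k
    coords <- cbind(row = rows[sel], col = cols[sel])
    coords <- pruneSpurs(coords, maxLen = spurLengthPx)
    if (!nrow(coords)) next
    out[[length(out) + 1]] <- list(coords = coords, length = nrow(coords),
                                   centroid = colMeans(coords))
  }
  out
}

# 8-neighbor adjacency helpers on a coordinate set.
skelDegrees <- function(coords) {
  key <- coords[, 1] * 2^26 + coords[, 2]
  deg <- integer(nrow(coords))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nk <- (coords[, 1] + dr) * 2^26 + (coords[, 2] + dc)
    deg <- deg + (nk %in% key)
  }
  deg
}

#' Prune short skeleton spurs
#'
#' Walks inward from each endpoint (pixel with a single skeleton neighbor);
#' if a branch point (3 or more neighbors) is reached within \code{maxLen}
#' pixels, the walked branch is removed. Repeats until stable, so nested
#' short spurs disappear. Open curves without branch points are untouched.
#'
#' @param coords n x 2 matrix of skeleton pixel coordinates.
#' @param maxLen branches strictly shorter than this many pixels are pruned.
#' @return The pruned coordinate matrix.
#' @export
pruneSpurs <- function(coords, maxLen = 5L) {
  adjacent <- function(i, j) {
    abs(coords[i, 1] - coords[j, 1]) <= 1 & abs(coords[i, 2] - coords[j, 2]) <= 1
  }
  connectedSet <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    seen <- c(idx[1]); queue <- idx[1]
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nxt <- idx[!(idx %in% seen) & adjacent(idx, cur)]
      seen <- c(seen, nxt); queue <- c(queue, nxt)
    }
    length(seen) == length(idx)
  }
  repeat {
    if (nrow(coords) < 3) return(coords)
    deg <- skelDegrees(coords)
    if (!any(deg >= 3)) return(coords)  # no branch points: nothing to prune
    ends <- which(deg == 1)
    if (!length(ends)) return(coords)
    drop <- logical(nrow(coords))
    for (e in ends) {
      chain <- integer(0)
      cur <- e
      branchAt <- NA_integer_
      while (length(chain) < maxLen) {
        chain <- c(chain, cur)
        nb <- which(adjacent(seq_len(nrow(coords)), cur))
        nb <- setdiff(nb, chain)
        nb <- nb[!drop[nb]]
        if (!length(nb)) break
        if (any(deg[nb] >= 3)) { branchAt <- nb[deg[nb] >= 3][1]; break }
        if (length(nb) > 1) break
        cur <- nb
      }
      if (!is.na(branchAt) && length(chain) < maxLen) {
        drop[chain] <- TRUE
        # drop the junction pixel too when its other neighbors remain a
        # connected piece without it (a 1-px nub left by thinning)
        others <- which(adjacent(seq_len(nrow(coords)), branchAt) & !drop)
        others <- setdiff(others, branchAt)
        if (length(others) >= 2 && connectedSet(others))
          drop[branchAt] <- TRUE
      }
    }
    if (!any(drop)) return(coords)
    coords <- coords[!drop, , drop = FALSE]
  }
}

#' Select the skeletal remnant of the pore boundary
#'
#' Among skeletons whose length lies within the configured bounds and whose
#' pixel centroid lies within \code{maxCenterDistFrac} of the smaller ROI
#' dimension from the center (when \code{roiDim} is given), returns the one
#' nearest the ROI center; \code{NULL} when none qualifies.
#'
#' @param skeletons list from \code{\link{skeletonizeRegions}}.
#' @param roiCenter 0-based (row, col) ROI center.
#' @param config a \code{\link{PoreConfig}} (uses
#'   \code{skeletonLengthBounds} and \code{maxCenterDistFrac}).
#' @param roiDim ROI dimensions c(rows, cols); without it the centrality
#'   cap is not applied.
#' @return A skeleton, or \code{NULL}.
#' @export
selectSkeleton <- function(skeletons, roiCenter, config = PoreConfig(),
                           roiDim = NULL) {
  b <- config@skeletonLengthBounds
  distCap <- if (is.null(roiDim)) Inf else
    config@maxCenterDistFrac * min(roiDim)
  ok <- vapply(skeletons, function(s)
    s$length >= b[1] && s$length <= b[2] &&
      sqrt(sum((s$centroid - roiCenter)^2)) <= distCap, logical(1))
  if (!any(ok)) return(NULL)
  cand <- skeletons[ok]
  d <- vapply(cand, function(s)
    sqrt(sum((s$centroid - roiCenter)^2)), numeric(1))
  cand[[which.min(d)]]
}
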