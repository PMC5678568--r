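# The two-path pore measurement engine.

#' Measure the pore inside a fitted ellipse mask
#'
#' Restricts the segmentation binary (bright-phase foreground) to the
#' interior of the fitted ellipse and identifies the pore as the largest
#' foreground region lying fully inside the mask (regions touching the ROI
#' edge are cut off and excluded; ties are broken by proximity to the
#' ellipse center). The region is then measured like any segmentation-path
#' region.
#'
#' @param ellipse fit from \code{\link{fitEllipse}}.
#' @param binary logical matrix from \code{\link{binarizeROI}}.
#' @param pixelScale pixels per micrometer.
#' @param config a \code{\link{PoreConfig}}.
#' @return A \code{\link{PoreMeasurement-class}}; discarded (reason
#'   \code{"empty_mask"}) when no region lies inside the mask.
#' @export
maskAndMeasure <- function(ellipse, binary, pixelScale = 8.6,
                           config = PoreConfig()) {
  nr <- nrow(binary); nc <- ncol(binary)
  rows <- matrix(seq_len(nr) - 1, nr, nc)
  cols <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  th <- ellipse$orientationDeg * pi / 180
  dy <- rows - ellipse$center["row"]; dx <- cols - ellipse$center["col"]
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  mask <- (xr / ellipse$semiMajor)^2 + (yr / ellipse$semiMinor)^2 <= 1
  if (!any(mask & binary)) return(newDiscarded("empty_mask", "skeleton"))
  regions <- findRegions(binary & mask, config@connectivity)
  touchesEdge <- vapply(regions, function(r)
    any(r$coords[, 1] %in% c(0, nr - 1) | r$coords[, 2] %in% c(0, nc - 1)),
    logical(1))
  regions <- regions[!touchesEdge]
  regions <- regions[vapply(regions, function(r)
    r$area >= config@areaMinPx, logical(1))]
  if (!length(regions)) return(newDiscarded("empty_mask", "skeleton"))
  areas <- vapply(regions, function(r) r$area, numeric(1))
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    ctr <- c(ellipse$center["row"], ellipse$center["col"])
    d <- vapply(regions[best], function(r)
      sqrt(sum((r$centroid - ctr)^2)), numeric(1))
    best <- best[which.min(d)]
  }
  measureRegion(regions[[best]], pixelScale, method = "skeleton")
}

#' Measure the stomatal pore in a cropped ROI
#'
#' The start-to-end measurement for one region of interest. The ROI is
#' binarized (\code{\link{binarizeROI}}) and first fed to the segmentation
#' path: among the binary's connected regions, the pore is the one near the
#' ROI center with area inside the configured window
#' (\code{\link{selectPoreRegion}}). This succeeds for stomata with complete
#' pore boundaries, where the boundary ring encloses the interior as an
#' independent region. When no region qualifies -- typically because a
#' boundary gap merged the interior with the background -- the ROI is handed
#' to the skeletonization path: the binary is inverted so the dark boundary
#' structures become foreground, each structure is thinned to its skeletal
#' remnant, the remnant near the center with admissible length is selected,
#' an ellipse is fitted to its pixels (with the boundary-completeness
#' confidence gate), and the pore is measured inside the ellipse mask
#' (\code{\link{maskAndMeasure}}). All failures fold into a discarded record
#' with a reason code.
#'
#' @param roi numeric matrix or RGB array (intensities in [0, 1]).
#' @param config a \code{\link{PoreConfig}}.
#' @param pixelScale pixels per micrometer (default 8.6).
#' @return A \code{\link{PoreMeasurement-class}}. \code{measurementMethod}
#'   records the successful path ("segmentation" or "skeleton").
#' @examples
#' ts <- makeTrainingSet(SceneSpec(seed = 5L), nPos = 1, nNeg = 1)
#' measurePore(ts$positives[[1]])
#' @export
measurePore <- function(roi, config = PoreConfig(), pixelScale = 8.6) {
  roi <- toGray(roi)
  bin <- binarizeROI(roi, config)
  roiCenter <- (dim(roi) - 1) / 2
  if (any(bin)) {
    regions <- findRegions(bin, config@connectivity)
    sel <- selectPoreRegion(regions, roiCenter, config, roiDim = dim(roi))
    if (!is.null(sel))
      return(measureRegion(sel, pixelScale, method = "segmentation"))
  } else {
    return(newDiscarded("blank_roi"))
  }
  # skeletonization path on the inverted binary (dark structures)
  skels <- skeletonizeRegions(!bin, config@connectivity)
  ssel <- selectSkeleton(skels, roiCenter, config, roiDim = dim(roi))
  if (is.null(ssel)) return(newDiscarded("no_skeleton_in_bounds", "skeleton"))
  fit <- tryCatch(
    fitEllipse(ssel$coords, minArcFraction = config@minCompleteness),
    ellipseFitError = function(e) e)
  if (inherits(fit, "error"))
    return(newDiscarded(paste0("ellipse_fit: ", conditionMessage(fit)),
                        "skeleton"))
  maskAndMeasure(fit, bin, pixelScale, config)
}
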