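#' @useDynLib stomataMorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cov rnorm runif approx quantile
#' @importFrom utils read.csv write.csv head
NULL

#' Scene specification for the synthetic micrograph generator
#'
#' A \code{SceneSpec} fixes every parameter of a synthetic leaf-epidermis
#' micrograph: canvas size, number and geometry of stomata, boundary
#' completeness mix, distractor density (veins, dust), optical degradation
#' (blur, noise) and the master seed. Identical specs render byte-identical
#' scenes.
#'
#' Pore geometry is an ellipse with semi-axes drawn uniformly from
#' \code{poreSemiAxisRange} (semi-major, px) and an aspect ratio
#' (semi-minor/semi-major) from \code{aspectRange}. A fraction
#' \code{pComplete} of stomata are rendered with a fully closed pore
#' boundary; the rest get a single contiguous boundary gap so that the
#' rendered fraction of the boundary's arc length equals a completeness
#' value drawn from \code{completenessRange}.
#'
#' @slot widthPx,heightPx canvas size in pixels.
#' @slot nStomata number of stomata to place.
#' @slot poreSemiAxisRange length-2 numeric, semi-major axis range in px.
#' @slot aspectRange length-2 numeric in (0, 1], semi-minor/semi-major ratio.
#' @slot completenessRange length-2 numeric in (0, 1], boundary completeness
#'   of the incomplete stomata.
#' @slot pComplete fraction of stomata with a fully closed boundary.
#' @slot nVeins,nDust numbers of vein-like curvilinear distractors and dust
#'   blobs.
#' @slot blurSigmaPx Gaussian blur sigma in px.
#' @slot noiseSd additive Gaussian noise standard deviation (intensity units,
#'   image range is [0, 1]).
#' @slot minSeparationPx minimum pairwise distance between stoma centers.
#' @slot seed integer master seed; all stochastic draws flow from it.
#' @name SceneSpec-class
#' @aliases SceneSpec-class
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    widthPx = "integer", heightPx = "integer", nStomata = "integer",
    poreSemiAxisRange = "numeric", aspectRange = "numeric",
    completenessRange = "numeric", pComplete = "numeric",
    nVeins = "integer", nDust = "integer",
    blurSigmaPx = "numeric", noiseSd = "numeric",
    minSeparationPx = "numeric", seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  rng2 <- function(x, nm, lo = -Inf, hi = Inf) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
      return(sprintf("%s must be a finite (min, max) pair with min <= max", nm))
    if (x[1] < lo || x[2] > hi)
      return(sprintf("%s must lie within (%s, %s]", nm, lo, hi))
    NULL
  }
  msg <- c(msg, rng2(object@poreSemiAxisRange, "poreSemiAxisRange"))
  msg <- c(msg, rng2(object@aspectRange, "aspectRange"))
  msg <- c(msg, rng2(object@completenessRange, "completenessRange"))
  if (length(object@completenessRange) == 2 &&
      (object@completenessRange[1] <= 0 || object@completenessRange[2] > 1))
    msg <- c(msg, "completenessRange must lie in (0, 1]")
  if (length(object@aspectRange) == 2 &&
      (object@aspectRange[1] <= 0 || object@aspectRange[2] > 1))
    msg <- c(msg, "aspectRange must lie in (0, 1]")
  if (object@widthPx < 32L || object@heightPx < 32L)
    msg <- c(msg, "canvas must be at least 32 x 32 px")
  if (object@nStomata < 0L) msg <- c(msg, "nStomata must be non-negative")
  if (object@pComplete < 0 || object@pComplete > 1)
    msg <- c(msg, "pComplete must lie in [0, 1]")
  if (object@blurSigmaPx < 0) msg <- c(msg, "blurSigmaPx must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@minSeparationPx <= 0) msg <- c(msg, "minSeparationPx must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' Defaults describe the desk-scale study scene: a 768 x 768 px canvas with 8
#' stomata of semi-major axis 14--24 px, a 60/40 mix of complete and
#' incomplete (completeness 0.65--0.9) pore boundaries, vein and dust
#' distractors, mild blur and additive noise.
#'
#' @param widthPx,heightPx canvas size in px.
#' @param nStomata number of stomata.
#' @param poreSemiAxisRange semi-major axis range (px).
#' @param aspectRange semi-minor/semi-major ratio range.
#' @param completenessRange completeness range of incomplete stomata.
#' @param pComplete fraction of stomata with closed boundaries.
#' @param nVeins,nDust distractor counts.
#' @param blurSigmaPx Gaussian blur sigma (px).
#' @param noiseSd additive noise sd (intensity units).
#' @param minSeparationPx minimum stoma center separation (px).
#' @param seed integer master seed.
#' @return A \code{SceneSpec} object.
#' @examples
#' spec <- SceneSpec(nStomata = 2L, seed = 7L)
#' spec
#' @export
SceneSpec <- function(widthPx = 768L, heightPx = 768L, nStomata = 8L,
                      poreSemiAxisRange = c(14, 24),
                      aspectRange = c(0.45, 0.8),
                      completenessRange = c(0.65, 0.9), pComplete = 0.6,
                      nVeins = 6L, nDust = 40L, blurSigmaPx = 0.8,
                      noiseSd = 0.02, minSeparationPx = 110, seed = 1L) {
  new("SceneSpec",
    widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
    nStomata = as.integer(nStomata),
    poreSemiAxisRange = as.numeric(poreSemiAxisRange),
    aspectRange = as.numeric(aspectRange),
    completenessRange = as.numeric(completenessRange),
    pComplete = as.numeric(pComplete),
    nVeins = as.integer(nVeins), nDust = as.integer(nDust),
    blurSigmaPx = as.numeric(blurSigmaPx), noiseSd = as.numeric(noiseSd),
    minSeparationPx = as.numeric(minSeparationPx), seed = as.integer(seed)
  )
}

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", object@widthPx, "x", object@heightPx, "px,",
      object@nStomata, "stomata\n")
  cat("  pore semi-major", object@poreSemiAxisRange[1], "-",
      object@poreSemiAxisRange[2], "px, aspect",
      object@aspectRange[1], "-", object@aspectRange[2], "\n")
  cat("  completeness mix:", round(100 * object@pComplete), "% closed, rest in [",
      object@completenessRange[1], ",", object@completenessRange[2], "]\n")
  cat("  distractors:", object@nVeins, "veins,", object@nDust, "dust; blur",
      object@blurSigmaPx, "px, noise sd", object@noiseSd, "\n")
  cat("  seed:", object@seed, "\n")
})

#' HOG descriptor parameters
#'
#' Parameters of the histogram-of-oriented-gradients descriptor used by the
#' cascade detector: a square detection window partitioned into square cells,
#' unsigned gradient orientations accumulated into \code{nOrientationBins}
#' histogram bins per cell, and overlapping blocks of
#' \code{blockCells} x \code{blockCells} cells that are L2-normalized with
#' \code{normalizationEpsilon} guarding the division.
#'
#' @slot windowPx length-2 integer (height, width); must be square and
#'   divisible by \code{cellPx}.
#' @slot cellPx cell side in px.
#' @slot blockCells block side in cells.
#' @slot nOrientationBins orientation bins over [0, 180) degrees.
#' @slot normalizationEpsilon small positive constant in the block norm.
#' @name HOGParams-class
#' @aliases HOGParams-class
#' @exportClass HOGParams
setClass("HOGParams",
  representation(windowPx = "integer", cellPx = "integer",
                 blockCells = "integer", nOrientationBins = "integer",
                 normalizationEpsilon = "numeric")
)

setValidity("HOGParams", function(object) {
  msg <- character()
  if (length(object@windowPx) != 2 || any(object@windowPx <= 0))
    msg <- c(msg, "windowPx must be two positive integers")
  if (length(object@windowPx) == 2 && object@windowPx[1] != object@windowPx[2])
    msg <- c(msg, "the detection window must be square")
  if (object@cellPx <= 0 || any(object@windowPx %% object@cellPx != 0))
    msg <- c(msg, "window dimensions must be divisible by cellPx")
  if (object@blockCells < 1 ||
      object@blockCells > min(object@windowPx %/% object@cellPx))
    msg <- c(msg, "blockCells must fit inside the window cell grid")
  if (object@nOrientationBins < 2)
    msg <- c(msg, "need at least 2 orientation bins")
  if (object@normalizationEpsilon <= 0)
    msg <- c(msg, "normalizationEpsilon must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct HOG parameters
#'
#' @param windowPx window side in px (square window).
#' @param cellPx cell side in px.
#' @param blockCells block side in cells.
#' @param nOrientationBins orientation bins over [0, 180).
#' @param normalizationEpsilon block-normalization guard.
#' @return A \code{HOGParams} object.
#' @examples
#' hogFeatureLength(HOGParams())
#' @export
HOGParams <- function(windowPx = 96L, cellPx = 8L, blockCells = 2L,
                      nOrientationBins = 9L, normalizationEpsilon = 1e-3) {
  if (length(windowPx) == 1) windowPx <- c(windowPx, windowPx)
  new("HOGParams", windowPx = as.integer(windowPx), cellPx = as.integer(cellPx),
      blockCells = as.integer(blockCells),
      nOrientationBins = as.integer(nOrientationBins),
      normalizationEpsilon = as.numeric(normalizationEpsilon))
}

setMethod("show", "HOGParams", function(object) {
  cat("HOGParams:", object@windowPx[1], "x", object@windowPx[2], "px window,",
      object@cellPx, "px cells,", object@blockCells, "x", object@blockCells,
      "cell blocks,", object@nOrientationBins, "orientation bins\n")
  cat("  descriptor length:", hogFeatureLength(object), "\n")
})

#' Trained cascade detector
#'
#' An ordered sequence of boosted stages over HOG features. Each stage is a
#' list with elements \code{learners} (matrix with columns \code{feature},
#' \code{threshold}, \code{polarity}, \code{weight}; one decision stump per
#' row) and \code{threshold} (the stage acceptance threshold on the weighted
#' stump vote). A window is accepted only if it passes every stage; most
#' windows are rejected by the first stages, which is what makes dense
#' sliding-window scanning affordable.
#'
#' @slot hog the \code{HOGParams} the stages were trained with.
#' @slot stages list of boosted stages, in evaluation order.
#' @name CascadeModel-class
#' @aliases CascadeModel-class
#' @exportClass CascadeModel
setClass("CascadeModel",
  representation(hog = "HOGParams", stages = "list"))

setValidity("CascadeModel", function(object) {
  msg <- character()
  for (i in seq_along(object@stages)) {
    st <- object@stages[[i]]
    if (!is.list(st) || is.null(st$learners) || is.null(st$threshold)) {
      msg <- c(msg, sprintf("stage %d lacks learners/threshold", i))
      next
    }
    L <- st$learners
    if (!is.matrix(L) || ncol(L) != 4 || nrow(L) < 1)
      msg <- c(msg, sprintf("stage %d must have a k x 4 learner matrix with k >= 1", i))
    else {
      if (any(L[, 4] < 0))
        msg <- c(msg, sprintf("stage %d has negative learner weights", i))
      if (any(L[, 1] < 1 | L[, 1] > hogFeatureLength(object@hog)))
        msg <- c(msg, sprintf("stage %d references features outside the descriptor", i))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CascadeModel-class number of stages.
#' @param object,x a \code{CascadeModel}.
#' @export
nStages <- function(x) length(x@stages)

setMethod("show", "CascadeModel", function(object) {
  nl <- vapply(object@stages, function(s) nrow(s$learners), integer(1))
  cat("CascadeModel with", length(object@stages), "boosted stages\n")
  cat("  weak learners per stage:", paste(nl, collapse = ", "), "\n")
  show(object@hog)
})

#' Pore measurement configuration
#'
#' Tunable parameters of the two-path pore measurement engine.
#'
#' @slot areaMaxPx upper pore-area limit in px^2; \code{NA} resolves at run
#'   time to 20\% of the ROI area.
#' @slot areaMinPx noise floor: candidate regions below this area are ignored.
#' @slot maxCenterDistFrac how close to the ROI center a candidate pore
#'   region (or skeletal remnant) must be: its centroid may lie at most this
#'   fraction of the smaller ROI dimension from the center.
#' @slot skeletonLengthBounds (Lmin, Lmax) admissible skeletal-remnant length
#'   in px.
#' @slot minCompleteness minimum fraction of the fitted ellipse's perimeter
#'   that the skeletal remnant must cover for the fit to be trusted
#'   (default 0.6: boundaries less than ~60\% complete are discarded).
#' @slot connectivity pixel connectivity for regions and skeletons (4 or 8).
#' @slot thresholdMethod automatic global threshold method ("otsu").
#' @slot sharpenAmount unsharp-mask strength applied before thresholding.
#' @slot sharpenSigma unsharp-mask Gaussian sigma in px.
#' @name PoreConfig-class
#' @aliases PoreConfig-class
#' @exportClass PoreConfig
setClass("PoreConfig",
  representation(areaMaxPx = "numeric", areaMinPx = "numeric",
                 maxCenterDistFrac = "numeric",
                 skeletonLengthBounds = "numeric", minCompleteness = "numeric",
                 connectivity = "integer", thresholdMethod = "character",
                 sharpenAmount = "numeric", sharpenSigma = "numeric"))

setValidity("PoreConfig", function(object) {
  msg <- character()
  if (!is.na(object@areaMaxPx) && object@areaMaxPx <= 0)
    msg <- c(msg, "areaMaxPx must be positive (or NA for 20% of ROI area)")
  if (object@areaMinPx < 0) msg <- c(msg, "areaMinPx must be >= 0")
  if (object@maxCenterDistFrac <= 0 || object@maxCenterDistFrac > 1)
    msg <- c(msg, "maxCenterDistFrac must lie in (0, 1]")
  b <- object@skeletonLengthBounds
  if (length(b) != 2 || b[1] >= b[2] || b[1] < 0)
    msg <- c(msg, "skeletonLengthBounds must be (Lmin, Lmax) with 0 <= Lmin < Lmax")
  if (object@minCompleteness <= 0 || object@minCompleteness >= 1)
    msg <- c(msg, "minCompleteness must lie in (0, 1)")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (!object@thresholdMethod %in% "otsu")
    msg <- c(msg, "thresholdMethod must be 'otsu'")
  if (length(msg)) msg else TRUE
})

#' Construct a pore measurement configuration
#'
#' @param areaMaxPx pore area upper limit (px^2); \code{NA} means 20\% of the
#'   ROI area, the approximate maximum a pore can cover at the default scale.
#' @param areaMinPx candidate-region noise floor (px^2).
#' @param maxCenterDistFrac centrality requirement: a candidate's centroid
#'   must lie within this fraction of the smaller ROI dimension from the ROI
#'   center (the pore belongs to the stoma the detector centered on; distant
#'   fragments cut off by veins or cell walls do not qualify).
#' @param skeletonLengthBounds admissible skeleton length window (px).
#' @param minCompleteness minimum boundary completeness for a trusted ellipse
#'   fit.
#' @param connectivity 4 or 8.
#' @param thresholdMethod automatic threshold method.
#' @param sharpenAmount,sharpenSigma unsharp-mask parameters.
#' @return A \code{PoreConfig} object.
#' @examples
#' PoreConfig()
#' @export
PoreConfig <- function(areaMaxPx = NA_real_, areaMinPx = 60,
                       maxCenterDistFrac = 0.25,
                       skeletonLengthBounds = c(10, 210),
                       minCompleteness = 0.6, connectivity = 8L,
                       thresholdMethod = "otsu", sharpenAmount = 1,
                       sharpenSigma = 1.5) {
  new("PoreConfig", areaMaxPx = as.numeric(areaMaxPx),
      areaMinPx = as.numeric(areaMinPx),
      maxCenterDistFrac = as.numeric(maxCenterDistFrac),
      skeletonLengthBounds = as.numeric(skeletonLengthBounds),
      minCompleteness = as.numeric(minCompleteness),
      connectivity = as.integer(connectivity),
      thresholdMethod = thresholdMethod,
      sharpenAmount = as.numeric(sharpenAmount),
      sharpenSigma = as.numeric(sharpenSigma))
}

setMethod("show", "PoreConfig", function(object) {
  cat("PoreConfig: area in [", object@areaMinPx, ",",
      ifelse(is.na(object@areaMaxPx), "20% of ROI", object@areaMaxPx),
      "] px^2; skeleton length in [", object@skeletonLengthBounds[1], ",",
      object@skeletonLengthBounds[2], "] px\n")
  cat("  min boundary completeness:", object@minCompleteness,
      "; connectivity:", object@connectivity, "\n")
})

#' A single pore measurement
#'
#' The output record of the pore measurement engine. When
#' \code{status == "measured"}, the record carries the pore area \eqn{A}
#' (px^2 and um^2), the eccentricity \eqn{E}, and semi-axis lengths
#' \eqn{a, b} derived from \eqn{(A, E)} through
#' \deqn{a = \sqrt{A / (\pi \sqrt{1 - E^2})}, \qquad
#'       b = \sqrt{A \sqrt{1 - E^2} / \pi},}
#' so that \eqn{\pi a b = A} and \eqn{b/a = \sqrt{1 - E^2}} hold exactly.
#' \code{method} records which path produced the measurement
#' ("segmentation" for complete boundaries, "skeleton" for the
#' skeletonization + ellipse-fitting fallback). Discarded records carry a
#' machine-readable \code{reason} and no numeric fields.
#'
#' @slot status "measured" or "discarded".
#' @slot method "segmentation", "skeleton" or "none".
#' @slot areaPx2,areaUm2 pore area.
#' @slot semiMajorPx,semiMinorPx semi-axis lengths (px).
#' @slot eccentricity eccentricity in [0, 1).
#' @slot boundary integer matrix of traced pore outline pixels
#'   (0-based row, col).
#' @slot reason reason code for discarded measurements.
#' @name PoreMeasurement-class
#' @aliases PoreMeasurement-class
#' @exportClass PoreMeasurement
setClass("PoreMeasurement",
  representation(status = "character", method = "character",
                 areaPx2 = "numeric", areaUm2 = "numeric",
                 semiMajorPx = "numeric", semiMinorPx = "numeric",
                 eccentricity = "numeric", boundary = "matrix",
                 reason = "character"))

setValidity("PoreMeasurement", function(object) {
  msg <- character()
  if (!object@status %in% c("measured", "discarded"))
    msg <- c(msg, "status must be 'measured' or 'discarded'")
  if (!object@method %in% c("segmentation", "skeleton", "none"))
    msg <- c(msg, "method must be 'segmentation', 'skeleton' or 'none'")
  if (object@status == "measured") {
    A <- object@areaPx2; a <- object@semiMajorPx; b <- object@semiMinorPx
    E <- object@eccentricity
    if (any(is.na(c(A, a, b, E))))
      msg <- c(msg, "measured records must carry numeric fields")
    else {
      if (abs(pi * a * b - A) > 1e-9 * max(A, 1))
        msg <- c(msg, "pi * a * b must equal the area")
      if (abs(b / a - sqrt(1 - E^2)) > 1e-9)
        msg <- c(msg, "b/a must equal sqrt(1 - E^2)")
      if (E < 0 || E >= 1) msg <- c(msg, "eccentricity must lie in [0, 1)")
    }
  } else {
    if (!all(is.na(c(object@areaPx2, object@semiMajorPx,
                     object@semiMinorPx, object@eccentricity))))
      msg <- c(msg, "discarded records must not carry numeric fields")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoreMeasurement", function(object) {
  if (object@status == "measured") {
    cat(sprintf(
      "PoreMeasurement [%s]: A = %.1f px^2 (%.2f um^2), a = %.2f px, b = %.2f px, E = %.3f\n",
      object@method, object@areaPx2, object@areaUm2, object@semiMajorPx,
      object@semiMinorPx, object@eccentricity))
  } else {
    cat("PoreMeasurement [discarded]:", object@reason, "\n")
  }
})

#' @describeIn PoreMeasurement-class measurement status ("measured"/"discarded").
#' @param x a \code{PoreMeasurement}.
#' @export
measurementStatus <- function(x) x@status

#' @describeIn PoreMeasurement-class path that produced the measurement.
#' @export
measurementMethod <- function(x) x@method

#' @describeIn PoreMeasurement-class pore area.
#' @param units "px" (px^2) or "um" (um^2).
#' @export
poreArea <- function(x, units = c("px", "um")) {
  units <- match.arg(units)
  if (units == "px") x@areaPx2 else x@areaUm2
}

#' @describeIn PoreMeasurement-class semi-axis lengths c(a, b) in px.
#' @export
poreAxes <- function(x) c(a = x@semiMajorPx, b = x@semiMinorPx)

#' @describeIn PoreMeasurement-class eccentricity.
#' @export
poreEccentricity <- function(x) x@eccentricity

#' @describeIn PoreMeasurement-class traced pore outline (0-based row, col).
#' @export
poreBoundary <- function(x) x@boundary

#' Coerce a pore measurement to a one-row data frame
#'
#' @param x a \code{PoreMeasurement}.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return A one-row \code{data.frame}.
#' @export
as.data.frame.PoreMeasurement <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(status = x@status, method = x@method, area_px2 = x@areaPx2,
             area_um2 = x@areaUm2, semi_major_px = x@semiMajorPx,
             semi_minor_px = x@semiMinorPx, eccentricity = x@eccentricity,
             reason = x@reason, stringsAsFactors = FALSE)
}

# internal constructors
newMeasured <- function(method, areaPx2, areaUm2, a, b, E, boundary) {
  new("PoreMeasurement", status = "measured", method = method,
      areaPx2 = areaPx2, areaUm2 = areaUm2, semiMajorPx = a, semiMinorPx = b,
      eccentricity = E, boundary = boundary, reason = "")
}

newDiscarded <- function(reason, method = "none") {
  new("PoreMeasurement", status = "discarded", method = method,
      areaPx2 = NA_real_, areaUm2 = NA_real_, semiMajorPx = NA_real_,
      semiMinorPx = NA_real_, eccentricity = NA_real_,
      boundary = matrix(integer(0), 0, 2), reason = reason)
}
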