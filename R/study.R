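# The scaled synthetic evaluation study: train a cascade on generated
# samples, run the full pipeline on held-out scenes, and score detection
# and measurement against the generator's ground truth.

#' Run the scaled synthetic detection-and-measurement study
#'
#' Trains a cascade on generated positives/negatives, runs detection and
#' two-path pore measurement on held-out synthetic scenes, and scores the
#' result against the generator's ground truth: detection precision/recall,
#' the fraction of detected ROIs that yielded a measurement, and per-path
#' agreement between estimated and planted pore area and eccentricity (a
#' planted ellipse with semi-axes sa, sb has area pi*sa*sb and eccentricity
#' sqrt(1 - (sb/sa)^2)).
#'
#' @param seed master seed; training samples, scenes and any stochastic
#'   training step all derive from it.
#' @param nPos,nNeg training-set sizes.
#' @param nScenes number of held-out evaluation scenes.
#' @param spec the \code{\link{SceneSpec}} describing the study conditions
#'   (its seed slot is overridden per scene).
#' @param nStages cascade depth to train.
#' @param config a \code{\link{PoreConfig}}.
#' @param verbose log progress.
#' @return List with \code{model}, \code{counts} (TP/FP/FN),
#'   \code{metrics} (precision/recall/accuracy percent, f1),
#'   \code{nDetected}, \code{nMeasured}, \code{measuredFractionPct},
#'   \code{pathCounts} (measured per path), \code{areaAgreementSegPct},
#'   \code{areaAgreementSkelPct}, \code{eccAgreementPct},
#'   \code{identificationRatePct} (measured ROIs whose area lies within
#'   25\% of the planted value), and the per-ROI \code{records} data frame.
#' @export
runSyntheticStudy <- function(seed = 1L, nPos = 200L, nNeg = 100L,
                              nScenes = 20L, spec = SceneSpec(),
                              nStages = 8L, config = PoreConfig(),
                              verbose = FALSE) {
  trainSpec <- spec
  trainSpec@seed <- as.integer(childSeed(seed, 1))
  if (verbose) message("rendering training set ...")
  ts <- makeTrainingSet(trainSpec, nPos = nPos, nNeg = nNeg)
  if (verbose) message("training cascade ...")
  model <- trainCascade(ts$positives, ts$negatives, nStages = nStages,
                        seed = as.integer(childSeed(seed, 2)),
                        verbose = verbose)
  counts <- c(TP = 0L, FP = 0L, FN = 0L)
  recs <- list()
  for (s in seq_len(nScenes)) {
    evalSpec <- spec
    evalSpec@seed <- as.integer(childSeed(seed, 1000 + s))
    scene <- renderScene(evalSpec)
    det <- detectStomata(model, scene$image)
    gtC <- as.matrix(scene$groundTruth[, c("row", "col")])
    counts <- counts + matchDetections(det, gtC)
    pairing <- assignDetections(det, gtC)
    for (i in seq_len(nrow(det))) {
      roi <- cropROI(scene$image,
                     as.numeric(det[i, c("row0", "col0", "row1", "col1")]))
      pm <- measurePore(roi, config)
      j <- pairing[i]
      rec <- data.frame(scene = s, roi = i, matched = !is.na(j),
                        status = measurementStatus(pm),
                        method = measurementMethod(pm),
                        area_px2 = if (measurementStatus(pm) == "measured")
                          poreArea(pm) else NA_real_,
                        ecc = if (measurementStatus(pm) == "measured")
                          poreEccentricity(pm) else NA_real_,
                        area_true = NA_real_, ecc_true = NA_real_,
                        completeness = NA_real_)
      if (!is.na(j)) {
        g <- scene$groundTruth[j, ]
        rec$area_true <- pi * g$semi_major_px * g$semi_minor_px
        rec$ecc_true <- sqrt(1 - (g$semi_minor_px / g$semi_major_px)^2)
        rec$completeness <- g$completeness
      }
      recs[[length(recs) + 1]] <- rec
    }
    if (verbose)
      message(sprintf("scene %d/%d: %d detections", s, nScenes, nrow(det)))
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(scene = integer(0), roi = integer(0), matched = logical(0),
               status = character(0), method = character(0),
               area_px2 = numeric(0), ecc = numeric(0),
               area_true = numeric(0), ecc_true = numeric(0),
               completeness = numeric(0))
  metrics <- detectionMetrics(counts)
  measured <- records$status == "measured"
  scored <- measured & records$matched & !is.na(records$area_true)
  agr <- function(idx, col, truth) {
    if (!any(idx)) return(NA_real_)
    mean(measurementAgreement(records[[truth]][idx],
                              records[[col]][idx])$agreement_pct)
  }
  seg <- scored & records$method == "segmentation"
  skel <- scored & records$method == "skeleton"
  areaErr <- abs(records$area_px2 - records$area_true) /
    records$area_true
  accurate <- scored & areaErr <= 0.25
  list(model = model, counts = counts, metrics = metrics,
       nDetected = nrow(records), nMeasured = sum(measured),
       measuredFractionPct = 100 * sum(measured) / max(1, nrow(records)),
       pathCounts = c(segmentation = sum(measured &
                        records$method == "segmentation"),
                      skeleton = sum(measured & records$method == "skeleton")),
       areaAgreementSegPct = agr(seg, "area_px2", "area_true"),
       areaAgreementSkelPct = agr(skel, "area_px2", "area_true"),
       eccAgreementPct = agr(scored, "ecc", "ecc_true"),
       identificationRatePct =
         if (sum(measured & records$matched)) {
           100 * sum(accurate, na.rm = TRUE) / sum(measured & records$matched)
         } else NA_real_,
       records = records)
}
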