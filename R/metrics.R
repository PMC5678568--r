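# Detection matching and evaluation statistics.

# One-to-one assignment of detections to ground-truth centers. Containment
# pairs are matched nearest-center-first; augmenting-path reassignment then
# guarantees the matching has maximum cardinality (so the count of matches
# equals the exhaustive optimal assignment), while close pairs keep their
# preferred partners whenever possible. Returns, for each detection, the
# matched ground-truth index or NA.
assignDetections <- function(detections, gtCenters) {
  nd <- nrow(detections); ng <- nrow(gtCenters)
  assign <- rep(NA_integer_, nd)
  if (nd == 0 || ng == 0) return(assign)
  bcR <- (detections$row0 + detections$row1) / 2
  bcC <- (detections$col0 + detections$col1) / 2
  edges <- vector("list", nd)
  pairs <- NULL
  for (i in seq_len(nd)) {
    inside <- gtCenters[, 1] >= detections$row0[i] &
      gtCenters[, 1] < detections$row1[i] &
      gtCenters[, 2] >= detections$col0[i] &
      gtCenters[, 2] < detections$col1[i]
    js <- which(inside)
    edges[[i]] <- js
    if (length(js)) {
      d <- sqrt((gtCenters[js, 1] - bcR[i])^2 + (gtCenters[js, 2] - bcC[i])^2)
      pairs <- rbind(pairs, cbind(det = i, gt = js, dist = d))
    }
  }
  if (is.null(pairs)) return(assign)
  pairs <- pairs[order(pairs[, "dist"]), , drop = FALSE]
  gtOwner <- rep(NA_integer_, ng)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, "det"]; j <- pairs[k, "gt"]
    if (is.na(assign[i]) && is.na(gtOwner[j])) {
      assign[i] <- j
      gtOwner[j] <- i
    }
  }
  # augmenting paths: every additional match that exists is taken
  seen <- logical(ng)
  augment <- function(i) {
    for (j in edges[[i]]) {
      if (seen[j]) next
      seen[j] <<- TRUE
      owner <- gtOwner[j]
      if (is.na(owner) || augment(owner)) {
        assign[i] <<- j
        gtOwner[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in which(is.na(assign))) {
    seen <- logical(ng)
    augment(i)
  }
  assign
}

#' Match detections against ground-truth stoma centers
#'
#' One-to-one matching: a detection is a true positive when its box contains
#' a not-yet-matched ground-truth center; among all (detection, center)
#' containment pairs, closer center-to-box-center pairs are matched first,
#' and augmenting-path reassignment then ensures the matching has maximum
#' cardinality (it always agrees with the exhaustive optimal assignment).
#' Unmatched detections are false positives; unmatched centers are false
#' negatives. With point ground truth, center-in-box is the matching
#' criterion (an IoU criterion would need ground-truth boxes).
#'
#' @param detections data frame with \code{row0}, \code{col0}, \code{row1},
#'   \code{col1} (0-based, half-open boxes).
#' @param gtCenters matrix or data frame with columns (row, col), one
#'   ground-truth stoma center per row, in the same coordinate frame.
#' @return Named integer vector \code{c(TP, FP, FN)}; always satisfies
#'   \code{TP + FP = nrow(detections)} and \code{TP + FN = nrow(gtCenters)}.
#' @examples
#' det <- data.frame(row0 = 0, col0 = 0, row1 = 10, col1 = 10)
#' matchDetections(det, cbind(5, 5))
#' @export
matchDetections <- function(detections, gtCenters) {
  gtCenters <- as.matrix(gtCenters)
  nd <- nrow(detections); ng <- nrow(gtCenters)
  tp <- sum(!is.na(assignDetections(detections, gtCenters)))
  c(TP = as.integer(tp), FP = as.integer(nd - tp), FN = as.integer(ng - tp))
}

#' Detection performance metrics
#'
#' From confusion counts: precision = TP/(TP+FP), recall = TP/(TP+FN) (both
#' in percent), F1 = harmonic mean of precision and recall as fractions, and
#' accuracy = TP/(TP+FP+FN) in percent -- the critical-success-index form,
#' the arithmetic consistent with how detection "accuracy" is convention-
#' ally tabulated alongside precision and recall for this task. Zero
#' denominators yield 0.
#'
#' @param counts named vector with elements TP, FP, FN.
#' @return Named numeric vector \code{c(precision, recall, accuracy, f1)};
#'   precision/recall/accuracy in percent, f1 in [0, 1].
#' @examples
#' detectionMetrics(c(TP = 1597, FP = 145, FN = 415))
#' @export
detectionMetrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (tp + fp + fn == 0) {
    warning("no detections and no ground truth; metrics defined as 0")
    return(c(precision = 0, recall = 0, accuracy = 0, f1 = 0))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  acc <- tp / (tp + fp + fn)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = 100 * p, recall = 100 * r, accuracy = 100 * acc, f1 = f1)
}

#' Agreement between an estimated and a reference measurement
#'
#' The relative error is \eqn{|(Y - \hat{Y}) / Y| \times 100} (percent);
#' the agreement is its complement \eqn{100 - } error, the reading under
#' which a perfect estimate scores 100\%. Both are returned. Vectorized.
#'
#' @param Y reference (ground-truth) value(s), non-zero.
#' @param Yhat estimated value(s).
#' @return Data frame with columns \code{Y}, \code{Yhat},
#'   \code{relative_error_pct}, \code{agreement_pct}.
#' @examples
#' measurementAgreement(100, 110)
#' @export
measurementAgreement <- function(Y, Yhat) {
  if (any(Y == 0)) stop("reference value must be non-zero")
  err <- abs((Y - Yhat) / Y) * 100
  data.frame(Y = Y, Yhat = Yhat, relative_error_pct = err,
             agreement_pct = 100 - err)
}

#' Pore identification rate
#'
#' Percentage of measured pores whose boundary was identified correctly:
#' \code{100 * accurate / (accurate + inaccurate)}.
#'
#' @param accurate,inaccurate counts of accurate and inaccurate pore
#'   identifications.
#' @return Percentage.
#' @examples
#' poreIdentificationRate(1093, 174)
#' @export
poreIdentificationRate <- function(accurate, inaccurate) {
  if (accurate + inaccurate <= 0)
    stop("at least one identification is required")
  100 * accurate / (accurate + inaccurate)
}
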