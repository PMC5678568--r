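# End-to-end orchestration: detect -> crop -> measure -> report.

#' Crop a detection box from a micrograph
#'
#' @param image numeric matrix.
#' @param box numeric (row0, col0, row1, col1), 0-based half-open.
#' @return The cropped matrix (clamped to the image bounds).
#' @export
cropROI <- function(image, box) {
  r0 <- max(0, floor(box[1])); c0 <- max(0, floor(box[2]))
  r1 <- min(nrow(image), ceiling(box[3])); c1 <- min(ncol(image), ceiling(box[4]))
  image[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
}

#' Run the full pipeline on a set of micrographs
#'
#' For each image: detect stomata with the cascade, crop each detection,
#' measure the pore with the two-path engine, and aggregate one row per ROI.
#' Per-image counts (ROIs detected, measured, discarded) are logged and
#' returned; detected = measured + discarded in every run.
#'
#' @param model a \code{\link{CascadeModel-class}}.
#' @param images list of numeric matrices, or character paths readable by
#'   \code{\link{readMicrograph}}; unreadable paths are skipped with a
#'   warning.
#' @param config a \code{\link{PoreConfig}}.
#' @param pixelScale pixels per micrometer.
#' @param stridePx,scaleFactors,nmsIoU detector settings, see
#'   \code{\link{detectStomata}}.
#' @param overlayDir if non-NULL, writes per-image PNG overlays: detection
#'   boxes in yellow, each measured pore boundary traced in green.
#' @param verbose log per-image counts.
#' @return List with \code{measurements} (data frame: \code{image_id},
#'   \code{roi_id}, box coordinates, \code{status}, \code{method},
#'   \code{area_px2}, \code{area_um2}, \code{semi_major_px},
#'   \code{semi_minor_px}, \code{eccentricity}, \code{reason}) and
#'   \code{counts} (per image: \code{detected}, \code{measured},
#'   \code{discarded}).
#' @export
runEndToEnd <- function(model, images, config = PoreConfig(),
                        pixelScale = 8.6, stridePx = 8L,
                        scaleFactors = c(0.8, 1, 1.25), nmsIoU = 0.3,
                        overlayDir = NULL, verbose = FALSE) {
  if (!length(images))
    return(list(measurements = emptyMeasurementTable(),
                counts = data.frame(image_id = character(0),
                                    detected = integer(0),
                                    measured = integer(0),
                                    discarded = integer(0))))
  ids <- names(images)
  if (is.null(ids)) {
    ids <- if (all(vapply(images, is.character, logical(1))))
      basename(unlist(images)) else sprintf("image%03d", seq_along(images))
  }
  rowsOut <- list(); countsOut <- list()
  for (k in seq_along(images)) {
    img <- images[[k]]
    if (is.character(img)) {
      img <- tryCatch(suppressWarnings(readMicrograph(img)),
                      error = function(e) NULL)
      if (is.null(img)) {
        warning(sprintf("skipping unreadable image '%s'", ids[k]))
        next
      }
    }
    img <- toGray(img)
    det <- detectStomata(model, img, stridePx = stridePx,
                         scaleFactors = scaleFactors, nmsIoU = nmsIoU)
    nMeasured <- 0L
    meas <- vector("list", nrow(det))
    pms <- vector("list", nrow(det))
    for (i in seq_len(nrow(det))) {
      roi <- cropROI(img, as.numeric(det[i, c("row0", "col0", "row1", "col1")]))
      pm <- measurePore(roi, config, pixelScale)
      pms[[i]] <- pm
      if (measurementStatus(pm) == "measured") nMeasured <- nMeasured + 1L
      meas[[i]] <- cbind(data.frame(image_id = ids[k], roi_id = i,
                                    det[i, c("row0", "col0", "row1", "col1",
                                             "score")], row.names = NULL),
                         as.data.frame(pm))
    }
    if (length(meas)) rowsOut[[length(rowsOut) + 1]] <- do.call(rbind, meas)
    countsOut[[length(countsOut) + 1]] <-
      data.frame(image_id = ids[k], detected = nrow(det),
                 measured = nMeasured, discarded = nrow(det) - nMeasured)
    if (verbose)
      message(sprintf("%s: %d ROIs detected, %d measured, %d discarded",
                      ids[k], nrow(det), nMeasured, nrow(det) - nMeasured))
    if (!is.null(overlayDir) && nrow(det))
      writeOverlayPNG(img, det, pms,
                      file.path(overlayDir, paste0(ids[k], "_overlay.png")))
  }
  measurements <- if (length(rowsOut)) do.call(rbind, rowsOut) else
    emptyMeasurementTable()
  rownames(measurements) <- NULL
  list(measurements = measurements, counts = do.call(rbind, countsOut))
}

emptyMeasurementTable <- function() {
  data.frame(image_id = character(0), roi_id = integer(0), row0 = numeric(0),
             col0 = numeric(0), row1 = numeric(0), col1 = numeric(0),
             score = numeric(0), status = character(0), method = character(0),
             area_px2 = numeric(0), area_um2 = numeric(0),
             semi_major_px = numeric(0), semi_minor_px = numeric(0),
             eccentricity = numeric(0), reason = character(0))
}

# Overlay: detection boxes in yellow, measured pore boundaries in green.
writeOverlayPNG <- function(img, det, pms, path) {
  rgb <- array(rep(clamp01(img), 3), c(dim(img), 3))
  paint <- function(rows, cols, color) {
    ok <- rows >= 1 & rows <= nrow(img) & cols >= 1 & cols <= ncol(img)
    for (ch in 1:3)
      rgb[cbind(rows[ok], cols[ok], ch)] <<- color[ch]
  }
  for (i in seq_len(nrow(det))) {
    b <- round(as.numeric(det[i, c("row0", "col0", "row1", "col1")]))
    yellow <- c(1, 1, 0)
    paint(rep(c(b[1] + 1, b[3]), each = b[4] - b[2]),
          rep((b[2] + 1):b[4], 2), yellow)
    paint(rep((b[1] + 1):b[3], 2),
          rep(c(b[2] + 1, b[4]), each = b[3] - b[1]), yellow)
    pm <- pms[[i]]
    if (measurementStatus(pm) == "measured" && nrow(poreBoundary(pm))) {
      bd <- poreBoundary(pm)
      paint(bd[, 1] + b[1] + 1, bd[, 2] + b[2] + 1, c(0, 1, 0))
    }
  }
  EBImage::writeImage(EBImage::Image(aperm(rgb, c(2, 1, 3)),
                                     colormode = "Color"), path, type = "png")
  invisible(path)
}

#' Write / read detection tables
#'
#' CSV with columns \code{image_id}, \code{row0}, \code{col0}, \code{row1},
#' \code{col1}, \code{score}; boxes are 0-based, half-open, stated in the
#' file header. Write -> read -> write round-trips are byte-identical.
#'
#' @param detections data frame of detections.
#' @param path CSV path.
#' @param imageId id stored when the table has no \code{image_id} column.
#' @return \code{writeDetections}: the path, invisibly;
#'   \code{readDetections}: the data frame.
#' @export
writeDetections <- function(detections, path, imageId = "image1") {
  if (!"image_id" %in% names(detections) && nrow(detections))
    detections <- cbind(image_id = imageId, detections)
  con <- file(path, "w")
  writeLines("# boxes: 0-based (row, col), half-open [row0, row1) x [col0, col1)",
             con)
  write.csv(detections, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write a measurement table
#'
#' CSV mirror of the \code{measurements} element of
#' \code{\link{runEndToEnd}}; coordinates 0-based, stated in the header.
#'
#' @param measurements measurement data frame.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
writeMeasurements <- function(measurements, path) {
  for (col in c("status", "method", "reason"))
    if (col %in% names(measurements))
      measurements[[col]][is.na(measurements[[col]])] <- ""
  con <- file(path, "w")
  writeLines("# coordinates: 0-based (row, col); boxes half-open; areas px^2 / um^2",
             con)
  write.csv(measurements, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized top-level keys (all optional): \code{pixel_scale} (px per um,
#' default 8.6), \code{stride_px}, \code{scale_factors}, \code{nms_iou},
#' \code{seed}, \code{model} (path to a cascade JSON), \code{pore}
#' (sub-keys matching \code{\link{PoreConfig}} arguments, snake_case) and
#' \code{scene} (sub-keys matching \code{\link{SceneSpec}} arguments,
#' snake_case).
#'
#' @param path YAML file path.
#' @return List with elements \code{pixelScale}, \code{stridePx},
#'   \code{scaleFactors}, \code{nmsIoU}, \code{seed}, \code{modelPath},
#'   \code{pore} (a \code{PoreConfig}) and \code{scene} (a
#'   \code{SceneSpec}).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  snake2camel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  buildArgs <- function(lst) {
    if (is.null(lst)) return(list())
    names(lst) <- snake2camel(names(lst))
    lst
  }
  pore <- do.call(PoreConfig, buildArgs(y$pore))
  scene <- do.call(SceneSpec, buildArgs(y$scene))
  ps <- if (is.null(y$pixel_scale)) 8.6 else y$pixel_scale
  if (ps <= 0) stop("pixel_scale must be positive")
  list(pixelScale = ps,
       stridePx = if (is.null(y$stride_px)) 8L else as.integer(y$stride_px),
       scaleFactors = if (is.null(y$scale_factors)) c(0.8, 1, 1.25) else
         as.numeric(y$scale_factors),
       nmsIoU = if (is.null(y$nms_iou)) 0.3 else y$nms_iou,
       seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
       modelPath = y$model, pore = pore, scene = scene)
}
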