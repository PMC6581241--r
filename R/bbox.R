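#' Axis-aligned bounding box
#'
#' Boxes are 0-based, half-open pixel rectangles `[x_min, x_max) x
#' [y_min, y_max)` with continuous coordinates. All format converters
#' (YOLO-txt, COCO-JSON) translate to and from this convention explicitly.
#'
#' @param x_min,y_min,x_max,y_max corner coordinates in pixels.
#' @return a named numeric vector of class `bbox`.
#' @export
#' @examples
#' bbox(0, 0, 2, 2)
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (!all(is.finite(b))) stop("bbox coordinates must be finite")
  if (b["x_max"] <= b["x_min"] || b["y_max"] <= b["y_min"]) {
    stop("invalid bbox: require x_max > x_min and y_max > y_min")
  }
  class(b) <- "bbox"
  b
}

bbox_area <- function(b) {
  unname((b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]]))
}

#' Intersection over union of two boxes
#'
#' The overlap criterion used both by non-maximum suppression and by the
#' detection-to-truth matching underlying average precision.
#'
#' @param a,b boxes created with [bbox()] (any object with the four corner
#'   fields is accepted).
#' @return a value in \[0, 1\]: 1 for identical boxes, 0 for disjoint ones.
#' @export
#' @examples
#' iou(bbox(0, 0, 2, 2), bbox(1, 0, 3, 2))  # 1/3
iou <- function(a, b) {
  ix <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  iy <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

## Vectorised IoU of one box against a corner matrix (n x 4, columns
## x_min, y_min, x_max, y_max). Used on hot paths (NMS, matching, targets).
iou_one_many <- function(x_min, y_min, x_max, y_max, m) {
  ix <- pmin(x_max, m[, 3L]) - pmax(x_min, m[, 1L])
  iy <- pmin(y_max, m[, 4L]) - pmax(y_min, m[, 2L])
  inter <- pmax(ix, 0) * pmax(iy, 0)
  a <- (x_max - x_min) * (y_max - y_min)
  b <- (m[, 3L] - m[, 1L]) * (m[, 4L] - m[, 2L])
  inter / (a + b - inter)
}

det_corner_matrix <- function(d) {
  cbind(d$x_min, d$y_min, d$x_max, d$y_max)
}

#' Class-wise greedy non-maximum suppression
#'
#' Within each class, detections are visited in order of descending
#' confidence (ties broken by input order); a detection is kept unless its
#' IoU with an already-kept detection of the same class exceeds
#' `iou_threshold`. Detections from different images never suppress each
#' other.
#'
#' @param dets a detection data frame (see [detections()]).
#' @param iou_threshold overlap above which the lower-confidence box is
#'   dropped; default 0.45, the conventional single-stage setting.
#' @return the surviving subset, sorted by descending confidence (input
#'   order among ties).
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  validate_detections(dets)
  if (nrow(dets) <= 1L) return(dets)
  dets$.ord <- seq_len(nrow(dets))
  o <- order(-dets$confidence, dets$.ord)
  d <- dets[o, , drop = FALSE]
  keep <- logical(nrow(d))
  m <- det_corner_matrix(d)
  for (grp in split(seq_len(nrow(d)),
                    list(d$image_id, d$class), drop = TRUE)) {
    kept <- integer(0)
    for (i in grp) {
      if (length(kept)) {
        ov <- iou_one_many(m[i, 1L], m[i, 2L], m[i, 3L], m[i, 4L],
                           m[kept, , drop = FALSE])
        if (any(ov > iou_threshold)) next
      }
      keep[i] <- TRUE
      kept <- c(kept, i)
    }
  }
  out <- d[keep, , drop = FALSE]
  out <- out[order(-out$confidence, out$.ord), , drop = FALSE]
  out$.ord <- NULL
  rownames(out) <- NULL
  out
}
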