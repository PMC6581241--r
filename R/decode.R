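#' Logistic function and its inverse
#'
#' @param x numeric vector.
#' @return `sigmoid()` maps reals to (0, 1); `logit()` is its inverse.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname sigmoid
#' @param p numeric vector in (0, 1).
#' @export
logit <- function(p) log(p / (1 - p))

#' Raw grid-cell prediction
#'
#' One anchor's raw network output at one grid cell: unconstrained box
#' offsets `tx, ty, tw, th`, an objectness logit, and one logit per class.
#' `cell = (cx, cy)` are the 0-based cell indices and `anchor = (pw, ph)`
#' the anchor prior in cell units.
#'
#' @param tx,ty,tw,th raw box outputs (any reals).
#' @param objectness_logit raw objectness output.
#' @param class_logits numeric vector of 5 raw class scores.
#' @param cell integer vector `c(cx, cy)`, 0-based.
#' @param anchor numeric vector `c(pw, ph)` in cell units, both > 0.
#' @param grid_size cells per side (default 13).
#' @return an object of class `grid_cell_prediction`.
#' @export
grid_cell_prediction <- function(tx, ty, tw, th, objectness_logit = 0,
                                 class_logits = rep(0, 5),
                                 cell = c(0L, 0L), anchor = c(1, 1),
                                 grid_size = 13L) {
  p <- list(tx = tx, ty = ty, tw = tw, th = th,
            objectness_logit = objectness_logit,
            class_logits = class_logits,
            cell = as.integer(cell), anchor = as.numeric(anchor),
            grid_size = as.integer(grid_size))
  raw <- c(tx, ty, tw, th, objectness_logit, class_logits)
  if (!all(is.finite(raw))) stop("non-finite raw network outputs")
  if (length(class_logits) != 5L) stop("class_logits must have length 5")
  if (any(p$cell < 0L) || any(p$cell >= p$grid_size)) {
    stop("cell indices must satisfy 0 <= cx, cy < grid_size")
  }
  if (any(p$anchor <= 0)) stop("anchor dimensions must be positive")
  class(p) <- "grid_cell_prediction"
  p
}

#' Decode one grid-cell prediction to a normalized box
#'
#' The box centre is the cell origin plus a sigmoid-squashed offset, so it
#' always falls strictly inside the predicting cell; the box size is the
#' anchor prior scaled by the exponential of the raw output (a log-space
#' transform). All four values are normalised by the image side, so a box
#' with centre `(bx, by)` sits at `(grid_size * bx, grid_size * by)` in
#' feature-map cell units. Class confidences are sigmoids of the class
#' logits -- independent per class, not a softmax.
#'
#' @param pred a [grid_cell_prediction()].
#' @param image_size image side in pixels; when given, pixel-space corners
#'   are attached to the result.
#' @return a list of class `decoded_box` with `bx, by, bw, bh` in
#'   normalized image units, `objectness` in (0,1), `class_conf` (5 named
#'   sigmoid scores), and if `image_size` was supplied a `bbox` in pixels.
#' @export
#' @examples
#' p <- grid_cell_prediction(0, 0, 0, 0, cell = c(0, 0), anchor = c(1, 1))
#' decode_cell(p)  # centre (0.5/13, 0.5/13), size 1/13
decode_cell <- function(pred, image_size = NULL) {
  stopifnot(inherits(pred, "grid_cell_prediction"))
  g <- pred$grid_size
  bx <- (pred$cell[1L] + sigmoid(pred$tx)) / g
  by <- (pred$cell[2L] + sigmoid(pred$ty)) / g
  bw <- pred$anchor[1L] * exp(pred$tw) / g
  bh <- pred$anchor[2L] * exp(pred$th) / g
  out <- list(
    bx = bx, by = by, bw = bw, bh = bh,
    objectness = sigmoid(pred$objectness_logit),
    class_conf = stats::setNames(sigmoid(pred$class_logits),
                                 cholescan_classes())
  )
  if (!is.null(image_size)) {
    out$bbox <- bbox((bx - bw / 2) * image_size, (by - bh / 2) * image_size,
                     (bx + bw / 2) * image_size, (by + bh / 2) * image_size)
  }
  class(out) <- "decoded_box"
  out
}

#' Encode a ground-truth box as grid-cell regression targets
#'
#' Exact inverse of [decode_cell()]: finds the responsible cell from the
#' normalized box centre and inverts the sigmoid/exponential transforms.
#' A centre exactly on the far image boundary is clamped into the last
#' cell; the sigmoid inverse is clamped away from 0/1 by `eps` so targets
#' stay finite when a centre sits on a cell edge.
#'
#' @param truth a [bbox()] in pixels.
#' @param image_size image side in pixels.
#' @param grid_size cells per side.
#' @param anchor `c(pw, ph)` anchor prior in cell units.
#' @param eps clamp for the inverse sigmoid (default 1e-12).
#' @return a [grid_cell_prediction()] whose `tx, ty, tw, th` reproduce
#'   `truth` through [decode_cell()] (centre and size to < 1e-9 normalized
#'   units away from cell edges).
#' @export
encode_box <- function(truth, image_size, grid_size = 13L, anchor = c(1, 1),
                       eps = 1e-12) {
  stopifnot(inherits(truth, "bbox"))
  w <- (truth[["x_max"]] - truth[["x_min"]]) / image_size
  h <- (truth[["y_max"]] - truth[["y_min"]]) / image_size
  if (w <= 0 || h <= 0) stop("degenerate truth box: width/height must be > 0")
  bx <- (truth[["x_min"]] + truth[["x_max"]]) / 2 / image_size
  by <- (truth[["y_min"]] + truth[["y_max"]]) / 2 / image_size
  if (bx < 0 || bx > 1 || by < 0 || by > 1) {
    stop("truth box centre lies outside the image")
  }
  cx <- min(floor(bx * grid_size), grid_size - 1L)
  cy <- min(floor(by * grid_size), grid_size - 1L)
  ox <- min(max(bx * grid_size - cx, eps), 1 - eps)
  oy <- min(max(by * grid_size - cy, eps), 1 - eps)
  grid_cell_prediction(
    tx = logit(ox), ty = logit(oy),
    tw = log(w * grid_size / anchor[1L]),
    th = log(h * grid_size / anchor[2L]),
    cell = c(cx, cy), anchor = anchor, grid_size = grid_size
  )
}
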