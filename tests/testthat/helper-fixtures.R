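# Shared fixtures, built in code at test time.

empty_detections_fixture <- function() {
  detections(character(0), character(0), numeric(0), numeric(0),
             numeric(0), numeric(0), numeric(0))
}

random_bbox <- function(image_size = 128) {
  w <- runif(1, 2, image_size / 2)
  h <- runif(1, 2, image_size / 2)
  x <- runif(1, 0, image_size - w)
  y <- runif(1, 0, image_size - h)
  bbox(x, y, x + w, y + h)
}

random_detections <- function(n, image_size = 100, classes = "gall",
                              image_id = "img") {
  d <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- random_bbox(image_size)
    detections(image_id, sample(classes, 1), runif(1, 1, 100),
               b[["x_min"]], b[["y_min"]], b[["x_max"]], b[["y_max"]])
  }))
  d
}

## Naive reference NMS: scalar loops, pairwise iou() calls.
nms_oracle <- function(dets, iou_threshold = 0.45) {
  o <- order(-dets$confidence, seq_len(nrow(dets)))
  d <- dets[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(d))) {
      if (j <= i || !keep[j]) next
      if (d$class[j] != d$class[i] || d$image_id[j] != d$image_id[i]) next
      bi <- bbox(d$x_min[i], d$y_min[i], d$x_max[i], d$y_max[i])
      bj <- bbox(d$x_min[j], d$y_min[j], d$x_max[j], d$y_max[j])
      if (iou(bi, bj) > iou_threshold) keep[j] <- FALSE
    }
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Independent AP oracle: sum, over each true positive, the interpolated
## precision at its recall level (max precision over that rank or later),
## divided by the number of truths.
ap_oracle <- function(labels, n_truth) {
  if (n_truth == 0) return(if (length(labels)) 0 else NA_real_)
  if (!length(labels)) return(0)
  precision <- cumsum(labels) / seq_along(labels)
  total <- 0
  for (i in which(labels)) {
    total <- total + max(precision[i:length(labels)])
  }
  total / n_truth
}

## Max IoU of each detection against a set of truth boxes.
iou_one_many_fixture <- function(truths, dets) {
  tm <- cbind(truths$x_min, truths$y_min, truths$x_max, truths$y_max)
  vapply(seq_len(nrow(dets)), function(i) {
    max(cholescan:::iou_one_many(dets$x_min[i], dets$y_min[i],
                                 dets$x_max[i], dets$y_max[i], tm))
  }, 0)
}

## One-image detection set with configurable organ/stone confidences.
context_fixture <- function(stone_conf = 33, stone_class = "muddy_stone",
                            liver_conf = NULL, gall_conf = NULL,
                            image_id = "img") {
  d <- detections(image_id, stone_class, stone_conf, 60, 40, 75, 52)
  if (!is.null(liver_conf)) {
    d <- rbind(d, detections(image_id, "liver", liver_conf, 10, 10, 60, 60))
  }
  if (!is.null(gall_conf)) {
    d <- rbind(d, detections(image_id, "gall", gall_conf, 55, 30, 85, 55))
  }
  d
}
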