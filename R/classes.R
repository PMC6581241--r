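#' Object classes recognised by the pipeline
#'
#' The detector localises five object classes on abdominal CT-like slices:
#' the spine (a bright, stable landmark present on every slice), the liver,
#' the gallbladder ("gall", the container in which stones occur), and the
#' two stone types -- granular stones (bright, irregular) and muddy stones
#' (low-contrast gray, slightly darker than the gallbladder contents).
#'
#' Class indices are fixed for all on-disk formats: spine = 0, liver = 1,
#' gall = 2, granular_stone = 3, muddy_stone = 4.
#'
#' @return `cholescan_classes()` returns the character vector of the five
#'   class labels in index order.
#' @export
#' @examples
#' cholescan_classes()
cholescan_classes <- function() {
  c("spine", "liver", "gall", "granular_stone", "muddy_stone")
}

#' @rdname cholescan_classes
#' @return `stone_classes()` returns the labels of the two stone classes.
#' @export
stone_classes <- function() {
  c("granular_stone", "muddy_stone")
}

#' @rdname cholescan_classes
#' @param label character vector of class labels.
#' @return `class_index()` returns the 0-based integer index for each label.
#' @export
class_index <- function(label) {
  idx <- match(label, cholescan_classes()) - 1L
  if (anyNA(idx)) {
    stop("unknown class label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' @rdname cholescan_classes
#' @param index integer vector of 0-based class indices.
#' @return `class_label()` returns the label for each 0-based index.
#' @export
class_label <- function(index) {
  if (any(index < 0L | index > 4L | index != floor(index))) {
    stop("class index must be an integer in 0..4")
  }
  cholescan_classes()[index + 1L]
}

## Empty detection table: the common currency between detector, policy and
## evaluation. Confidence is in percent [0, 100].
empty_detections <- function() {
  data.frame(
    image_id = character(0), class = character(0),
    confidence = numeric(0),
    x_min = numeric(0), y_min = numeric(0),
    x_max = numeric(0), y_max = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Build a detection table
#'
#' Detections are plain data frames with one row per box: `image_id`,
#' `class` (one of [cholescan_classes()]), `confidence` in percent
#' \[0, 100\], and pixel corners `x_min`, `y_min`, `x_max`, `y_max`
#' (0-based, half-open).
#'
#' @param image_id character image identifiers (recycled).
#' @param class class labels.
#' @param confidence confidences in percent.
#' @param x_min,y_min,x_max,y_max box corners in pixels.
#' @return a detection data frame.
#' @export
#' @examples
#' detections("img1", "muddy_stone", 33, 10, 10, 30, 30)
detections <- function(image_id, class, confidence, x_min, y_min, x_max, y_max) {
  d <- data.frame(
    image_id = as.character(image_id), class = as.character(class),
    confidence = as.numeric(confidence),
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    stringsAsFactors = FALSE
  )
  validate_detections(d)
  d
}

validate_detections <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("image_id", "class", "confidence",
            "x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("detection table lacks column(s): ",
                         paste(miss, collapse = ", "))
  class_index(d$class)  # errors on unknown labels
  if (any(d$confidence < 0 | d$confidence > 100)) {
    stop("detection confidence must lie in [0, 100] percent")
  }
  if (nrow(d) && any(d$x_max <= d$x_min | d$y_max <= d$y_min)) {
    stop("degenerate detection box: x_max <= x_min or y_max <= y_min")
  }
  invisible(d)
}
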