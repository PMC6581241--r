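#' Write / read a phantom image as 8-bit grayscale PNG
#'
#' @param rec an `image_record`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_image_png <- function(rec, path) {
  png::writePNG(rec$pixels / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @param id image id to attach; defaults to the file name without
#'   extension.
#' @return `read_image_png()` returns an `image_record` without truth
#'   (attach annotations via [read_yolo_txt()] or [read_coco_json()]).
#' @export
read_image_png <- function(path, id = sub("\\.png$", "", basename(path))) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]   # tolerate gray+alpha
  rec <- list(id = id, width = ncol(px), height = nrow(px),
              pixels = matrix(as.integer(round(px * 255)), nrow(px), ncol(px)),
              truth = empty_truth())
  class(rec) <- "image_record"
  rec
}

#' YOLO-txt annotation format
#'
#' One line per object: `class_index x_centre y_centre width height`, all
#' normalized to \[0, 1\], with the fixed class indices spine=0, liver=1,
#' gall=2, granular_stone=3, muddy_stone=4. Conversion to pixel corners
#' uses the package's 0-based half-open convention, so write followed by
#' read is the identity to within 1e-6 normalized units.
#'
#' @param truth data frame with `class` and corner columns.
#' @param image_size square image side in pixels.
#' @param path file path.
#' @return `read_yolo_txt()` returns a truth data frame.
#' @export
write_yolo_txt <- function(truth, image_size, path) {
  lines <- character(nrow(truth))
  if (nrow(truth)) {
    xc <- (truth$x_min + truth$x_max) / 2 / image_size
    yc <- (truth$y_min + truth$y_max) / 2 / image_size
    w <- (truth$x_max - truth$x_min) / image_size
    h <- (truth$y_max - truth$y_min) / image_size
    lines <- sprintf("%d %.8f %.8f %.8f %.8f",
                     class_index(truth$class), xc, yc, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_txt
#' @export
read_yolo_txt <- function(path, image_size) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_truth())
  out <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (length(f) != 5L || anyNA(f)) {
      stop("malformed YOLO line ", i, " in ", path)
    }
    if (!(f[1L] %in% 0:4)) {
      stop("invalid class index ", f[1L], " on line ", i, " of ", path)
    }
    data.frame(class = class_label(f[1L]),
               x_min = (f[2L] - f[4L] / 2) * image_size,
               y_min = (f[3L] - f[5L] / 2) * image_size,
               x_max = (f[2L] + f[4L] / 2) * image_size,
               y_max = (f[3L] + f[5L] / 2) * image_size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

coco_categories <- function() {
  data.frame(id = 0:4, name = cholescan_classes(), stringsAsFactors = FALSE)
}

#' COCO-JSON annotations and detection lists
#'
#' Ground truth is written as a standard COCO file (`images`,
#' `annotations`, `categories`); detections carry a `score` field (in
#' percent here, matching the package's confidence convention). COCO
#' boxes are `[x, y, width, height]`; corners are recovered as
#' `(x, y, x + width, y + height)`. Category ids are the fixed class
#' indices 0..4. A file mixing scored and unscored annotations is
#' rejected.
#'
#' @param images list of `image_record`s (or a data frame with `id`,
#'   `width`, `height`).
#' @param path file path.
#' @param detections optional detection data frame to write instead of
#'   the images' truth tables.
#' @return `read_coco_json()` returns a list with `images` (data frame),
#'   `truth` or `detections` (data frame with `image_id`), `categories`.
#' @export
write_coco_json <- function(images, path, detections = NULL) {
  imgdf <- if (is.data.frame(images)) images else data.frame(
    id = vapply(images, `[[`, "", "id"),
    width = vapply(images, `[[`, 0L, "width"),
    height = vapply(images, `[[`, 0L, "height"),
    stringsAsFactors = FALSE)
  imgdf$file_name <- paste0(imgdf$id, ".png")
  if (is.null(detections)) {
    tr <- pool_truth(images)
    ann <- data.frame(
      id = seq_len(NROW(tr)), image_id = tr$image_id,
      category_id = class_index(tr$class),
      bbox = I(lapply(seq_len(NROW(tr)), function(i)
        c(tr$x_min[i], tr$y_min[i],
          tr$x_max[i] - tr$x_min[i], tr$y_max[i] - tr$y_min[i]))),
      area = (tr$x_max - tr$x_min) * (tr$y_max - tr$y_min),
      iscrowd = 0L, stringsAsFactors = FALSE)
  } else {
    validate_detections(detections)
    d <- detections
    ann <- data.frame(
      id = seq_len(NROW(d)), image_id = d$image_id,
      category_id = class_index(d$class),
      bbox = I(lapply(seq_len(NROW(d)), function(i)
        c(d$x_min[i], d$y_min[i],
          d$x_max[i] - d$x_min[i], d$y_max[i] - d$y_min[i]))),
      score = d$confidence, stringsAsFactors = FALSE)
  }
  obj <- list(images = imgdf, annotations = ann,
              categories = coco_categories())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_json
#' @export
read_coco_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("images", "annotations", "categories")) {
    if (is.null(obj[[f]])) stop("not a COCO file: missing '", f, "' in ", path)
  }
  cats <- obj$categories
  known <- coco_categories()
  if (!all(cats$id %in% known$id) ||
      !all(known$name[match(cats$id, known$id)] == cats$name)) {
    stop("unknown or mismatched category table in ", path)
  }
  ann <- obj$annotations
  has_score <- "score" %in% names(ann) & !all(is.na(ann$score))
  if ("score" %in% names(ann) && anyNA(ann$score) && !all(is.na(ann$score))) {
    stop("file mixes scored detections and unscored annotations: ", path)
  }
  if (NROW(ann)) {
    if (!all(ann$category_id %in% known$id)) {
      stop("unknown category id in ", path)
    }
    bb <- if (is.list(ann$bbox)) do.call(rbind, ann$bbox) else ann$bbox
    tab <- data.frame(
      image_id = as.character(ann$image_id),
      class = class_label(ann$category_id),
      x_min = bb[, 1L], y_min = bb[, 2L],
      x_max = bb[, 1L] + bb[, 3L], y_max = bb[, 2L] + bb[, 4L],
      stringsAsFactors = FALSE)
    if (has_score) tab$confidence <- ann$score
  } else {
    tab <- cbind(empty_truth(), image_id = character(0))
  }
  out <- list(images = obj$images, categories = known)
  if (has_score) {
    out$detections <- tab[, c("image_id", "class", "confidence",
                              "x_min", "y_min", "x_max", "y_max")]
  } else {
    out$truth <- tab
  }
  out
}

#' Save / load a trained model
#'
#' Weights are serialized as a plain R list via RDS; a convenience for
#' the command-line pipeline, not an interchange format.
#'
#' @param model a `cholescan_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  class(model) <- "cholescan_model"
  model
}

#' Write a dataset to a directory (PNG + YOLO-txt + COCO-JSON)
#'
#' Emits `<id>.png` and `<id>.txt` per image plus one
#' `annotations.json` COCO file covering the whole set.
#'
#' @param dataset list of `image_record`s.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in dataset) {
    write_image_png(rec, file.path(dir, paste0(rec$id, ".png")))
    write_yolo_txt(rec$truth, rec$width, file.path(dir, paste0(rec$id, ".txt")))
  }
  write_coco_json(dataset, file.path(dir, "annotations.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @return `read_dataset()` returns the list of `image_record`s found in
#'   `dir` (PNG plus YOLO-txt sidecar annotations).
#' @export
read_dataset <- function(dir) {
  pngs <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(pngs, function(p) {
    rec <- read_image_png(p)
    side <- file.path(dir, paste0(rec$id, ".txt"))
    if (file.exists(side)) rec$truth <- read_yolo_txt(side, rec$width)
    rec
  })
}

#' Read a run configuration file
#'
#' A YAML file with optional sections `phantom`, `net`, `train`,
#' `policy`, `evaluation` plus top-level `seed`; every present key
#' overrides the corresponding constructor default, so an empty file is a
#' valid full default configuration.
#'
#' @param path YAML file path; NULL for all defaults.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return list with `phantom_args`, `net`, `train`, `policy`,
#'   `evaluation` (list), `seed`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) raw[[parts[1L]]][[parts[2L]]] <- overrides[[nm]]
    else raw[[nm]] <- overrides[[nm]]
  }
  build <- function(fun, args) {
    args <- as.list(args)
    args <- args[!duplicated(names(args))]  # a section's own key wins
    do.call(fun, args[names(args) %in% names(formals(fun))])
  }
  list(
    phantom_args = raw$phantom,
    net = build(net_config, c(raw$net, if (!is.null(raw$seed))
      list(seed = raw$seed))),
    train = build(train_config, c(raw$train, if (!is.null(raw$seed))
      list(seed = raw$seed))),
    policy = build(policy_config, raw$policy),
    evaluation = c(list(iou_threshold = 0.5, k = 3L), raw$evaluation),
    seed = if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  )
}
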