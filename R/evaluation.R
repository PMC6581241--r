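#' Greedy detection-to-truth matching
#'
#' Detections are visited in order of descending confidence (ties broken
#' by input order). Each detection is matched to the not-yet-matched truth
#' object of the same class and image with the highest IoU, provided that
#' IoU reaches `iou_threshold`; a truth object can yield at most one true
#' positive.
#'
#' @param dets detection data frame; may span several images.
#' @param truths truth data frame with columns `image_id`, `class` and the
#'   four corner columns (an `image_record$truth` gains `image_id`
#'   automatically via [pool_truth()]).
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return `dets` sorted in the visiting order with a logical `tp` column.
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  validate_detections(dets)
  if (is.null(truths$image_id)) truths$image_id <- dets$image_id[1L]
  o <- order(-dets$confidence, seq_len(nrow(dets)))
  d <- dets[o, , drop = FALSE]
  d$tp <- FALSE
  used <- logical(nrow(truths))
  tm <- cbind(truths$x_min, truths$y_min, truths$x_max, truths$y_max)
  for (i in seq_len(nrow(d))) {
    cand <- which(!used & truths$class == d$class[i] &
                    truths$image_id == d$image_id[i])
    if (!length(cand)) next
    ov <- iou_one_many(d$x_min[i], d$y_min[i], d$x_max[i], d$y_max[i],
                       tm[cand, , drop = FALSE])
    j <- which.max(ov)
    if (ov[j] >= iou_threshold) {
      d$tp[i] <- TRUE
      used[cand[j]] <- TRUE
    }
  }
  rownames(d) <- NULL
  d
}

#' Average precision from ranked TP/FP labels
#'
#' Area under the precision-recall curve for one class, with detections
#' already ranked by descending confidence. The default integrates the
#' monotone (right-envelope) interpolated curve at every distinct recall
#' value; `interpolation = "11point"` averages the interpolated precision
#' at recalls 0, 0.1, ..., 1 instead.
#'
#' @param labels logical vector: TRUE for a true positive, in rank order.
#' @param n_truth number of truth objects of the class.
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP in \[0, 1\]; 0 when `n_truth` is 0 but detections exist; NA
#'   when there are neither truths nor detections.
#' @export
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), 2)
average_precision <- function(labels, n_truth,
                              interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (n_truth < 0) stop("n_truth must be >= 0")
  if (n_truth == 0) return(if (length(labels)) 0 else NA_real_)
  if (!length(labels)) return(0)
  tp <- cumsum(labels)
  fp <- cumsum(!labels)
  precision <- tp / (tp + fp)
  recall <- tp / n_truth
  # monotone envelope: best precision at this recall or beyond
  env <- rev(cummax(rev(precision)))
  if (interpolation == "11point") {
    return(mean(vapply(seq(0, 1, 0.1), function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(precision[ok]) else 0
    }, 0)))
  }
  sum(diff(c(0, recall)) * env)
}

#' Pool truth tables from a list of image records
#'
#' @param images list of `image_record`s.
#' @return one data frame with an `image_id` column.
#' @export
pool_truth <- function(images) {
  do.call(rbind, lapply(images, function(rec) {
    t <- rec$truth
    if (nrow(t)) cbind(image_id = rec$id, t, stringsAsFactors = FALSE)
    else cbind(image_id = character(0), t)
  }))
}

#' Evaluate detections against truth: per-class AP, mAP(all), mAP(stones)
#'
#' Average precision is computed per class over the pooled detections of
#' all images. `mAP_all` is the mean over the five class APs and
#' `mAP_stones` the mean over the granular and muddy stone APs only (the
#' cholelithiasis-identification figure of merit). A class with neither
#' truths nor detections has undefined AP and is excluded from the means
#' with a warning. APs are carried at full precision, in percent;
#' rounding is display-only.
#'
#' @param dets pooled detection data frame.
#' @param truths pooled truth data frame (see [pool_truth()]).
#' @param iou_threshold matching IoU (default 0.5).
#' @param n_images number of images evaluated (recorded in the report).
#' @param interpolation passed to [average_precision()].
#' @return a list of class `eval_report`: `per_class` (named percent
#'   vector), `mAP_all`, `mAP_stones`, `n_images`, `iou_threshold`.
#' @export
evaluate_detections <- function(dets, truths, iou_threshold = 0.5,
                                n_images = length(unique(c(dets$image_id,
                                                           truths$image_id))),
                                interpolation = "all") {
  validate_detections(dets)
  per <- stats::setNames(rep(NA_real_, 5L), cholescan_classes())
  for (cl in cholescan_classes()) {
    dcl <- dets[dets$class == cl, , drop = FALSE]
    ntr <- sum(truths$class == cl)
    if (ntr == 0L && nrow(dcl) == 0L) next
    m <- match_detections(dcl, truths[truths$class == cl, , drop = FALSE],
                          iou_threshold)
    per[cl] <- 100 * average_precision(m$tp, ntr, interpolation)
  }
  if (anyNA(per)) {
    warning("AP undefined (no truths, no detections) for: ",
            paste(names(per)[is.na(per)], collapse = ", "),
            "; excluded from means")
  }
  report <- list(per_class = per,
                 mAP_all = mean(per, na.rm = TRUE),
                 mAP_stones = mean(per[stone_classes()], na.rm = TRUE),
                 n_images = n_images,
                 iou_threshold = iou_threshold)
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat("<eval_report>\n")
  print(round(x$per_class, digits))
  cat(sprintf("mAP(all) %.2f%%  mAP(stones) %.2f%%  (%d images, IoU %.2f)\n",
              x$mAP_all, x$mAP_stones, x$n_images, x$iou_threshold))
  invisible(x)
}

#' Average evaluation reports over folds
#'
#' Arithmetic mean of every AP column and of the two mAP summaries, at
#' full precision (rounding only at display time). NA cells (undefined
#' APs) are excluded column-wise.
#'
#' @param reports non-empty list of `eval_report`s.
#' @return an averaged `eval_report`.
#' @export
aggregate_folds <- function(reports) {
  if (!length(reports)) stop("need at least one report to aggregate")
  per <- rowMeans(sapply(reports, `[[`, "per_class"), na.rm = TRUE)
  out <- list(per_class = per,
              mAP_all = mean(vapply(reports, `[[`, 0, "mAP_all"),
                             na.rm = TRUE),
              mAP_stones = mean(vapply(reports, `[[`, 0, "mAP_stones"),
                                na.rm = TRUE),
              n_images = sum(vapply(reports, `[[`, 0, "n_images")),
              iou_threshold = reports[[1L]]$iou_threshold)
  class(out) <- "eval_report"
  out
}

#' Balanced random fold assignment
#'
#' @param n number of images.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of fold labels in 1..k; fold sizes differ by at
#'   most 1.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k must not exceed the dataset size")
  base <- rep(seq_len(k), length.out = n)
  with_seed(seed, sample(base))
}

## Tables 1-2 column order of the cross-validation report.
report_row <- function(rep) {
  data.frame(liver = rep$per_class[["liver"]],
             gall = rep$per_class[["gall"]],
             granular_stone = rep$per_class[["granular_stone"]],
             muddy_stone = rep$per_class[["muddy_stone"]],
             spine = rep$per_class[["spine"]],
             mAP_all = rep$mAP_all, mAP_stones = rep$mAP_stones)
}

#' k-fold cross-validation of the detector, with and without the policy
#'
#' For each fold, trains the detector on the remaining folds and
#' evaluates the held-out images twice: on the raw detections and on the
#' policy-adjusted output. Also counts held-out negative images (no stone
#' truth) with stone false positives above the output threshold, before
#' and after the policy.
#'
#' @param dataset list of `image_record`s.
#' @param k number of folds.
#' @param net a [net_config()].
#' @param tc a [train_config()].
#' @param policy a [policy_config()].
#' @param seed seed for the fold assignment.
#' @param iou_threshold evaluation matching IoU.
#' @param conf_floor floor (percent) for collecting raw detections; kept
#'   low so the precision-recall curve is well resolved.
#' @return a list of class `cv_result`: `folds` (assignment), `raw` and
#'   `policy` (per-fold `eval_report` lists), `table_raw`, `table_policy`
#'   (data frames shaped like the per-fold report with an average row),
#'   `negatives` (per-fold false-positive image counts before/after the
#'   policy).
#' @export
cross_validate <- function(dataset, k, net = net_config(),
                           tc = train_config(), policy = policy_config(),
                           seed = 1L, iou_threshold = 0.5, conf_floor = 1) {
  n <- length(dataset)
  if (k > n) stop("k must not exceed the dataset size")
  folds <- make_folds(n, k, seed)
  raw_reports <- list(); pol_reports <- list()
  negatives <- data.frame(fold = integer(0), n_negative = integer(0),
                          fp_raw = integer(0), fp_policy = integer(0))
  for (f in seq_len(k)) {
    train_set <- dataset[folds != f]
    test_set <- dataset[folds == f]
    model <- train_detector(train_set, net, tc)
    dets_raw <- list(); dets_pol <- list()
    fp_raw <- 0L; fp_pol <- 0L; n_neg <- 0L
    for (rec in test_set) {
      d <- detect(model, rec, conf_floor = conf_floor)
      p <- apply_policy(d, policy)
      dets_raw[[length(dets_raw) + 1L]] <- d
      dets_pol[[length(dets_pol) + 1L]] <- p
      if (!any(rec$truth$class %in% stone_classes())) {
        n_neg <- n_neg + 1L
        if (any(d$class %in% stone_classes() &
                d$confidence > policy$output_threshold)) fp_raw <- fp_raw + 1L
        if (any(p$class %in% stone_classes())) fp_pol <- fp_pol + 1L
      }
    }
    truths <- pool_truth(test_set)
    raw_reports[[f]] <- evaluate_detections(
      do.call(rbind, dets_raw), truths, iou_threshold,
      n_images = length(test_set))
    pol_reports[[f]] <- evaluate_detections(
      do.call(rbind, dets_pol), truths, iou_threshold,
      n_images = length(test_set))
    negatives <- rbind(negatives, data.frame(
      fold = f, n_negative = n_neg, fp_raw = fp_raw, fp_policy = fp_pol))
  }
  mk_table <- function(reports) {
    tab <- do.call(rbind, lapply(reports, report_row))
    tab <- rbind(tab, report_row(aggregate_folds(reports)))
    cbind(fold = c(as.character(seq_along(reports)), "average"), tab)
  }
  out <- list(folds = folds, raw = raw_reports, policy = pol_reports,
              table_raw = mk_table(raw_reports),
              table_policy = mk_table(pol_reports),
              negatives = negatives)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation, policy-adjusted output:\n")
  print(x$table_policy, digits = 4)
  cat("Negative-image false positives per fold (raw vs policy):\n")
  print(x$negatives)
  invisible(x)
}

#' Write a cross-validation table as tab-separated text
#'
#' Columns follow the conventional report order: liver, gall, granular
#' stone, muddy stone, spine, mAP(all), mAP(stones).
#'
#' @param tab a table from [cross_validate()] (`table_raw`/`table_policy`).
#' @param path output file.
#' @export
write_cv_tsv <- function(tab, path) {
  utils::write.table(format(tab, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Curate slices: keep images where both liver and gall are detected
#'
#' The pre-processing stage of the pipeline: out of a stack of slices,
#' keep those on which the detector finds both a liver and a gallbladder
#' at the presence threshold -- the slices on which stone identification
#' is meaningful. When truth is available, reports selection precision
#' and recall against the truth flag "image contains both liver and
#' gall".
#'
#' @param images list of `image_record`s.
#' @param model a trained `cholescan_model` (or NULL when `detections`
#'   are supplied).
#' @param presence_threshold percent.
#' @param detections optional precomputed raw detections data frame.
#' @return list of class `curation_report`: `selected` (logical per
#'   image), `ids`, `precision`, `recall`, `n_selected`.
#' @export
curate_slices <- function(images, model = NULL, presence_threshold = 25,
                          detections = NULL) {
  ids <- vapply(images, `[[`, "", "id")
  if (is.null(detections)) {
    if (is.null(model)) stop("supply either a model or precomputed detections")
    detections <- do.call(rbind, lapply(images, function(rec)
      detect(model, rec, conf_floor = 0)))
  }
  cfg <- policy_config(presence_threshold = presence_threshold)
  selected <- vapply(seq_along(images), function(i) {
    d <- detections[detections$image_id == ids[i], , drop = FALSE]
    ctx <- assess_context(d, cfg)
    ctx$liver_present && ctx$gall_present
  }, TRUE)
  truth_flag <- vapply(images, function(rec) {
    all(c("liver", "gall") %in% rec$truth$class)
  }, TRUE)
  tp <- sum(selected & truth_flag)
  res <- list(selected = selected, ids = ids,
              n_selected = sum(selected),
              precision = if (sum(selected)) tp / sum(selected) else NA_real_,
              recall = if (sum(truth_flag)) tp / sum(truth_flag) else NA_real_)
  class(res) <- "curation_report"
  res
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(
    "<curation_report: %d/%d selected, precision %.3f, recall %.3f>\n",
    x$n_selected, length(x$ids), x$precision, x$recall))
  invisible(x)
}
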