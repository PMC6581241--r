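#' Anatomical-context confidence policy configuration
#'
#' Gallstones only occur inside the gallbladder, next to the liver, so the
#' credibility of a stone detection depends on whether those organs were
#' co-detected on the same slice. The policy rescales every stone
#' confidence `c` to `c' = min(100, c * w)` with the weight chosen by
#' context:
#'
#' * R1 -- liver and gall both present: `w_both` (boost, capped at 100%);
#' * R2 -- gall present, liver absent: `w_gall_only` (unchanged or a
#'   slight decrease);
#' * R3 -- liver present, gall absent: `w_liver_only` (a clear reduction,
#'   but never to zero; default 0.6);
#' * R4 -- neither present: the confidence is set to zero outright.
#'
#' A box is output only if its (adjusted) confidence exceeds
#' `output_threshold` (default 25%). Organ presence is judged against
#' `presence_threshold`, which defaults to the output threshold.
#'
#' @param w_both,w_gall_only,w_liver_only rule weights; must satisfy
#'   `0 <= w_liver_only <= w_gall_only <= w_both`.
#' @param output_threshold percent; a detection is output iff its adjusted
#'   confidence is strictly greater.
#' @param presence_threshold percent; an organ counts as present iff some
#'   detection of it reaches this confidence.
#' @param require_containment if TRUE, a stone whose centre lies outside
#'   the best gall box is treated as if the gall were absent (R3 when the
#'   liver is present, else R4).
#' @return a list of class `policy_config`.
#' @export
#' @examples
#' cfg <- policy_config()
#' cfg$w_liver_only  # 0.6
policy_config <- function(w_both = 1.2, w_gall_only = 1.0,
                          w_liver_only = 0.6, output_threshold = 25,
                          presence_threshold = output_threshold,
                          require_containment = FALSE) {
  if (!(0 <= w_liver_only && w_liver_only <= w_gall_only &&
        w_gall_only <= w_both)) {
    stop("rule weights must satisfy 0 <= w_liver_only <= w_gall_only ",
         "<= w_both")
  }
  if (output_threshold < 0 || output_threshold > 100 ||
      presence_threshold < 0 || presence_threshold > 100) {
    stop("thresholds must lie in [0, 100] percent")
  }
  cfg <- list(w_both = w_both, w_gall_only = w_gall_only,
              w_liver_only = w_liver_only,
              output_threshold = output_threshold,
              presence_threshold = presence_threshold,
              require_containment = isTRUE(require_containment))
  class(cfg) <- "policy_config"
  cfg
}

#' Assess the anatomical context of one image's detections
#'
#' @param dets post-NMS detection data frame for a single image.
#' @param cfg a [policy_config()].
#' @return a list of class `context_assessment`: `liver_present`,
#'   `gall_present`, `gall_bbox` (corners of the highest-confidence gall
#'   detection at or above the presence threshold, or NULL), and
#'   `contained` (named by stone row index: is the stone centre inside
#'   `gall_bbox`).
#' @export
assess_context <- function(dets, cfg = policy_config()) {
  validate_detections(dets)
  th <- cfg$presence_threshold
  livers <- dets[dets$class == "liver" & dets$confidence >= th, , drop = FALSE]
  galls <- dets[dets$class == "gall" & dets$confidence >= th, , drop = FALSE]
  gall_bbox <- NULL
  if (nrow(galls)) {
    best <- which.max(galls$confidence)
    gall_bbox <- c(x_min = galls$x_min[best], y_min = galls$y_min[best],
                   x_max = galls$x_max[best], y_max = galls$y_max[best])
  }
  stone_rows <- which(dets$class %in% stone_classes())
  contained <- logical(length(stone_rows))
  if (!is.null(gall_bbox) && length(stone_rows)) {
    cx <- (dets$x_min[stone_rows] + dets$x_max[stone_rows]) / 2
    cy <- (dets$y_min[stone_rows] + dets$y_max[stone_rows]) / 2
    contained <- cx >= gall_bbox[["x_min"]] & cx <= gall_bbox[["x_max"]] &
      cy >= gall_bbox[["y_min"]] & cy <= gall_bbox[["y_max"]]
  }
  names(contained) <- stone_rows
  out <- list(liver_present = nrow(livers) > 0L,
              gall_present = nrow(galls) > 0L,
              gall_bbox = gall_bbox, contained = contained)
  class(out) <- "context_assessment"
  out
}

policy_weight <- function(liver, gall, cfg) {
  if (liver && gall) cfg$w_both
  else if (gall) cfg$w_gall_only
  else if (liver) cfg$w_liver_only
  else 0
}

#' Apply the confidence-setting policy to one image's detections
#'
#' Stone confidences are rescaled by the context rule (see
#' [policy_config()]); boxes, class labels and non-stone confidences are
#' never altered. The returned table contains exactly the detections
#' whose adjusted confidence exceeds the output threshold, with stones
#' carrying their adjusted confidence. Apply exactly once per image: the
#' policy is a final output decision, not an idempotent filter.
#'
#' @param dets post-NMS detection data frame for a single image.
#' @param cfg a [policy_config()].
#' @return the output detection data frame; the full pre-threshold table
#'   with adjusted confidences is attached as attribute `"adjusted"`, the
#'   [assess_context()] result as attribute `"assessment"`.
#' @export
#' @examples
#' d <- rbind(
#'   detections("img", "liver", 90, 10, 10, 80, 80),
#'   detections("img", "muddy_stone", 33, 40, 40, 55, 52)
#' )
#' apply_policy(d, policy_config())  # 33 * 0.6 = 19.8 < 25: suppressed
apply_policy <- function(dets, cfg = policy_config()) {
  validate_detections(dets)
  if (length(unique(dets$image_id)) > 1L) {
    stop("apply_policy works on one image at a time; split by image_id")
  }
  ctx <- assess_context(dets, cfg)
  adj <- dets
  stone_rows <- which(dets$class %in% stone_classes())
  for (i in seq_along(stone_rows)) {
    r <- stone_rows[i]
    gall_here <- ctx$gall_present &&
      (!cfg$require_containment || isTRUE(ctx$contained[[i]]))
    w <- policy_weight(ctx$liver_present, gall_here, cfg)
    adj$confidence[r] <- min(100, dets$confidence[r] * w)
  }
  out <- adj[adj$confidence > cfg$output_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "adjusted") <- adj
  attr(out, "assessment") <- ctx
  out
}

#' Audit the policy on negative images
#'
#' A negative sample is an image whose truth contains no stone; any stone
#' box output on it is a misjudgement. The audit counts images misjudged
#' by the raw detector (any stone detection above the output threshold)
#' and after the policy, which can only be fewer or equal.
#'
#' @param images list of `image_record`s, all without stone truth objects.
#' @param model a trained `cholescan_model`, used to produce raw
#'   detections when `detections` is not supplied.
#' @param detections optional precomputed raw (pre-policy, post-NMS)
#'   detections: a single data frame covering the images by `image_id`.
#' @param cfg a [policy_config()].
#' @return a list of class `negative_audit`: `n_images`,
#'   `n_misjudged_raw`, `n_misjudged_after_policy`, and a per-image data
#'   frame `per_image`.
#' @export
audit_negatives <- function(images, model = NULL, detections = NULL,
                            cfg = policy_config()) {
  for (rec in images) {
    if (any(rec$truth$class %in% stone_classes())) {
      stop("image ", rec$id, " contains stone truth: not a negative sample")
    }
  }
  ids <- vapply(images, `[[`, "", "id")
  if (is.null(detections)) {
    if (is.null(model)) stop("supply either a model or precomputed detections")
    detections <- do.call(rbind, lapply(images, function(rec)
      detect(model, rec, conf_floor = 0)))
  }
  validate_detections(detections)
  per <- data.frame(image_id = ids, raw = FALSE, after = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    d <- detections[detections$image_id == ids[i], , drop = FALSE]
    stones_raw <- d$class %in% stone_classes() &
      d$confidence > cfg$output_threshold
    per$raw[i] <- any(stones_raw)
    out <- apply_policy(d, cfg)
    per$after[i] <- any(out$class %in% stone_classes())
  }
  res <- list(n_images = length(ids),
              n_misjudged_raw = sum(per$raw),
              n_misjudged_after_policy = sum(per$after),
              per_image = per)
  class(res) <- "negative_audit"
  res
}

#' @export
print.negative_audit <- function(x, ...) {
  cat(sprintf(
    "<negative_audit: %d images, misjudged raw %d, after policy %d>\n",
    x$n_images, x$n_misjudged_raw, x$n_misjudged_after_policy))
  invisible(x)
}

#' Write a negative-sample audit as tab-separated text
#'
#' @param audit a `negative_audit`.
#' @param path output file.
#' @export
write_audit_tsv <- function(audit, path) {
  utils::write.table(audit$per_image, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
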