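#' Training configuration
#'
#' Standard single-stage loss: squared error on the sigmoid-squashed
#' centre offsets and raw log-space sizes at responsible anchors, binary
#' cross-entropy on objectness everywhere (anchors whose prior overlaps a
#' truth box above `ignore_iou` are excluded unless responsible), and
#' binary cross-entropy on the five independent class scores at
#' responsible anchors.
#'
#' @param epochs passes over the training set.
#' @param batch_size images per gradient step.
#' @param lr Adam learning rate.
#' @param w_box,w_obj,w_class loss-component weights.
#' @param w_noobj multiplier (within `w_obj`) for the objectness loss at
#'   cells with no object, so the many empty cells do not swamp the few
#'   responsible ones.
#' @param class_weights named per-class multipliers applied to the box,
#'   class and positive-objectness losses at responsible anchors.
#' @param augment_flips train on random horizontal/vertical flips of each
#'   image (targets flipped accordingly); quadruples the effective data
#'   diversity at no per-epoch cost.
#' @param ignore_iou prior/truth IoU above which a non-responsible anchor
#'   is excluded from the objectness loss.
#' @param seed integer seed for shuffling.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, lr = 2e-3,
                         w_box = 5, w_obj = 2, w_class = 1, w_noobj = 0.3,
                         class_weights = NULL, augment_flips = TRUE,
                         ignore_iou = 0.5, seed = 1L) {
  tc <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
             lr = lr, w_box = w_box, w_obj = w_obj, w_class = w_class,
             w_noobj = w_noobj, class_weights = class_weights,
             augment_flips = isTRUE(augment_flips),
             ignore_iou = ignore_iou, seed = as.integer(seed))
  if (any(unlist(tc[c("epochs", "batch_size", "lr", "w_box", "w_obj",
                      "w_class", "w_noobj", "ignore_iou")]) <= 0)) {
    stop("all train_config values must be positive")
  }
  class(tc) <- "train_config"
  tc
}

## Flip an image record horizontally and/or vertically, truth included.
flip_record <- function(rec, h = FALSE, v = FALSE) {
  px <- rec$pixels
  t <- rec$truth
  if (h) {
    px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
    x0 <- rec$width - t$x_max
    t$x_max <- rec$width - t$x_min
    t$x_min <- x0
  }
  if (v) {
    px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
    y0 <- rec$height - t$y_max
    t$y_max <- rec$height - t$y_min
    t$y_min <- y0
  }
  rec$pixels <- px
  rec$truth <- t
  rec
}

## Anchor-prior IoU on width/height only (boxes co-centred).
wh_iou <- function(w, h, pw, ph) {
  inter <- pmin(w, pw) * pmin(h, ph)
  inter / (w * h + pw * ph - inter)
}

#' Build regression/objectness/class targets for one image
#'
#' Each truth box is assigned to the grid cell containing its centre and
#' to the anchor whose prior shape has the highest IoU with the box (ties
#' broken by the smallest anchor index). Later truth rows win cell/anchor
#' collisions.
#'
#' @param truth truth data frame (`class`, corner columns).
#' @param image_size image side in pixels.
#' @param grid_size cells per side.
#' @param anchors 3x2 anchor matrix in cell units.
#' @param ignore_iou see [train_config()].
#' @param ignore_truth truth table used for the ignore mask; defaults to
#'   `truth`, but with several detection scales the full table is passed
#'   here while responsibility is restricted to the boxes this scale owns,
#'   so cells over unassigned objects are neither punished nor rewarded.
#' @return a list: `obj` and `ignore` (`grid_size^2` x 3 matrices), `resp`
#'   (data frame of responsible entries: cell row `p`, anchor `a`, offsets
#'   `ox, oy`, log-size targets `twt, tht`, 1-based class `cls`).
#' @export
build_targets <- function(truth, image_size, grid_size, anchors,
                          ignore_iou = 0.5, ignore_truth = truth) {
  g <- grid_size
  obj <- matrix(0, g * g, 3L)
  ignore <- matrix(FALSE, g * g, 3L)
  hard <- matrix(FALSE, g * g, 3L)
  resp <- list()
  soft <- list()
  if (nrow(ignore_truth)) {
    iw <- (ignore_truth$x_max - ignore_truth$x_min) / image_size * g
    ih <- (ignore_truth$y_max - ignore_truth$y_min) / image_size * g
    ibx <- (ignore_truth$x_min + ignore_truth$x_max) / 2 / image_size * g
    iby <- (ignore_truth$y_min + ignore_truth$y_max) / 2 / image_size * g
    cell_cx <- (rep(seq_len(g) - 1L, each = g)) + 0.5  # column-major order
    cell_cy <- (rep(seq_len(g) - 1L, times = g)) + 0.5
    for (a in 1:3) {
      pw <- anchors[a, 1L]; ph <- anchors[a, 2L]
      for (t in seq_len(nrow(ignore_truth))) {
        ix <- pmin(cell_cx + pw / 2, ibx[t] + iw[t] / 2) -
          pmax(cell_cx - pw / 2, ibx[t] - iw[t] / 2)
        iy <- pmin(cell_cy + ph / 2, iby[t] + ih[t] / 2) -
          pmax(cell_cy - ph / 2, iby[t] - ih[t] / 2)
        inter <- pmax(ix, 0) * pmax(iy, 0)
        ov <- inter / (pw * ph + iw[t] * ih[t] - inter)
        ignore[ov > ignore_iou, a] <- TRUE
        # cells whose prior touches a truth box are the hard negatives
        # (organ interiors): they keep full objectness weight
        hard[ov > 0, a] <- TRUE
      }
    }
  }
  if (nrow(truth)) {
    # cell-unit truth geometry
    w <- (truth$x_max - truth$x_min) / image_size * g
    h <- (truth$y_max - truth$y_min) / image_size * g
    bx <- (truth$x_min + truth$x_max) / 2 / image_size * g
    by <- (truth$y_min + truth$y_max) / 2 / image_size * g
    cx <- pmin(floor(bx), g - 1L)
    cy <- pmin(floor(by), g - 1L)
    p <- cx * g + cy + 1L
    cls <- class_index(truth$class) + 1L

    cell_cx <- (rep(seq_len(g) - 1L, each = g)) + 0.5  # column-major order
    cell_cy <- (rep(seq_len(g) - 1L, times = g)) + 0.5
    eps <- 1e-7
    for (t in seq_len(nrow(truth))) {
      ious <- wh_iou(w[t], h[t], anchors[, 1L], anchors[, 2L])
      a <- which.max(ious)  # ties: smallest index (which.max convention)
      # a box spanning several cells: same-anchor cells under or touching
      # the box see near-identical features as the centre cell, so they
      # are ignored rather than punished (the centre cell alone stays
      # responsible); the margin is half a cell beyond the box
      under <- abs(cell_cx - bx[t]) < w[t] / 2 + 0.5 &
        abs(cell_cy - by[t]) < h[t] / 2 + 0.5
      ignore[under, a] <- TRUE
      # class identity is well defined across the whole box: train the
      # class scores (not objectness) of every covered cell, so that a
      # spurious firing inside the box at least carries the right label
      # and is then merged away by class-wise NMS
      soft[[length(soft) + 1L]] <- data.frame(
        p = which(under), a = a, cls = cls[t])
      obj[p[t], a] <- 1
      resp[[length(resp) + 1L]] <- data.frame(
        p = p[t], a = a,
        ox = min(max(bx[t] - cx[t], eps), 1 - eps),
        oy = min(max(by[t] - cy[t], eps), 1 - eps),
        twt = log(w[t] / anchors[a, 1L]),
        tht = log(h[t] / anchors[a, 2L]),
        # emphasise small boxes: 2 - normalized area, the usual heuristic
        bscale = 2 - (w[t] * h[t]) / (g * g),
        cls = cls[t])
    }
  }
  resp <- if (length(resp)) do.call(rbind, resp) else
    data.frame(p = integer(0), a = integer(0), ox = numeric(0),
               oy = numeric(0), twt = numeric(0), tht = numeric(0),
               bscale = numeric(0), cls = integer(0))
  # drop duplicate (p, a) assignments: the last truth wins
  if (nrow(resp) > 1L) {
    resp <- resp[!duplicated(resp[, c("p", "a")], fromLast = TRUE), ,
                 drop = FALSE]
  }
  soft <- if (length(soft)) do.call(rbind, soft) else
    data.frame(p = integer(0), a = integer(0), cls = integer(0))
  if (nrow(soft) > 1L) {
    soft <- soft[!duplicated(soft[, c("p", "a")], fromLast = TRUE), ,
                 drop = FALSE]
  }
  # responsible anchors are never ignored
  if (nrow(resp)) ignore[cbind(resp$p, resp$a)] <- FALSE
  list(obj = obj, ignore = ignore, hard = hard, resp = resp, soft = soft)
}

## Assign each truth box to exactly one detection scale: the scale whose
## best anchor prior has the highest IoU with the box (ties favour the
## coarser scale). Without unique ownership both heads would emit a
## confident box per object, and small-box duplicates survive NMS as
## false positives.
build_targets_multi <- function(truth, image_size, scales, anchors,
                                ignore_iou = 0.5) {
  if (length(scales) == 1L) {
    return(list(build_targets(truth, image_size, scales, anchors,
                              ignore_iou)))
  }
  best_scale <- integer(nrow(truth))
  if (nrow(truth)) {
    for (t in seq_len(nrow(truth))) {
      score <- vapply(scales, function(g) {
        w <- (truth$x_max[t] - truth$x_min[t]) / image_size * g
        h <- (truth$y_max[t] - truth$y_min[t]) / image_size * g
        max(wh_iou(w, h, anchors[, 1L], anchors[, 2L]))
      }, 0)
      best_scale[t] <- which.max(score)
    }
  }
  lapply(seq_along(scales), function(si) {
    build_targets(truth[best_scale == si, , drop = FALSE], image_size,
                  scales[si], anchors, ignore_iou, ignore_truth = truth)
  })
}

## Numerically stable binary cross-entropy with logits.
## y in {0,1}: bce = max(z,0) - z*y + log1p(exp(-|z|))
bce_logits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

#' Loss components for one image
#'
#' @param raw raw head output, a `grid^2` x 30 matrix (per anchor block:
#'   tx, ty, tw, th, objectness, 5 class logits), or the list returned by
#'   the internal forward pass.
#' @param targets result of [build_targets()].
#' @param tc a [train_config()] (supplies the loss weights).
#' @return list with `box`, `objectness`, `class`, `total` (all >= 0).
#' @export
compute_loss <- function(raw, targets, tc = train_config()) {
  if (is.list(raw)) raw <- raw$head1
  if (!all(is.finite(raw))) stop("non-finite network outputs")
  lg <- loss_and_grad(raw, targets, tc)
  lg[c("box", "objectness", "class", "total")]
}

loss_and_grad <- function(raw, targets, tc) {
  n <- nrow(raw)
  grad <- matrix(0, n, ncol(raw))
  l_box <- 0; l_obj <- 0; l_cls <- 0
  resp <- targets$resp
  cw <- stats::setNames(rep(1, 5), cholescan_classes())
  if (!is.null(tc$class_weights)) {
    cw[names(tc$class_weights)] <- tc$class_weights
  }
  for (a in 1:3) {
    base <- (a - 1L) * 10L
    r <- resp[resp$a == a, , drop = FALSE]
    wpos <- cw[r$cls]
    zo <- raw[, base + 5L]
    y <- targets$obj[, a]
    live <- !targets$ignore[, a]
    so <- sigmoid(zo)
    wno <- if (is.null(tc$w_noobj)) 1 else tc$w_noobj
    wcell <- ifelse(y > 0, 1, wno) * tc$w_obj
    # negatives near truth boxes (organ interiors) keep full weight
    if (!is.null(targets$hard)) {
      up <- y == 0 & targets$hard[, a]
      wcell[up] <- tc$w_obj
    }
    if (nrow(r)) wcell[r$p] <- wcell[r$p] * wpos
    l_obj <- l_obj + sum((wcell * bce_logits(zo, y))[live])
    gobj <- (so - y) * wcell
    gobj[!live] <- 0
    grad[, base + 5L] <- gobj

    if (nrow(r)) {
      p <- r$p
      bs <- if (is.null(r$bscale)) rep(1, nrow(r)) else r$bscale
      wb <- tc$w_box * bs * wpos
      sx <- sigmoid(raw[p, base + 1L]); sy <- sigmoid(raw[p, base + 2L])
      tw <- raw[p, base + 3L]; th <- raw[p, base + 4L]
      l_box <- l_box + sum(wb * ((sx - r$ox)^2 + (sy - r$oy)^2 +
                                   (tw - r$twt)^2 + (th - r$tht)^2))
      grad[cbind(p, base + 1L)] <- wb * 2 * (sx - r$ox) * sx * (1 - sx)
      grad[cbind(p, base + 2L)] <- wb * 2 * (sy - r$oy) * sy * (1 - sy)
      grad[cbind(p, base + 3L)] <- wb * 2 * (tw - r$twt)
      grad[cbind(p, base + 4L)] <- wb * 2 * (th - r$tht)
      zc <- raw[p, base + 5L + 1:5, drop = FALSE]
      yc <- matrix(0, nrow(r), 5L)
      yc[cbind(seq_len(nrow(r)), r$cls)] <- 1
      l_cls <- l_cls + tc$w_class * sum(wpos * bce_logits(zc, yc))
      grad[p, base + 5L + 1:5] <- grad[p, base + 5L + 1:5, drop = FALSE] +
        tc$w_class * wpos * (sigmoid(zc) - yc)
    }
    s <- targets$soft
    if (!is.null(s) && nrow(s)) {
      s <- s[s$a == a & !(s$p %in% r$p), , drop = FALSE]
      if (nrow(s)) {
        wsoft <- 0.5 * tc$w_class
        zs <- raw[s$p, base + 5L + 1:5, drop = FALSE]
        ys <- matrix(0, nrow(s), 5L)
        ys[cbind(seq_len(nrow(s)), s$cls)] <- 1
        l_cls <- l_cls + wsoft * sum(bce_logits(zs, ys))
        grad[s$p, base + 5L + 1:5] <-
          grad[s$p, base + 5L + 1:5, drop = FALSE] +
          wsoft * (sigmoid(zs) - ys)
      }
    }
  }
  list(box = l_box, objectness = l_obj, class = l_cls,
       total = l_box + l_obj + l_cls, grad = grad)
}

## ---- Adam -------------------------------------------------------------
adam_init <- function(model) {
  zero_like <- function(ly) list(W = ly$W * 0, b = ly$b * 0)
  list(t = 0,
       m = lapply(model$layers, zero_like),
       v = lapply(model$layers, zero_like),
       m2 = if (!is.null(model$head2)) zero_like(model$head2),
       v2 = if (!is.null(model$head2)) zero_like(model$head2),
       mt = if (!is.null(model$tower2)) lapply(model$tower2, zero_like),
       vt = if (!is.null(model$tower2)) lapply(model$tower2, zero_like))
}

adam_step <- function(model, st, grads, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  corr <- sqrt(1 - b2^st$t) / (1 - b1^st$t)
  upd <- function(par, m, v, g) {
    m$W <- b1 * m$W + (1 - b1) * g$dW
    m$b <- b1 * m$b + (1 - b1) * g$db
    v$W <- b2 * v$W + (1 - b2) * g$dW^2
    v$b <- b2 * v$b + (1 - b2) * g$db^2
    par$W <- par$W - lr * corr * m$W / (sqrt(v$W) + eps)
    par$b <- par$b - lr * corr * m$b / (sqrt(v$b) + eps)
    list(par = par, m = m, v = v)
  }
  for (i in seq_along(model$layers)) {
    u <- upd(model$layers[[i]], st$m[[i]], st$v[[i]], grads$layers[[i]])
    model$layers[[i]] <- u$par; st$m[[i]] <- u$m; st$v[[i]] <- u$v
  }
  if (!is.null(model$head2) && !is.null(grads$head2)) {
    u <- upd(model$head2, st$m2, st$v2, grads$head2)
    model$head2 <- u$par; st$m2 <- u$m; st$v2 <- u$v
    for (i in seq_along(model$tower2)) {
      u <- upd(model$tower2[[i]], st$mt[[i]], st$vt[[i]], grads$tower2[[i]])
      model$tower2[[i]] <- u$par; st$mt[[i]] <- u$m; st$vt[[i]] <- u$v
    }
  }
  list(model = model, st = st)
}

## 5x5 box mean via an integral image (exact, replicate-free: each pixel
## is normalised by the true window size at the borders).
box_mean <- function(m, r = 2L) {
  h <- nrow(m); w <- ncol(m)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  r1 <- as.vector(pmin(pmax(row(m) - r - 1L, 0L), h))
  r2 <- as.vector(pmin(row(m) + r, h))
  c1 <- as.vector(pmin(pmax(col(m) - r - 1L, 0L), w))
  c2 <- as.vector(pmin(col(m) + r, w))
  tot <- S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1 + 1L, c2 + 1L)] -
    S[cbind(r2 + 1L, c1 + 1L)] + S[cbind(r1 + 1L, c1 + 1L)]
  matrix(tot / ((r2 - r1) * (c2 - c1)), h, w)
}

## Separable running-median background at stone scale. The median (unlike
## a mean) is insensitive to a bright compact object occupying under half
## of the window, so bright stones leave no dark "halo" in the residual.
median_background <- function(x, k = 13L) {
  a <- apply(x, 2L, function(col) stats::runmed(col, k, endrule = "keep"))
  t(apply(a, 1L, function(row) stats::runmed(row, k, endrule = "keep")))
}

## Three input channels: intensity, a sharp 5x5 mean high-pass, and a
## stone-scale median high-pass. The contrast channels encode
## "darker/brighter than the surroundings" -- the cue that separates a
## muddy stone from the gallbladder interior, whose absolute intensity
## differs by only a few noise standard deviations.
image_input <- function(rec) {
  x <- rec$pixels / 255
  cbind(as.numeric(x),
        as.numeric(x - box_mean(x, 2L)),
        as.numeric(x - median_background(x)))
}

#' Train the detector on a phantom dataset
#'
#' Mini-batch Adam on the loss of [compute_loss()]. Fully seeded: the
#' same dataset, configs and seeds reproduce the same loss trace on a
#' single CPU.
#'
#' @param dataset non-empty list of `image_record`s, all annotated and of
#'   the model's input size.
#' @param net a [net_config()].
#' @param tc a [train_config()].
#' @param verbose print the per-epoch loss.
#' @return a trained `cholescan_model`; `$loss_trace` holds the mean
#'   per-image total loss per epoch.
#' @export
train_detector <- function(dataset, net = net_config(), tc = train_config(),
                           verbose = FALSE) {
  if (!length(dataset)) stop("training dataset must be non-empty")
  for (rec in dataset) {
    if (rec$width != net$input_size || rec$height != net$input_size) {
      stop("image ", rec$id, " does not match the network input size")
    }
    if (is.null(rec$truth)) stop("image ", rec$id, " has no annotation table")
  }
  model <- build_network(net)
  scales <- detection_scales(model)
  # precompute inputs and targets for each flip variant
  variants <- if (tc$augment_flips) {
    list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  } else list(c(FALSE, FALSE))
  x0 <- list(); tgt <- list()
  for (v in seq_along(variants)) {
    recs <- lapply(dataset, flip_record,
                   h = variants[[v]][1L], v = variants[[v]][2L])
    x0[[v]] <- lapply(recs, image_input)
    tgt[[v]] <- lapply(recs, function(rec) {
      build_targets_multi(rec$truth, net$input_size, scales, net$anchors,
                          tc$ignore_iou)
    })
  }
  st <- adam_init(model)
  n <- length(dataset)
  nv <- length(variants)
  g1 <- scales[1L]^2
  g2 <- if (length(scales) > 1L) scales[2L]^2 else 0L
  trace <- numeric(tc$epochs)
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      vsel <- sample.int(nv, n, replace = TRUE)
      ep_loss <- 0
      for (start in seq(1L, n, by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1L, n)]
        nb <- length(idx)
        # one stacked forward/backward per mini-batch: gradients over the
        # batch fall out of the same GEMMs that serve a single image
        xb <- do.call(rbind, lapply(seq_len(nb), function(j)
          x0[[vsel[idx[j]]]][[idx[j]]]))
        fwd <- net_forward(model, xb, keep = TRUE, batch = nb)
        d1 <- matrix(0, nb * g1, ncol(fwd$head1))
        d2 <- if (!is.null(model$head2))
          matrix(0, nb * g2, ncol(fwd$head2))
        bl <- 0
        for (j in seq_len(nb)) {
          tg <- tgt[[vsel[idx[j]]]][[idx[j]]]
          r1 <- ((j - 1L) * g1 + 1L):(j * g1)
          lg1 <- loss_and_grad(fwd$head1[r1, , drop = FALSE], tg[[1L]], tc)
          d1[r1, ] <- lg1$grad
          loss_j <- lg1$total
          if (!is.null(d2)) {
            r2 <- ((j - 1L) * g2 + 1L):(j * g2)
            lg2 <- loss_and_grad(fwd$head2[r2, , drop = FALSE], tg[[2L]], tc)
            d2[r2, ] <- lg2$grad
            loss_j <- loss_j + lg2$total
          }
          if (!is.finite(loss_j)) {
            stop("training diverged: non-finite loss at epoch ", ep,
                 ", image ", dataset[[idx[j]]]$id)
          }
          bl <- bl + loss_j
        }
        grads <- net_backward(model, fwd, d1, d2)
        grads <- scale_grads(grads, 1 / nb)
        # step decay: fine-tune the box regression in the last quarter
        lr_ep <- if (ep > 0.75 * tc$epochs) tc$lr * 0.1 else tc$lr
        res <- adam_step(model, st, grads, lr_ep)
        model <- res$model; st <- res$st
        ep_loss <- ep_loss + bl
      }
      trace[ep] <- ep_loss / n
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, trace[ep]))
    }
  })
  model$trained <- TRUE
  model$loss_trace <- trace
  model
}

scale_grads <- function(a, f) {
  for (i in seq_along(a$layers)) {
    a$layers[[i]]$dW <- a$layers[[i]]$dW * f
    a$layers[[i]]$db <- a$layers[[i]]$db * f
  }
  if (!is.null(a$head2)) {
    a$head2$dW <- a$head2$dW * f
    a$head2$db <- a$head2$db * f
    for (i in seq_along(a$tower2)) {
      a$tower2[[i]]$dW <- a$tower2[[i]]$dW * f
      a$tower2[[i]]$db <- a$tower2[[i]]$db * f
    }
  }
  a
}

detection_scales <- function(model) {
  g <- model$cfg$grid_size
  if (model$cfg$use_skip_upsample) c(g, 2L * g) else g
}

## Decode one raw head matrix into a detection table.
decode_head <- function(raw, g, anchors, image_size, image_id) {
  p <- seq_len(g * g)
  cx <- (p - 1L) %/% g
  cy <- (p - 1L) %% g
  out <- vector("list", 3L)
  for (a in 1:3) {
    base <- (a - 1L) * 10L
    bx <- (cx + sigmoid(raw[, base + 1L])) / g
    by <- (cy + sigmoid(raw[, base + 2L])) / g
    bw <- anchors[a, 1L] * exp(raw[, base + 3L]) / g
    bh <- anchors[a, 2L] * exp(raw[, base + 4L]) / g
    obj <- sigmoid(raw[, base + 5L])
    cls <- sigmoid(raw[, base + 5L + 1:5, drop = FALSE])
    best <- max.col(cls, ties.method = "first")
    conf <- 100 * obj * cls[cbind(p, best)]
    out[[a]] <- data.frame(
      image_id = image_id,
      class = cholescan_classes()[best],
      confidence = conf,
      x_min = (bx - bw / 2) * image_size,
      y_min = (by - bh / 2) * image_size,
      x_max = (bx + bw / 2) * image_size,
      y_max = (by + bh / 2) * image_size,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the detector on one image
#'
#' Decodes every cell/anchor prediction, drops boxes at or below the
#' confidence floor, and applies class-wise NMS. Output detections are
#' raw, pre-policy: pass them to [apply_policy()] for the context-aware
#' final output.
#'
#' @param model a trained `cholescan_model`.
#' @param image an `image_record` matching the model input size.
#' @param conf_floor confidence floor in percent; boxes with confidence
#'   strictly greater are kept (default 25, the output-threshold
#'   convention of the policy layer).
#' @param iou_threshold NMS overlap threshold.
#' @return a detection data frame in pixel coordinates.
#' @export
detect <- function(model, image, conf_floor = 25, iou_threshold = 0.45) {
  stopifnot(inherits(model, "cholescan_model"))
  if (image$width != model$cfg$input_size ||
      image$height != model$cfg$input_size) {
    stop("image size does not match the model input size")
  }
  fwd <- net_forward(model, image_input(image), keep = FALSE)
  g <- model$cfg$grid_size
  dets <- decode_head(fwd$head1, g, model$cfg$anchors,
                      model$cfg$input_size, image$id)
  if (!is.null(fwd$head2)) {
    dets <- rbind(dets, decode_head(fwd$head2, 2L * g, model$cfg$anchors,
                                    model$cfg$input_size, image$id))
  }
  dets <- dets[dets$confidence > conf_floor, , drop = FALSE]
  # clip boxes to the image, dropping any that degenerate
  dets$x_min <- pmax(dets$x_min, 0)
  dets$y_min <- pmax(dets$y_min, 0)
  dets$x_max <- pmin(dets$x_max, image$width)
  dets$y_max <- pmin(dets$y_max, image$height)
  dets <- dets[dets$x_max > dets$x_min & dets$y_max > dets$y_min, ,
               drop = FALSE]
  rownames(dets) <- NULL
  nms(dets, iou_threshold)
}
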