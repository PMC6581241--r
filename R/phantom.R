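#' Specification of one synthetic abdominal phantom
#'
#' The phantom generator emulates the appearance and spatial relations the
#' detection pipeline relies on: a bright spine at the bottom centre of
#' every slice, a large liver blob, a gallbladder ("gall") ellipse adjacent
#' to the liver, bright irregular granular stones and a large low-contrast
#' muddy stone inside the gall, and optionally a gray liver patch that
#' mimics a muddy stone (the confounder the context policy is designed to
#' suppress).
#'
#' Default intensity bands (8-bit gray): background 30, liver 100, muddy
#' stone 120, gall 140, spine 220, granular stone 230. They enforce the
#' qualitative ordering granular > gall > muddy > background with margins
#' comfortably larger than the default pixel noise (sd 8).
#'
#' @param image_size square image side in pixels (default 128; 512
#'   supported).
#' @param include_spine,include_liver,include_gall which organs to draw.
#' @param n_granular,n_muddy number of stones of each type (require
#'   `include_gall = TRUE` when positive).
#' @param confounder draw a muddy-stone-like gray patch inside the liver
#'   (requires `include_liver = TRUE`).
#' @param intensity_bands named numeric vector of mean gray levels for
#'   `background`, `spine`, `liver`, `gall`, `granular_stone`,
#'   `muddy_stone`; must satisfy granular_stone > gall > muddy_stone >
#'   background.
#' @param noise_sd standard deviation of additive Gaussian pixel noise in
#'   gray levels.
#' @param seed integer seed; the same spec and seed reproduce identical
#'   pixels.
#' @return a list of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(n_granular = 1, seed = 7)
#' img <- generate_phantom(spec)
#' img$truth
phantom_spec <- function(image_size = 128L,
                         include_spine = TRUE,
                         include_liver = TRUE,
                         include_gall = TRUE,
                         n_granular = 0L,
                         n_muddy = 0L,
                         confounder = FALSE,
                         intensity_bands = c(background = 30, liver = 100,
                                             muddy_stone = 120, gall = 140,
                                             spine = 220,
                                             granular_stone = 230),
                         noise_sd = 8,
                         seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               include_spine = isTRUE(include_spine),
               include_liver = isTRUE(include_liver),
               include_gall = isTRUE(include_gall),
               n_granular = as.integer(n_granular),
               n_muddy = as.integer(n_muddy),
               confounder = isTRUE(confounder),
               intensity_bands = intensity_bands,
               noise_sd = as.numeric(noise_sd),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

validate_phantom_spec <- function(spec) {
  ib <- spec$intensity_bands
  need <- c("background", "liver", "muddy_stone", "gall", "spine",
            "granular_stone")
  miss <- setdiff(need, names(ib))
  if (length(miss)) stop("intensity_bands lacks: ", paste(miss, collapse = ", "))
  if (!(ib[["granular_stone"]] > ib[["gall"]] &&
        ib[["gall"]] > ib[["muddy_stone"]] &&
        ib[["muddy_stone"]] > ib[["background"]])) {
    stop("intensity_bands must satisfy granular_stone > gall > ",
         "muddy_stone > background")
  }
  if (spec$image_size < 32L) stop("image_size must be at least 32 pixels")
  if (spec$n_granular < 0L || spec$n_muddy < 0L) {
    stop("stone counts must be non-negative")
  }
  if ((spec$n_granular > 0L || spec$n_muddy > 0L) && !spec$include_gall) {
    stop("stones require include_gall = TRUE: gallstones only occur ",
         "inside the gallbladder")
  }
  if (spec$confounder && !spec$include_liver) {
    stop("confounder requires include_liver = TRUE: the confounder is a ",
         "gray patch inside the liver")
  }
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(spec)
}

## Run code under a seeded, restored RNG state so generators are pure.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

## Pixel-centre coordinate grids in 0-based continuous coordinates.
## pixels[r, c] covers [c-1, c) x [r-1, r); its centre is (c-0.5, r-0.5).
coord_grids <- function(s) {
  xs <- matrix(rep(seq_len(s) - 0.5, each = s), nrow = s)
  ys <- matrix(rep(seq_len(s) - 0.5, times = s), nrow = s)
  list(x = xs, y = ys)
}

ellipse_mask <- function(g, cx, cy, a, b) {
  ((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1
}

## Crossing-number polygon rasterisation on pixel centres.
polygon_mask <- function(g, px, py) {
  s <- nrow(g$x)
  inside <- matrix(FALSE, s, s)
  n <- length(px)
  xs <- g$x; ys <- g$y
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  bbox(min(idx[, 2L]) - 1L, min(idx[, 1L]) - 1L,
       max(idx[, 2L]), max(idx[, 1L]))
}

truth_row <- function(class, b) {
  data.frame(class = class,
             x_min = b[["x_min"]], y_min = b[["y_min"]],
             x_max = b[["x_max"]], y_max = b[["y_max"]],
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(class = character(0), x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0), stringsAsFactors = FALSE)
}

## Sample a stone centre inside the gall ellipse (inner fraction `frac` of
## each semi-axis) such that a stone of half-extent (rx, ry) stays inside
## and clear of already-placed stones (so truth boxes keep their own
## pixels). Falls back to the least-overlapping draw if the gall is full.
sample_stone_centre <- function(gall, rx, ry, frac = 0.55, placed = NULL) {
  best <- NULL
  best_pen <- Inf
  for (try in 1:300) {
    u <- stats::runif(1, -frac, frac)
    v <- stats::runif(1, -frac, frac)
    if (u^2 / frac^2 + v^2 / frac^2 > 1) next
    cx <- gall$cx + u * gall$a
    cy <- gall$cy + v * gall$b
    # stone must fit: check the stone's bbox corners stay inside the gall
    if (((abs(cx - gall$cx) + rx) / gall$a)^2 +
        ((abs(cy - gall$cy) + ry) / gall$b)^2 > 1.05) next
    pen <- 0
    for (p in placed) {
      ox <- min(cx + rx, p[1L] + p[3L]) - max(cx - rx, p[1L] - p[3L])
      oy <- min(cy + ry, p[2L] + p[4L]) - max(cy - ry, p[2L] - p[4L])
      pen <- pen + max(ox, 0) * max(oy, 0)
    }
    if (pen == 0) return(structure(c(cx, cy), pen = 0))
    if (pen < best_pen) { best_pen <- pen; best <- c(cx, cy) }
  }
  if (is.null(best)) stop("could not place a stone inside the gall")
  structure(best, pen = best_pen)
}

## Place a stone, shrinking it when the gall is too crowded for a
## non-overlapping position at the drawn size.
place_stone <- function(gall, rx, ry, frac, placed, min_scale = 0.6) {
  scale <- 1
  repeat {
    ctr <- sample_stone_centre(gall, rx * scale, ry * scale, frac, placed)
    if (attr(ctr, "pen") == 0 || scale <= min_scale) {
      return(list(ctr = as.numeric(ctr), rx = rx * scale, ry = ry * scale))
    }
    scale <- scale * 0.85
  }
}

#' Generate one synthetic phantom image with ground truth
#'
#' Draws the requested objects on a noisy background and returns the 8-bit
#' image together with a ground-truth table. Guarantees by construction:
#' the gall is adjacent to (slightly overlapping) the liver; every stone's
#' bounding-box centre lies inside the gall box; the spine sits at the
#' bottom centre; the muddy stone interior is strictly darker on average
#' than the surrounding gall; identical spec and seed give identical
#' pixels.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `image_record` with fields `id`, `width`,
#'   `height`, `pixels` (height x width integer matrix, 0-255, row = y),
#'   and `truth` (data frame: `class`, `x_min`, `y_min`, `x_max`, `y_max`).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec, id = NULL) {
  s <- spec$image_size
  ib <- spec$intensity_bands
  g <- coord_grids(s)
  img <- matrix(ib[["background"]], s, s)
  truth <- empty_truth()
  confounder_bbox <- NULL

  if (spec$include_liver) {
    # union of three overlapping ellipses: a large smooth blob upper-left
    lcx <- s * stats::runif(1, 0.34, 0.42)
    lcy <- s * stats::runif(1, 0.36, 0.44)
    la <- s * stats::runif(1, 0.20, 0.24)
    lb <- s * stats::runif(1, 0.15, 0.18)
    lmask <- ellipse_mask(g, lcx, lcy, la, lb)
    for (k in 1:2) {
      th <- stats::runif(1, 0, 2 * pi)
      lmask <- lmask | ellipse_mask(g, lcx + 0.45 * la * cos(th),
                                    lcy + 0.45 * lb * sin(th),
                                    0.7 * la, 0.7 * lb)
    }
    img[lmask] <- ib[["liver"]]
    truth <- rbind(truth, truth_row("liver", mask_bbox(lmask)))
    liver <- list(cx = lcx, cy = lcy, a = la, b = lb, mask = lmask)
  }

  if (spec$confounder) {
    # gray patch inside the liver whose band overlaps the muddy band
    pcx <- liver$cx + stats::runif(1, -0.3, 0.3) * liver$a
    pcy <- liver$cy + stats::runif(1, -0.3, 0.3) * liver$b
    pa <- s * stats::runif(1, 0.035, 0.05)
    pb <- s * stats::runif(1, 0.025, 0.04)
    pmask <- ellipse_mask(g, pcx, pcy, pa, pb) & liver$mask
    img[pmask] <- ib[["muddy_stone"]]
    # deliberately not added to truth: it is liver tissue, not a stone
    confounder_bbox <- mask_bbox(pmask)
  }

  if (spec$include_gall) {
    # ellipse adjacent to the liver, placed on its lower-right boundary;
    # drawn large enough (~2 grid cells at 128 px) to be clearly resolvable
    ga <- s * stats::runif(1, 0.115, 0.14)
    gb <- s * stats::runif(1, 0.085, 0.105)
    if (spec$include_liver) {
      th <- stats::runif(1, -0.2 * pi, 0.05 * pi)  # towards lower-right
      gcx <- liver$cx + (liver$a + 0.82 * ga) * cos(th)
      gcy <- liver$cy + (liver$b + 0.82 * gb) * sin(th)
    } else {
      gcx <- s * stats::runif(1, 0.58, 0.66)
      gcy <- s * stats::runif(1, 0.40, 0.50)
    }
    gcx <- min(max(gcx, ga + 1), s - ga - 1)
    gcy <- min(max(gcy, gb + 1), s * 0.72 - gb)
    gmask <- ellipse_mask(g, gcx, gcy, ga, gb)
    img[gmask] <- ib[["gall"]]
    truth <- rbind(truth, truth_row("gall", mask_bbox(gmask)))
    gall <- list(cx = gcx, cy = gcy, a = ga, b = gb)

    placed <- list()
    if (spec$n_muddy > 0L) {
      for (k in seq_len(spec$n_muddy)) {
        # one large low-contrast ellipse, slightly darker than the gall
        ma <- s * stats::runif(1, 0.042, 0.055)
        mb <- s * stats::runif(1, 0.030, 0.040)
        pl <- place_stone(gall, ma, mb, frac = 0.40, placed = placed)
        ctr <- pl$ctr; ma <- pl$rx; mb <- pl$ry
        placed[[length(placed) + 1L]] <- c(ctr, ma, mb)
        mmask <- ellipse_mask(g, ctr[1L], ctr[2L], ma, mb)
        img[mmask] <- ib[["muddy_stone"]]
        truth <- rbind(truth, truth_row("muddy_stone", mask_bbox(mmask)))
      }
    }
    if (spec$n_granular > 0L) {
      for (k in seq_len(spec$n_granular)) {
        # bright polygon with jittered vertices: irregular, white
        r <- max(s * stats::runif(1, 0.032, 0.05), 4.5)
        pl <- place_stone(gall, r, r, frac = 0.55, placed = placed)
        ctr <- pl$ctr; r <- max(pl$rx, 4.5)
        placed[[length(placed) + 1L]] <- c(ctr, r, r)
        nv <- 10L
        ang <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)] +
          stats::runif(nv, -0.12, 0.12)
        rad <- r * stats::runif(nv, 0.90, 1.10)
        smask <- polygon_mask(g, ctr[1L] + rad * cos(ang),
                              ctr[2L] + rad * sin(ang))
        img[smask] <- ib[["granular_stone"]]
        truth <- rbind(truth, truth_row("granular_stone", mask_bbox(smask)))
      }
    }
  }

  if (spec$include_spine) {
    # bright disk with a darker centre (spinal canal) at bottom centre
    scx <- s * 0.5 + stats::runif(1, -0.02, 0.02) * s
    scy <- s * 0.85 + stats::runif(1, -0.015, 0.015) * s
    sr <- s * stats::runif(1, 0.060, 0.075)
    smask <- ellipse_mask(g, scx, scy, sr, sr)
    img[smask] <- ib[["spine"]]
    canal <- ellipse_mask(g, scx, scy - 0.35 * sr, 0.3 * sr, 0.3 * sr)
    img[canal] <- ib[["liver"]]  # darker canal, liver-gray band
    truth <- rbind(truth, truth_row("spine", mask_bbox(smask)))
  }

  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), s, s)

  rec <- list(id = if (is.null(id)) sprintf("phantom_seed%d", spec$seed) else id,
              width = s, height = s, pixels = img, truth = truth)
  class(rec) <- "image_record"
  # the confounder is not truth, but its location aids diagnostics
  if (!is.null(confounder_bbox)) attr(rec, "confounder_bbox") <- confounder_bbox
  rec
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s: %dx%d, %d truth object(s)>\n",
              x$id, x$width, x$height, nrow(x$truth)))
  if (nrow(x$truth)) print(x$truth)
  invisible(x)
}

#' Generate a labelled phantom dataset from a scenario mix
#'
#' Scenarios: `granular` (1-2 granular stones), `muddy` (one muddy stone),
#' `both` (one of each), `negative_plain` (organs, no stones),
#' `negative_confounder` (liver with a muddy-like gray patch, gall absent,
#' no stones). Realized counts follow the requested proportions under
#' largest-remainder rounding, and the scenario sequence is shuffled.
#'
#' @param n number of images.
#' @param class_mix named numeric vector of scenario proportions summing
#'   to 1 (tolerance 1e-9).
#' @param seed integer seed for the whole dataset.
#' @param image_size square image side in pixels.
#' @param noise_sd pixel noise level passed to each phantom.
#' @return a list of `n` [generate_phantom()] records; each record gains a
#'   `scenario` attribute and an id of the form `phantom_0001`.
#' @export
#' @examples
#' ds <- generate_dataset(4, c(granular = 0.5, muddy = 0.5), seed = 1)
#' sapply(ds, function(r) nrow(r$truth))
generate_dataset <- function(n,
                             class_mix = c(granular = 0.3, muddy = 0.2,
                                           both = 0.1, negative_plain = 0.3,
                                           negative_confounder = 0.1),
                             seed = 1L, image_size = 128L, noise_sd = 8) {
  known <- c("granular", "muddy", "both", "negative_plain",
             "negative_confounder")
  bad <- setdiff(names(class_mix), known)
  if (length(bad)) stop("unknown scenario name(s): ",
                        paste(bad, collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix proportions must sum to 1")
  }
  if (n == 0L) return(list())

  # largest-remainder apportionment of n among scenarios
  quota <- n * class_mix
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(-(quota - counts), seq_along(quota))[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  scenarios <- rep(names(class_mix), times = counts)

  with_seed(seed, {
    scenarios <- sample(scenarios)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      sc <- scenarios[i]
      spec <- switch(sc,
        granular = phantom_spec(image_size, n_granular = sample(1:2, 1),
                                noise_sd = noise_sd, seed = seeds[i]),
        muddy = phantom_spec(image_size, n_muddy = 1L,
                             noise_sd = noise_sd, seed = seeds[i]),
        both = phantom_spec(image_size, n_granular = 1L, n_muddy = 1L,
                            noise_sd = noise_sd, seed = seeds[i]),
        negative_plain = phantom_spec(image_size, noise_sd = noise_sd,
                                      seed = seeds[i]),
        negative_confounder = phantom_spec(image_size, include_gall = FALSE,
                                           confounder = TRUE,
                                           noise_sd = noise_sd,
                                           seed = seeds[i])
      )
      rec <- with_seed(spec$seed, generate_phantom_impl(
        spec, id = sprintf("phantom_%04d", i)))
      attr(rec, "scenario") <- sc
      rec
    })
  })
}

#' Generate a gall-absent negative phantom with a liver confounder
#'
#' The scenario behind the policy's hardest rule: no gallbladder on the
#' slice, but a gray patch of liver whose intensity band overlaps the
#' muddy-stone band -- exactly what a detector tends to misjudge as a
#' muddy stone. Truth contains no stone and no gall object.
#'
#' @param spec a [phantom_spec()] with `include_liver = TRUE`,
#'   `include_gall = FALSE`; `confounder` is forced on.
#' @return an `image_record`.
#' @export
generate_negative_confounder <- function(spec) {
  if (spec$include_gall) {
    stop("confounder scenario is gall-absent: set include_gall = FALSE")
  }
  if (!spec$include_liver) {
    stop("confounder requires include_liver = TRUE")
  }
  spec$confounder <- TRUE
  validate_phantom_spec(spec)
  generate_phantom(spec)
}
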