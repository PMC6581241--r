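test_that("network config validates shape arithmetic", {
  cfg <- net_config(input_size = 128)
  expect_equal(cfg$grid_size, 8L)
  cfg416 <- net_config(input_size = 416, channels = c(8, 8, 8, 8, 8))
  expect_equal(cfg416$grid_size, 13L)
  expect_error(net_config(input_size = 100), "divisible")
  expect_error(net_config(anchors = matrix(1, 2, 2)), "3 anchors")
  expect_error(net_config(channels = c(8, 8), n_downsamples = 3),
               "one width per")
})

test_that("the layer registry contains convolutions only, no pooling", {
  reg <- layer_registry(build_network(net_config(input_size = 64,
                                                 channels = c(4, 8))))
  expect_true(all(grepl("^conv", reg$type)))
  expect_false(any(grepl("pool", reg$type, ignore.case = TRUE)))
  # downsampling happens only through stride-2 convolutions
  expect_equal(sum(reg$stride == 2L), 2L)
  reg2 <- layer_registry(build_network(net_config(
    input_size = 64, channels = c(4, 8), use_skip_upsample = TRUE)))
  expect_false(any(grepl("pool", reg2$type, ignore.case = TRUE)))
})

test_that("head emits 3 x (5 + 5) channels per grid cell", {
  cfg <- net_config(input_size = 64, channels = c(4, 8), seed = 2)
  m <- build_network(cfg)
  fwd <- cholescan:::net_forward(m, matrix(0.5, 64 * 64, 1))
  expect_equal(dim(fwd$head1), c(16L * 16L, 30L))
  cfg2 <- net_config(input_size = 64, channels = c(4, 8, 8),
                     use_skip_upsample = TRUE, seed = 2)
  fwd2 <- cholescan:::net_forward(build_network(cfg2), matrix(0.5, 64 * 64, 1))
  expect_equal(dim(fwd2$head1), c(8L * 8L, 30L))
  expect_equal(dim(fwd2$head2), c(16L * 16L, 30L))
})

test_that("weight initialization is reproducible from the seed", {
  cfg <- net_config(input_size = 64, channels = c(4, 8), seed = 11)
  a <- build_network(cfg)
  b <- build_network(cfg)
  expect_identical(a$layers, b$layers)
  c <- build_network(net_config(input_size = 64, channels = c(4, 8),
                                seed = 12))
  expect_false(identical(a$layers[[1]]$W, c$layers[[1]]$W))
})

test_that("loss vanishes in the perfect-fit limit", {
  cfg <- net_config(input_size = 64, channels = c(4, 8), seed = 1)
  g <- cfg$grid_size
  truth <- data.frame(class = "gall", x_min = 20, y_min = 20,
                      x_max = 36, y_max = 34, stringsAsFactors = FALSE)
  tg <- build_targets(truth, 64, g, cfg$anchors)
  # raw outputs that exactly reproduce the targets with saturated logits
  raw <- matrix(0, g * g, 30)
  for (a in 1:3) {
    raw[, (a - 1) * 10 + 5] <- -30                    # objectness off
    raw[, (a - 1) * 10 + 5 + 1:5] <- -30              # classes off
  }
  r <- tg$resp
  base <- (r$a - 1) * 10
  raw[cbind(r$p, base + 1)] <- logit(r$ox)
  raw[cbind(r$p, base + 2)] <- logit(r$oy)
  raw[cbind(r$p, base + 3)] <- r$twt
  raw[cbind(r$p, base + 4)] <- r$tht
  raw[cbind(r$p, base + 5)] <- 30                     # objectness on
  raw[cbind(r$p, base + 5 + r$cls)] <- 30
  s <- tg$soft                                        # covered cells carry
  raw[cbind(s$p, (s$a - 1) * 10 + 5 + s$cls)] <- 30   # the truth's class
  l <- compute_loss(raw, tg)
  expect_lt(l$total, 1e-3)
  expect_equal(l$box, 0)
})

test_that("correct negatives give near-zero objectness loss", {
  cfg <- net_config(input_size = 64, channels = c(4, 8))
  g <- cfg$grid_size
  tg <- build_targets(data.frame(class = character(0), x_min = numeric(0),
                                 y_min = numeric(0), x_max = numeric(0),
                                 y_max = numeric(0)), 64, g, cfg$anchors)
  raw <- matrix(0, g * g, 30)
  for (a in 1:3) raw[, (a - 1) * 10 + 5] <- -20
  l <- compute_loss(raw, tg)
  expect_lt(l$objectness, 1e-6)
  expect_equal(l$box + l$class, 0)
})

test_that("loss matches closed-form arithmetic on a one-cell case", {
  # 1x1 grid: a single cell, anchor 1 responsible for one truth box
  anchors <- matrix(c(1, 1, 2, 2, 4, 4), ncol = 2, byrow = TRUE)
  truth <- data.frame(class = "liver", x_min = 8, y_min = 8,
                      x_max = 56, y_max = 40, stringsAsFactors = FALSE)
  tg <- build_targets(truth, 64, 1L, anchors)
  expect_equal(nrow(tg$resp), 1L)
  raw <- matrix(0.3, 1, 30)
  tc <- train_config(w_box = 5, w_obj = 2, w_class = 1, w_noobj = 0.3)
  l <- compute_loss(raw, tg, tc)
  r <- tg$resp
  s <- 1 / (1 + exp(-0.3))
  bce <- function(z, y) max(z, 0) - z * y + log(1 + exp(-abs(z)))
  a_resp <- r$a
  box <- 5 * r$bscale * ((s - r$ox)^2 + (s - r$oy)^2 +
                           (0.3 - r$twt)^2 + (0.3 - r$tht)^2)
  obj <- 0
  for (a in 1:3) {
    y <- if (a == a_resp) 1 else 0
    # every prior overlaps the truth in this one-cell case, so negative
    # anchors count as hard negatives at full objectness weight
    wno <- 1
    if (!tg$ignore[1, a]) obj <- obj + 2 * wno * bce(0.3, y)
  }
  cls <- sum(vapply(1:5, function(k)
    bce(0.3, as.numeric(k == r$cls)), 0))
  expect_equal(l$box, box, tolerance = 1e-9)
  expect_equal(l$objectness, obj, tolerance = 1e-9)
  expect_equal(l$class, cls, tolerance = 1e-9)
  expect_error(compute_loss(raw * NA, tg), "non-finite")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(8)
  cfg <- net_config(input_size = 32, channels = c(4, 6), seed = 3)
  m <- build_network(cfg)
  x0 <- matrix(runif(32 * 32), ncol = 1)
  truth <- data.frame(class = c("liver", "gall"),
                      x_min = c(2, 18), y_min = c(2, 18),
                      x_max = c(16, 26), y_max = c(14, 25),
                      stringsAsFactors = FALSE)
  tc <- train_config()
  tg <- build_targets(truth, 32, cfg$grid_size, cfg$anchors)
  fwd <- cholescan:::net_forward(m, x0, keep = TRUE)
  lg <- cholescan:::loss_and_grad(fwd$head1, tg, tc)
  gr <- cholescan:::net_backward(m, fwd, lg$grad)
  lossf <- function(mm) {
    f <- cholescan:::net_forward(mm, x0)
    cholescan:::loss_and_grad(f$head1, tg, tc)$total
  }
  eps <- 1e-5
  for (li in seq_along(m$layers)) {
    i <- sample(length(m$layers[[li]]$W), 1)
    mp <- m; mp$layers[[li]]$W[i] <- mp$layers[[li]]$W[i] + eps
    mm <- m; mm$layers[[li]]$W[i] <- mm$layers[[li]]$W[i] - eps
    num <- (lossf(mp) - lossf(mm)) / (2 * eps)
    expect_equal(gr$layers[[li]]$dW[i], num, tolerance = 1e-4)
  }
})
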