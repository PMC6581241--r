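test_that("spec invariants are enforced", {
  expect_error(phantom_spec(n_granular = 1, include_gall = FALSE),
               "include_gall")
  expect_error(phantom_spec(confounder = TRUE, include_liver = FALSE),
               "include_liver")
  bad <- c(background = 30, liver = 100, muddy_stone = 150, gall = 140,
           spine = 220, granular_stone = 230)
  expect_error(phantom_spec(intensity_bands = bad), "ordering|satisfy")
  expect_error(phantom_spec(n_granular = -1), "non-negative")
})

test_that("an all-empty spec yields pure background noise", {
  img <- generate_phantom(phantom_spec(include_spine = FALSE,
                                       include_liver = FALSE,
                                       include_gall = FALSE, seed = 3))
  expect_equal(nrow(img$truth), 0L)
  expect_lt(abs(mean(img$pixels) - 30), 2)
})

test_that("identical spec and seed reproduce identical pixels", {
  sp <- phantom_spec(n_granular = 1, seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(phantom_spec(n_granular = 1, seed = 8))
  expect_false(identical(a$pixels, c$pixels))
})

test_that("truth boxes stay inside the image and use the five classes", {
  for (seed in 1:10) {
    img <- generate_phantom(phantom_spec(n_granular = 2, n_muddy = 1,
                                         seed = seed))
    expect_true(all(img$truth$class %in% cholescan_classes()))
    expect_true(all(img$truth$x_min >= 0 & img$truth$y_min >= 0))
    expect_true(all(img$truth$x_max <= img$width &
                      img$truth$y_max <= img$height))
  }
})

test_that("muddy stone interior is darker than the surrounding gall", {
  for (seed in c(2, 9, 21)) {
    img <- generate_phantom(phantom_spec(n_muddy = 1, seed = seed))
    t <- img$truth
    m <- t[t$class == "muddy_stone", ]
    px <- img$pixels
    inner <- px[(floor(m$y_min) + 2):(ceiling(m$y_max) - 1),
                (floor(m$x_min) + 2):(ceiling(m$x_max) - 1)]
    ring_rows <- c(max(1, floor(m$y_min) - 3):floor(m$y_min),
                   ceiling(m$y_max):min(img$height, ceiling(m$y_max) + 3))
    ring <- px[ring_rows, (floor(m$x_min) + 1):ceiling(m$x_max)]
    expect_lt(mean(inner), mean(ring))
  }
})

test_that("stone centres lie inside the gall box and spine sits bottom-centre", {
  for (seed in 4:8) {
    img <- generate_phantom(phantom_spec(n_granular = 1, n_muddy = 1,
                                         seed = seed))
    t <- img$truth
    g <- t[t$class == "gall", ]
    for (cl in stone_classes()) {
      s <- t[t$class == cl, ]
      cx <- (s$x_min + s$x_max) / 2
      cy <- (s$y_min + s$y_max) / 2
      expect_true(cx > g$x_min && cx < g$x_max)
      expect_true(cy > g$y_min && cy < g$y_max)
    }
    sp <- t[t$class == "spine", ]
    expect_gt((sp$y_min + sp$y_max) / 2, img$height * 0.7)
    expect_lt(abs((sp$x_min + sp$x_max) / 2 - img$width / 2),
              img$width * 0.1)
  }
})

test_that("gall is adjacent to the liver", {
  for (seed in 11:15) {
    img <- generate_phantom(phantom_spec(seed = seed))
    t <- img$truth
    l <- t[t$class == "liver", ]
    g <- t[t$class == "gall", ]
    # boxes overlap or touch: gap between them is non-positive
    gap_x <- max(l$x_min, g$x_min) - min(l$x_max, g$x_max)
    gap_y <- max(l$y_min, g$y_min) - min(l$y_max, g$y_max)
    expect_lte(max(gap_x, gap_y), 1)
  }
})

test_that("dataset apportionment follows largest-remainder rounding", {
  expect_equal(generate_dataset(0), list())
  ds <- generate_dataset(10, c(negative_plain = 1.0), seed = 2)
  expect_equal(length(ds), 10L)
  for (r in ds) expect_false(any(r$truth$class %in% stone_classes()))
  ds2 <- generate_dataset(100, c(granular = 0.5, muddy = 0.5), seed = 1)
  sc <- table(vapply(ds2, attr, "", "scenario"))
  expect_equal(as.integer(sc[c("granular", "muddy")]), c(50L, 50L))
  # 7 images over the default 5-scenario mix: floor + remainders
  ds3 <- generate_dataset(7, seed = 3)
  expect_equal(length(ds3), 7L)
  expect_error(generate_dataset(5, c(granular = 0.6, muddy = 0.5)), "sum")
  expect_error(generate_dataset(5, c(weird = 1.0)), "unknown scenario")
})

test_that("dataset generation is reproducible and ids are stable", {
  a <- generate_dataset(6, seed = 5)
  b <- generate_dataset(6, seed = 5)
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  expect_equal(vapply(a, `[[`, "", "id"), sprintf("phantom_%04d", 1:6))
})

test_that("negative confounder carries a muddy-like patch but no stone truth", {
  sp <- phantom_spec(include_gall = FALSE, seed = 13)
  img <- generate_negative_confounder(sp)
  expect_setequal(img$truth$class, c("spine", "liver"))
  expect_error(generate_negative_confounder(phantom_spec(seed = 1)),
               "gall-absent")
  # the patch's central region averages to the muddy band
  pb <- attr(img, "confounder_bbox")
  expect_false(is.null(pb))
  cx <- (pb[["x_min"]] + pb[["x_max"]]) / 2
  cy <- (pb[["y_min"]] + pb[["y_max"]]) / 2
  qw <- (pb[["x_max"]] - pb[["x_min"]]) / 4
  qh <- (pb[["y_max"]] - pb[["y_min"]]) / 4
  core <- img$pixels[round(cy - qh):round(cy + qh),
                     round(cx - qw):round(cx + qw)]
  expect_lt(abs(mean(core) - 120), 10)
  # determinism
  img2 <- generate_negative_confounder(sp)
  expect_identical(img$pixels, img2$pixels)
})

test_that("stone pixels concentrate in their intensity band", {
  # label/pixel consistency on a handful of phantoms (the wide sweep runs
  # in the acceptance suite)
  for (seed in c(1, 6, 12)) {
    img <- generate_phantom(phantom_spec(n_granular = 1, n_muddy = 1,
                                         seed = seed))
    bands <- c(granular_stone = 230, muddy_stone = 120)
    for (cl in names(bands)) {
      s <- img$truth[img$truth$class == cl, ]
      px <- img$pixels[(floor(s$y_min) + 1):ceiling(s$y_max),
                       (floor(s$x_min) + 1):ceiling(s$x_max)]
      frac <- mean(abs(px - bands[[cl]]) <= 2 * 8)
      expect_gte(frac, 0.6)
    }
  }
})
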