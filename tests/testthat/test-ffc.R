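# Fast Fourier convolution core: the spectral transform, squeeze-and-
# excitation attention, the FFC unit and the FFC residual block.

with_seed <- usginpaint:::with_seed

test_that("ffc_config validates and splits channels", {
  cfg <- ffc_config(8L, alpha_global = 0.5)
  expect_identical(cfg$c_local, 4L)
  expect_identical(cfg$c_global, 4L)
  expect_identical(ffc_config(8L, 0)$c_global, 0L)
  expect_identical(ffc_config(8L, 1)$c_local, 0L)
  expect_error(ffc_config(8L, kernel_size = 4L))
  expect_error(ffc_config(1L, alpha_global = 0.5), "at least one channel")
})

test_that("spectral transform preserves shape, stays real and finite", {
  w <- spectral_transform_weights(4L, seed = 1L)
  x <- with_seed(2, array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  y <- spectral_transform(x, w)
  expect_identical(dim(y), dim(x))
  expect_true(is.numeric(y))
  expect_true(all(is.finite(y)))
  # evaluation mode is deterministic
  expect_identical(y, spectral_transform(x, w))
  # non-square and batched inputs work
  xb <- with_seed(3, array(rnorm(6 * 10 * 2 * 4), c(6, 10, 2, 4)))
  yb <- usginpaint:::st_fwd(w, xb)$y
  expect_identical(dim(yb), dim(xb))
  expect_error(spectral_transform(array(NaN, c(4, 4, 4)), w), "non-finite")
})

test_that("spectral transform backward matches finite differences", {
  cfg_c <- 2L
  w <- spectral_transform_weights(cfg_c, seed = 4L)
  x <- with_seed(5, array(rnorm(4 * 6 * 1 * cfg_c), c(4, 6, 1L, cfg_c)))
  tgt <- with_seed(6, array(rnorm(length(x)), dim(x)))
  fwd <- usginpaint:::st_fwd(w, x, train = TRUE)
  dy <- 2 * (fwd$y - tgt) / length(x)
  bwd <- usginpaint:::st_bwd(w, fwd$cache, dy)
  loss_at <- function(xx) {
    y <- usginpaint:::st_fwd(w, xx, train = TRUE)$y
    mean((y - tgt)^2)
  }
  eps <- 1e-5
  idx <- with_seed(7, sample.int(length(x), 12))
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (loss_at(xp) - loss_at(xm)) / (2 * eps)
    expect_equal(bwd$dx[i], num, tolerance = 1e-5)
  }
})

test_that("SE layer gates channels multiplicatively in (0, 1)", {
  w <- se_layer_weights(6L, se_reduction = 2L, seed = 3L)
  x <- with_seed(8, array(abs(rnorm(5 * 5 * 6)) + 0.1, c(5, 5, 6)))
  r <- se_layer(x, w, return_weights = TRUE)
  expect_identical(dim(r$y), dim(x))
  expect_identical(dim(r$weights), c(1L, 6L))
  expect_true(all(r$weights > 0 & r$weights < 1))
  for (ch in 1:6)
    expect_equal(r$y[, , ch], x[, , ch] * r$weights[1, ch],
                 tolerance = 1e-12)
})

test_that("SE bottleneck width follows max(1, ceiling(C/r))", {
  expect_identical(usginpaint:::se_bottleneck_width(16L, 16L), 1L)
  expect_identical(usginpaint:::se_bottleneck_width(17L, 16L), 2L)
  expect_identical(usginpaint:::se_bottleneck_width(2L, 16L), 1L)
  expect_identical(usginpaint:::se_bottleneck_width(64L, 4L), 16L)
})

test_that("FFC unit output is shape-preserving for all channel splits", {
  x <- with_seed(9, array(rnorm(8 * 8 * 8), c(8, 8, 8)))
  for (a in c(0, 0.25, 0.5, 1)) {
    cfg <- ffc_config(8L, alpha_global = a, se_reduction = 4L)
    w <- ffc_unit_weights(cfg, seed = 2L)
    y <- ffc_unit(x, w, cfg)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  # unmerged form returns the two paths
  cfg <- ffc_config(8L, 0.5, se_reduction = 4L)
  pr <- ffc_unit(x, ffc_unit_weights(cfg, 2L), cfg, merge = FALSE)
  expect_identical(dim(pr$local)[4], 4L)
  expect_identical(dim(pr$global)[4], 4L)
})

test_that("closed-form FFC parameter count matches the weight tree", {
  for (a in c(0, 0.5, 1)) {
    cfg <- ffc_config(8L, alpha_global = a, se_reduction = 4L)
    w <- ffc_unit_weights(cfg, seed = 1L)
    expect_identical(ffc_unit_param_count(cfg),
                     as.integer(count_trainable(w)))
  }
})

test_that("FFC residual block is shape-preserving and residual", {
  cfg <- ffc_config(8L, 0.5, se_reduction = 4L)
  w <- ffc_block_weights(cfg, seed = 5L)
  x <- with_seed(10, array(rnorm(8 * 8 * 8), c(8, 8, 8)))
  y <- ffc_resnet_block(x, w, cfg)
  expect_identical(dim(y), dim(x))
  # the identity path: output minus the two-unit transform equals the input
  pr <- usginpaint:::split_pair(x, cfg)
  u1 <- usginpaint:::ffc_unit_fwd(w$u1, cfg, pr$local, pr$global)
  u2 <- usginpaint:::ffc_unit_fwd(w$u2, cfg, u1$yl, u1$yg)
  resid <- usginpaint:::merge_pair(u2$yl, u2$yg)
  expect_equal(y, x + drop(resid), tolerance = 1e-12)
})

test_that("FFC unit backward matches finite differences on the input", {
  cfg <- ffc_config(4L, 0.5, se_reduction = 2L)
  w <- ffc_unit_weights(cfg, seed = 6L)
  x <- with_seed(11, array(rnorm(4 * 4 * 1 * 4), c(4, 4, 1, 4)))
  tgt <- with_seed(12, array(rnorm(length(x)), dim(x)))
  pr <- list(local = x[, , , 1:2, drop = FALSE],
             global = x[, , , 3:4, drop = FALSE])
  fwd <- usginpaint:::ffc_unit_fwd(w, cfg, pr$local, pr$global, train = TRUE)
  y <- usginpaint:::merge_pair(fwd$yl, fwd$yg)
  dy <- 2 * (y - tgt) / length(y)
  bwd <- usginpaint:::ffc_unit_bwd(w, cfg, fwd$cache,
                                   dy[, , , 1:2, drop = FALSE],
                                   dy[, , , 3:4, drop = FALSE])
  dx <- usginpaint:::merge_pair(bwd$dxl, bwd$dxg)
  loss_at <- function(xx) {
    f <- usginpaint:::ffc_unit_fwd(w, cfg, xx[, , , 1:2, drop = FALSE],
                                   xx[, , , 3:4, drop = FALSE], train = TRUE)
    mean((usginpaint:::merge_pair(f$yl, f$yg) - tgt)^2)
  }
  eps <- 1e-5
  idx <- with_seed(13, sample.int(length(x), 10))
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(dx[i], (loss_at(xp) - loss_at(xm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})
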