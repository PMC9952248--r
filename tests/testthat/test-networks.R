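# Generator and discriminator: shapes, mask guidance, compositing,
# determinism, and the conditional patch discriminator contract.

with_seed <- usginpaint:::with_seed

tiny_cfg <- tiny_generator_config()
tiny_w <- generator_weights(tiny_cfg, seed = 1L)

test_that("generator maps a corrupted image to a same-shape (0,1) image", {
  img <- synth_clean_phantom(phantom_spec(height = 64L, width = 64L,
                                          seed = 1L))
  m <- generate_irregular_mask(64, 64, brush_params(), seed = 1L)
  i_in <- corrupt(img, m)
  y <- generator_forward(i_in, m, tiny_w, tiny_cfg)
  expect_identical(dim(y), dim(img))
  # the output sigmoid can saturate to exactly 0 or 1 in double precision
  expect_true(all(y >= 0 & y <= 1))
  expect_true(all(is.finite(y)))
  # evaluation mode is bit-deterministic
  expect_identical(y, generator_forward(i_in, m, tiny_w, tiny_cfg))
})

test_that("generator is fully convolutional across input sizes", {
  for (side in c(16L, 24L)) {
    x <- with_seed(side, array(runif(side * side * 3), c(side, side, 3)))
    m <- matrix(0, side, side); m[2:5, 2:5] <- 1
    y <- generator_forward(corrupt(x, m), m, tiny_w, tiny_cfg)
    expect_identical(dim(y), c(side, side, 3L))
  }
  x <- array(0.5, c(20, 20, 3))
  expect_error(generator_forward(x, matrix(0, 20, 20), tiny_w, tiny_cfg),
               "divisible by 8")
})

test_that("the mask channel guides the output (mask-guided contract)", {
  # same corrupted pixels, different mask channel -> different prediction:
  # the mask input is what lets the model tell holes from black pixels
  x <- array(0, c(16, 16, 3))
  m1 <- matrix(0, 16, 16); m1[3:6, 3:6] <- 1
  m2 <- matrix(0, 16, 16); m2[9:14, 9:14] <- 1
  y1 <- generator_forward(x, m1, tiny_w, tiny_cfg)
  y2 <- generator_forward(x, m2, tiny_w, tiny_cfg)
  expect_false(identical(y1, y2))
})

test_that("composite output copies known pixels and fills holes", {
  img <- with_seed(2, array(runif(16 * 16 * 3), c(16, 16, 3)))
  m <- matrix(0, 16, 16); m[5:9, 5:9] <- 1
  i_in <- corrupt(img, m)
  pred <- with_seed(3, array(runif(16 * 16 * 3), c(16, 16, 3)))
  out <- composite_output(pred, i_in, m)
  for (ch in 1:3) {
    expect_identical(out[, , ch][m == 0], img[, , ch][m == 0])
    expect_identical(out[, , ch][m == 1], pred[, , ch][m == 1])
  }
  expect_error(composite_output(pred, i_in[1:8, , ], m), "shape")
})

test_that("broadcast_mask replicates over channels and batch", {
  m <- matrix(0, 4, 4); m[1, ] <- 1
  b3 <- usginpaint:::broadcast_mask(m, c(4L, 4L, 3L))
  expect_identical(dim(b3), c(4L, 4L, 3L))
  for (ch in 1:3) expect_identical(b3[, , ch], m)
  b4 <- usginpaint:::broadcast_mask(m, c(4L, 4L, 2L, 3L))
  expect_identical(dim(b4), c(4L, 4L, 2L, 3L))
  expect_identical(b4[, , 2, 3], m)
  expect_error(usginpaint:::broadcast_mask(m, c(5L, 4L, 3L)), "spatial")
})

test_that("concat_channels stacks along the channel axis", {
  a <- array(1, c(4, 4, 2, 3))
  m <- array(0, c(4, 4, 2, 1))
  x <- usginpaint:::concat_channels(a, m)
  expect_identical(dim(x), c(4L, 4L, 2L, 4L))
  expect_true(all(x[, , , 1:3] == 1))
  expect_true(all(x[, , , 4] == 0))
})

test_that("discriminator emits a patch logit map and a feature pyramid", {
  dcfg <- discriminator_config(n_layers = 4L, base_channels = 8L)
  dw <- discriminator_weights(dcfg, seed = 2L)
  img <- with_seed(4, array(runif(64 * 64 * 3), c(64, 64, 3)))
  i_in <- img
  r <- discriminator_forward(img, i_in, dw, dcfg)
  expect_identical(dim(r$scores), c(4L, 4L, 1L))   # 64 / 2^4
  expect_identical(length(r$features), 4L)
  sides <- vapply(r$features, function(f) dim(f)[1], integer(1))
  expect_identical(sides, c(32L, 16L, 8L, 4L))
  expect_true(all(diff(sides) < 0))
  # channel doubling capped at 8x
  expect_equal(usginpaint:::disc_channels(
    discriminator_config(6L, 8L)), c(8, 16, 32, 64, 64, 64))
  expect_error(discriminator_config(n_layers = 2L))
  expect_error(discriminator_forward(img, img[1:32, , ], dw, dcfg), "shape")
})

test_that("generator backward yields finite nonzero parameter gradients", {
  x <- with_seed(5, array(runif(16 * 16 * 1 * 4), c(16, 16, 1, 4)))
  fwd <- usginpaint:::gen_fwd(tiny_w, tiny_cfg, x, train = TRUE)
  dy <- array(1 / length(fwd$y), dim(fwd$y))
  bwd <- usginpaint:::gen_bwd(tiny_w, tiny_cfg, fwd$cache, dy)
  gn <- usginpaint:::grad_norm(bwd$g)
  expect_true(is.finite(gn))
  expect_gt(gn, 0)
  expect_identical(dim(bwd$dx), dim(x))
})
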