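# Training losses: L1, adversarial, HRF perceptual, discriminator-feature,
# and the weighted total.

with_seed <- usginpaint:::with_seed

test_that("L1 loss reproduces the 2x2 hand case and basic properties", {
  a <- array(0, c(2, 2, 1))
  b <- array(0.5, c(2, 2, 1))
  expect_equal(l1_loss(a, b), 0.5)
  expect_equal(l1_loss(b, a), 0.5)           # symmetric
  expect_equal(l1_loss(a, a), 0)
  expect_error(l1_loss(a, array(0, c(2, 3, 1))), "shape")
})

test_that("L1 gradient matches finite differences", {
  a <- with_seed(1, array(rnorm(12), c(2, 2, 3)))
  b <- with_seed(2, array(rnorm(12), c(2, 2, 3)))
  g <- usginpaint:::l1_loss_grad(a, b)
  eps <- 1e-6
  for (i in c(1L, 5L, 12L)) {
    bp <- b; bp[i] <- bp[i] + eps
    bm <- b; bm[i] <- bm[i] - eps
    expect_equal(g[i], (l1_loss(a, bp) - l1_loss(a, bm)) / (2 * eps),
                 tolerance = 1e-6)
  }
})

test_that("adversarial losses at zero logits give log 4 and log 2", {
  z <- array(0, c(2, 2, 1))
  al <- adversarial_losses(z, z)
  expect_equal(al$loss_d, log(4), tolerance = 1e-12)
  expect_equal(al$loss_g, log(2), tolerance = 1e-12)
  # confident discriminator: loss_d decreases as real scores rise and fake
  # scores fall
  hi <- adversarial_losses(z + 3, z - 3)
  expect_lt(hi$loss_d, al$loss_d)
  expect_gt(hi$loss_g, al$loss_g)
  # numerically stable at extreme logits
  ex <- adversarial_losses(z + 500, z - 500)
  expect_true(is.finite(ex$loss_d) && is.finite(ex$loss_g))
  expect_error(adversarial_losses(z * NA, z), "non-finite")
})

test_that("adversarial gradients match finite differences", {
  s_r <- with_seed(3, array(rnorm(4), c(2, 2, 1)))
  s_f <- with_seed(4, array(rnorm(4), c(2, 2, 1)))
  gd <- usginpaint:::adv_grad_d(s_r, s_f)
  gg <- usginpaint:::adv_grad_g(s_f)
  eps <- 1e-6
  for (i in 1:4) {
    rp <- s_r; rp[i] <- rp[i] + eps
    rm <- s_r; rm[i] <- rm[i] - eps
    expect_equal(gd$d_real[i],
                 (adversarial_losses(rp, s_f)$loss_d -
                    adversarial_losses(rm, s_f)$loss_d) / (2 * eps),
                 tolerance = 1e-6)
    fp <- s_f; fp[i] <- fp[i] + eps
    fm <- s_f; fm[i] <- fm[i] - eps
    expect_equal(gd$d_fake[i],
                 (adversarial_losses(s_r, fp)$loss_d -
                    adversarial_losses(s_r, fm)$loss_d) / (2 * eps),
                 tolerance = 1e-6)
    expect_equal(gg[i],
                 (adversarial_losses(s_r, fp)$loss_g -
                    adversarial_losses(s_r, fm)$loss_g) / (2 * eps),
                 tolerance = 1e-6)
  }
})

test_that("identity extractor reduces the HRF loss to a plain MSE", {
  ex <- feature_extractor("identity")
  a <- with_seed(5, array(runif(8 * 8 * 3), c(8, 8, 3)))
  b <- with_seed(6, array(runif(8 * 8 * 3), c(8, 8, 3)))
  expect_equal(hrf_perceptual_loss(a, b, ex), mean((a - b)^2),
               tolerance = 1e-12)
})

test_that("seeded extractor is frozen, deterministic and discriminative", {
  ex1 <- feature_extractor("seeded", seed = 7L)
  ex2 <- feature_extractor("seeded", seed = 7L)
  expect_identical(ex1$params, ex2$params)
  a <- with_seed(7, array(runif(16 * 16 * 3), c(16, 16, 3)))
  b <- with_seed(8, array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_equal(hrf_perceptual_loss(a, a, ex1), 0)
  expect_gt(hrf_perceptual_loss(a, b, ex1), 0)
  # three tapped layers with the documented widths
  fs <- usginpaint:::fx_fwd(ex1, usginpaint:::as_ft(a))$features
  expect_identical(length(fs), 3L)
  expect_identical(vapply(fs, function(f) dim(f)[4], integer(1)),
                   c(8L, 16L, 16L))
})

test_that("discriminator feature loss is the stacked MSE", {
  fa <- list(array(1, c(2, 2, 1, 1)), array(2, c(1, 1, 1, 1)))
  fb <- list(array(2, c(2, 2, 1, 1)), array(2, c(1, 1, 1, 1)))
  expect_equal(disc_feature_loss(fa, fa), 0)
  expect_equal(disc_feature_loss(fa, fb), 0.5)   # mean(c(1, 0))
  expect_error(disc_feature_loss(fa, fb[1]), "length mismatch")
})

test_that("total loss uses eta = (10, 10, 30, 100) and recomputes exactly", {
  expect_equal(total_loss(c(1, 1, 1, 1)), 150)
  w <- loss_weights()
  expect_identical(c(w$eta1, w$eta2, w$eta3, w$eta4), c(10, 10, 30, 100))
  parts <- c(0.3, 1.2, 0.05, 0.01)
  expect_equal(total_loss(parts, w),
               10 * 0.3 + 10 * 1.2 + 30 * 0.05 + 100 * 0.01,
               tolerance = 1e-12)
  expect_error(total_loss(c(1, NA, 1, 1)), "non-finite")
  expect_error(total_loss(c(1, 1, 1)))
  expect_error(loss_weights(eta1 = -1))
})
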