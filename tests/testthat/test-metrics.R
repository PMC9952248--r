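# Evaluation metrics: SSIM, Frechet distance (FID), LPIPS-form perceptual
# distance, and mIoU.

with_seed <- usginpaint:::with_seed

test_that("SSIM of an image with itself is exactly 1", {
  img <- synth_clean_phantom(phantom_spec(height = 64L, width = 64L,
                                          seed = 1L))
  expect_equal(ssim(img, img), 1, tolerance = 0)
  expect_equal(ssim(img, img, window = "full"), 1, tolerance = 0)
  expect_equal(ssim(img[, , 1], img[, , 1]), 1, tolerance = 0)
})

test_that("SSIM is symmetric, bounded and degrades under noise", {
  a <- with_seed(2, array(runif(32 * 32 * 3), c(32, 32, 3)))
  b <- pmin(pmax(a + with_seed(3, array(rnorm(length(a), sd = 0.1),
                                        dim(a))), 0), 1)
  s <- ssim(a, b)
  expect_equal(s, ssim(b, a), tolerance = 1e-12)
  expect_true(s >= -1 && s < 1)
  c_ <- pmin(pmax(a + with_seed(4, array(rnorm(length(a), sd = 0.3),
                                         dim(a))), 0), 1)
  expect_lt(ssim(a, c_), s)
})

test_that("full-window SSIM reproduces the constant-image hand case", {
  k <- ssim_constants()
  a <- matrix(0, 8, 8)
  b <- matrix(1, 8, 8)
  expect_equal(ssim(a, b, k, window = "full"), k$c1 / (1 + k$c1),
               tolerance = 1e-12)
  # monotone decreasing in the mean separation for constants
  vals <- vapply(seq(0, 1, by = 0.25),
                 function(mu) ssim(a, matrix(mu, 8, 8), k, window = "full"),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM rejects mismatched shapes and oversized windows", {
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 9)), "shape")
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8),
                    ssim_constants(window_size = 11L)), "window")
  expect_error(ssim_constants(k1 = 0))
  # uniform-window variant also reaches exactly 1 on identical inputs
  u <- with_seed(10, matrix(runif(144), 12))
  expect_equal(ssim(u, u, ssim_constants(window_kind = "uniform")), 1,
               tolerance = 0)
})

test_that("FID of identical feature statistics is 0 within 1e-8", {
  x <- with_seed(5, matrix(rnorm(500 * 8), 500, 8))
  st <- feature_stats(x)
  expect_lt(abs(fid(st, st)), 1e-8)
})

test_that("FID matches the 1-D Gaussian closed form", {
  mk <- function(mu, s2, n = 10L)
    structure(list(mu = mu, sigma = matrix(s2, 1, 1), n = n),
              class = "feature_stats")
  # unit variance, means 0 vs 1 -> exactly 1
  expect_equal(fid(mk(0, 1), mk(1, 1)), 1, tolerance = 1e-10)
  # 100 random scalar cases against (mu1-mu2)^2 + s1 + s2 - 2 sqrt(s1 s2)
  prm <- with_seed(6, cbind(rnorm(100), rnorm(100),
                            runif(100, 0.1, 4), runif(100, 0.1, 4)))
  for (i in 1:100) {
    got <- fid(mk(prm[i, 1], prm[i, 3]), mk(prm[i, 2], prm[i, 4]))
    want <- (prm[i, 1] - prm[i, 2])^2 + prm[i, 3] + prm[i, 4] -
      2 * sqrt(prm[i, 3] * prm[i, 4])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("FID is symmetric and detects a mean shift in 8 dimensions", {
  a <- with_seed(7, matrix(rnorm(400 * 8), 400, 8))
  b <- a + 0.5
  sa <- feature_stats(a); sb <- feature_stats(b)
  expect_equal(fid(sa, sb), fid(sb, sa), tolerance = 1e-8)
  # equal covariances: distance is exactly the squared mean difference
  expect_equal(fid(sa, sb), sum((sa$mu - sb$mu)^2), tolerance = 1e-8)
  expect_error(fid(sa, feature_stats(a[, 1:4])), "dimension mismatch")
  expect_error(feature_stats(matrix(0, 1, 3)))
})

test_that("LPIPS is zero for identical images and positive otherwise", {
  ex <- feature_extractor("seeded", seed = 7L)
  a <- with_seed(8, array(runif(16 * 16 * 3), c(16, 16, 3)))
  b <- with_seed(9, array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_equal(lpips(a, a, ex), 0)
  expect_gt(lpips(a, b, ex), 0)
  expect_equal(lpips(a, b, ex), lpips(b, a, ex), tolerance = 1e-12)
  expect_error(lpips(a, b[1:8, , ], ex), "shape")
})

test_that("LPIPS channel weights scale layers quadratically", {
  ex <- feature_extractor("identity")
  a <- array(0.2, c(4, 4, 3))
  b <- array(0.4, c(4, 4, 3))
  base <- lpips(a, b, ex)
  doubled <- lpips(a, b, ex, channel_weights = list(rep(2, 3)))
  expect_equal(doubled, 4 * base, tolerance = 1e-12)
  expect_error(lpips(a, b, ex, channel_weights = list(rep(1, 2))),
               "channel weights")
})

test_that("mIoU reproduces the 4x4 worked case (11/21)", {
  # gt foreground 4 px, pred foreground 4 px, overlapping in 2 px
  gt <- matrix(0L, 4, 4); gt[1, 1:4] <- 1L
  pred <- matrix(0L, 4, 4); pred[1, 1:2] <- 1L; pred[2, 1:2] <- 1L
  expect_equal(unclass(miou(pred, gt, 2L))[1], 11 / 21, tolerance = 1e-12)
  expect_equal(unclass(miou(gt, gt, 2L))[1], 1)
  # disjoint full-frame classes -> 0
  expect_equal(unclass(miou(matrix(1L, 4, 4), matrix(0L, 4, 4), 2L))[1], 0)
})

test_that("mIoU counts classes absent from both maps as IoU 1", {
  gt <- matrix(0L, 3, 3)
  pred <- matrix(0L, 3, 3)
  m <- miou(pred, gt, 3L)   # classes 1 and 2 absent everywhere
  expect_equal(unclass(m)[1], 1)
  expect_identical(attr(m, "absent_classes"), c(1L, 2L))
  expect_error(miou(matrix(5L, 2, 2), matrix(0L, 2, 2), 2L), "label")
  expect_error(seg_confusion(matrix(0L, 2, 2), matrix(0L, 3, 2), 2L),
               "shape")
})

test_that("mIoU agrees with brute-force counting on random label maps", {
  brute <- function(pred, gt, k1) {
    iou <- numeric(k1)
    for (c0 in 0:(k1 - 1)) {
      inter <- sum(pred == c0 & gt == c0)
      uni <- sum(pred == c0 | gt == c0)
      iou[c0 + 1] <- if (uni == 0) 1 else inter / uni
    }
    mean(iou)
  }
  for (s in 1:25) {
    k1 <- 2L + (s %% 3L)
    pred <- with_seed(100 + s, matrix(sample(0:(k1 - 1), 64, TRUE), 8, 8))
    gt <- with_seed(200 + s, matrix(sample(0:(k1 - 1), 64, TRUE), 8, 8))
    expect_equal(unclass(miou(pred, gt, k1))[1], brute(pred, gt, k1),
                 tolerance = 1e-12)
  }
})
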