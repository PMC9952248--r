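## Image-quality and segmentation metrics: windowed structural similarity
## (SSIM), the Frechet distance between Gaussian fits of deep-feature
## distributions (FID), a layer-wise channel-normalized deep-feature
## distance (LPIPS-style, with a pluggable extractor), and mean
## intersection-over-union for label maps.

#' SSIM constants
#'
#' @param k1,k2 dimensionless stabilizers (standard 0.01 and 0.03).
#' @param dynamic_range the value range `L` of the images (1 for \[0, 1\]).
#' @param window_size sliding-window side in pixels.
#' @param window_kind `"gaussian"` (sigma 1.5, the universally reported
#'   variant) or `"uniform"`; `ssim(..., window = "full")` bypasses the
#'   sliding window entirely.
#' @return an `ssim_constants` list with `c1 = (k1 L)^2`, `c2 = (k2 L)^2`.
#' @export
ssim_constants <- function(k1 = 0.01, k2 = 0.03, dynamic_range = 1,
                           window_size = 11L,
                           window_kind = c("gaussian", "uniform")) {
  window_kind <- match.arg(window_kind)
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  stopifnot(c1 > 0, c2 > 0, window_size >= 1)
  structure(list(k1 = k1, k2 = k2, dynamic_range = dynamic_range,
                 window_size = as.integer(window_size),
                 window_kind = window_kind, c1 = c1, c2 = c2),
            class = "ssim_constants")
}

## Valid-region weighted local mean of a matrix under window weights wt.
local_mean <- function(x, wt) {
  k <- nrow(wt)
  ic <- im2col(array(x, c(dim(x), 1L, 1L)), k, 1L, 0L, 1L)
  drop(ic$cols %*% as.vector(wt))
}

ssim_channel <- function(a, b, consts) {
  k <- consts$window_size
  if (k > min(dim(a)))
    stop("ssim: window larger than image; use window = \"full\"")
  wt <- if (consts$window_kind == "gaussian") {
    g <- stats::dnorm(seq_len(k) - (k + 1) / 2, sd = 1.5)
    w2 <- outer(g, g)
    w2 / sum(w2)
  } else matrix(1 / (k * k), k, k)
  mu_a <- local_mean(a, wt)
  mu_b <- local_mean(b, wt)
  va <- local_mean(a * a, wt) - mu_a^2
  vb <- local_mean(b * b, wt) - mu_b^2
  cab <- local_mean(a * b, wt) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + consts$c1) * (2 * cab + consts$c2)
  den <- (mu_a^2 + mu_b^2 + consts$c1) * (va + vb + consts$c2)
  mean(num / den)
}

ssim_full_channel <- function(a, b, consts) {
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean(a^2) - mu_a^2
  vb <- mean(b^2) - mu_b^2
  cab <- mean(a * b) - mu_a * mu_b
  ((2 * mu_a * mu_b + consts$c1) * (2 * cab + consts$c2)) /
    ((mu_a^2 + mu_b^2 + consts$c1) * (va + vb + consts$c2))
}

#' Structural similarity between two images
#'
#' Evaluates the SSIM formula per sliding window and averages over windows
#' and channels; 1 means identical images, values lie in \[-1, 1\].
#'
#' @param a,b images of identical shape (`H x W` matrices or `H x W x C`).
#' @param consts an [ssim_constants()].
#' @param window `"sliding"` (default) or `"full"`: one global window over
#'   the whole frame (the hand-checkable degenerate form).
#' @return scalar SSIM.
#' @export
ssim <- function(a, b, consts = ssim_constants(),
                 window = c("sliding", "full")) {
  window <- match.arg(window)
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch")
  if (is.matrix(a)) { dim(a) <- c(dim(a), 1L); dim(b) <- dim(a) }
  f <- if (window == "full") ssim_full_channel else ssim_channel
  mean(vapply(seq_len(dim(a)[3]),
              function(ch) f(a[, , ch], b[, , ch], consts), numeric(1)))
}

## ---- FID -----------------------------------------------------------------

#' Gaussian feature statistics of a feature-vector set
#'
#' @param x `n x d` matrix of feature vectors (rows = images).
#' @return a `feature_stats` list with mean vector `mu`, covariance `sigma`
#'   and sample count `n`.
#' @export
feature_stats <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  structure(list(mu = colMeans(x), sigma = stats::cov(x), n = nrow(x)),
            class = "feature_stats")
}

## Symmetric PSD square root via eigendecomposition; small negative
## eigenvalues (numerical) are clamped to zero.
sqrtm_psd <- function(s) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Frechet distance between two Gaussian feature fits
#'
#' `||mu_1 - mu_2||^2 + Tr(S_1 + S_2 - 2 (S_1 S_2)^{1/2})`, the FID formula.
#' The matrix square root is computed as
#' `S_1^{1/2} (S_1^{1/2} S_2 S_1^{1/2})^{1/2} S_1^{-1/2}` reduced to its
#' trace, i.e. `Tr((S_1 S_2)^{1/2}) = Tr((S_1^{1/2} S_2 S_1^{1/2})^{1/2})`,
#' via symmetric eigendecompositions with negative eigenvalues clamped at 0.
#'
#' @param stats_gt,stats_pred [feature_stats()] of equal dimension.
#' @return scalar distance, >= 0 up to numerical tolerance; exactly the
#'   squared-mean term when both covariances are equal.
#' @export
fid <- function(stats_gt, stats_pred) {
  stopifnot(inherits(stats_gt, "feature_stats"),
            inherits(stats_pred, "feature_stats"))
  if (length(stats_gt$mu) != length(stats_pred$mu))
    stop("fid: feature dimension mismatch: ", length(stats_gt$mu), " vs ",
         length(stats_pred$mu))
  s1h <- sqrtm_psd(stats_gt$sigma)
  inner <- s1h %*% stats_pred$sigma %*% s1h
  ev <- eigen((inner + t(inner)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (any(!is.finite(ev)))
    stop("fid: matrix square root failed; covariance condition numbers: ",
         paste(signif(c(kappa(stats_gt$sigma), kappa(stats_pred$sigma)), 3),
               collapse = ", "))
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  sum((stats_gt$mu - stats_pred$mu)^2) +
    sum(diag(stats_gt$sigma)) + sum(diag(stats_pred$sigma)) - 2 * tr_sqrt
}

## ---- LPIPS-style perceptual distance --------------------------------------

#' Layer-wise channel-normalized deep-feature distance (LPIPS form)
#'
#' Per extractor layer the features are unit-normalized along channels,
#' scaled by per-channel weights `w_l`, and the squared l2 differences are
#' averaged over spatial positions; the layer values are summed. Calibrated
#' channel weights are out of scope; `w_l = 1` by default.
#'
#' @param a,b images of identical shape.
#' @param extractor a [feature_extractor()].
#' @param channel_weights optional list of per-layer weight vectors.
#' @return scalar distance >= 0; 0 for identical images.
#' @export
lpips <- function(a, b, extractor = feature_extractor(),
                  channel_weights = NULL) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (!identical(dim(a), dim(b))) stop("lpips: shape mismatch")
  fa <- fx_fwd(extractor, as_ft(a))$features
  fb <- fx_fwd(extractor, as_ft(b))$features
  if (!is.null(channel_weights) && length(channel_weights) != length(fa))
    stop("lpips: channel_weights must have one vector per layer")
  total <- 0
  for (l in seq_along(fa)) {
    ya <- unit_normalize_channels(fa[[l]])
    yb <- unit_normalize_channels(fb[[l]])
    d <- dim(ya)
    wl <- if (is.null(channel_weights)) rep(1, d[4]) else channel_weights[[l]]
    if (length(wl) != d[4])
      stop("lpips: layer ", l, " expects ", d[4], " channel weights")
    diff2 <- (ya - yb)^2
    ## w_l scales channels before the l2 norm: sum_c (w_c * delta_c)^2
    dim(diff2) <- c(d[1] * d[2] * d[3], d[4])
    wsum <- diff2 %*% (wl^2)
    total <- total + sum(wsum) / (d[1] * d[2]) / d[3]
  }
  total
}

## Unit l2 normalization along the channel (last) dimension of an
## H x W x N x C array (zero vectors stay zero).
unit_normalize_channels <- function(x) {
  d <- dim(x)
  x2 <- x^2
  dim(x2) <- c(d[1] * d[2] * d[3], d[4])
  nrm <- sqrt(rowSums(x2))
  nrm[nrm == 0] <- 1
  x / array(rep(nrm, d[4]), d)
}

## ---- mIoU ------------------------------------------------------------------

#' Per-class confusion counts for label maps
#'
#' @param pred_labels,gt_labels integer label matrices of equal shape with
#'   values in `0:(k_plus_1 - 1)`.
#' @param k_plus_1 number of classes.
#' @return a `seg_confusion` list of per-class TP, FP, FN.
#' @export
seg_confusion <- function(pred_labels, gt_labels, k_plus_1) {
  if (!identical(dim(pred_labels), dim(gt_labels)))
    stop("seg_confusion: shape mismatch")
  labs <- 0:(k_plus_1 - 1)
  if (any(!(pred_labels %in% labs)) || any(!(gt_labels %in% labs)))
    stop("seg_confusion: label out of range 0..", k_plus_1 - 1)
  tp <- fp <- fn <- numeric(k_plus_1)
  for (i in seq_len(k_plus_1)) {
    cl <- labs[i]
    tp[i] <- sum(pred_labels == cl & gt_labels == cl)
    fp[i] <- sum(pred_labels == cl & gt_labels != cl)
    fn[i] <- sum(pred_labels != cl & gt_labels == cl)
  }
  structure(list(tp = tp, fp = fp, fn = fn, k_plus_1 = k_plus_1),
            class = "seg_confusion")
}

#' Mean intersection-over-union of two label maps
#'
#' Per class `IoU = TP / (TP + FP + FN)`, averaged over all classes. A class
#' absent from both maps (0/0) contributes IoU 1 by convention, recorded in
#' the `absent_classes` attribute because the ratio is undefined there.
#'
#' @inheritParams seg_confusion
#' @return scalar mIoU in \[0, 1\].
#' @export
miou <- function(pred_labels, gt_labels, k_plus_1) {
  cf <- seg_confusion(pred_labels, gt_labels, k_plus_1)
  denom <- cf$tp + cf$fp + cf$fn
  iou <- ifelse(denom == 0, 1, cf$tp / denom)
  out <- mean(iou)
  attr(out, "absent_classes") <- which(denom == 0) - 1L
  out
}
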