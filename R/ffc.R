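## Fast Fourier convolution (FFC): a convolution unit whose input channels
## are split into a local path (ordinary k x k convolution) and a global
## path that convolves in the frequency domain after a real 2-D FFT, giving
## every layer an image-wide receptive field. A squeeze-and-excitation (SE)
## channel-attention layer sits after the spectral transform on the global
## path so the unit can down-weight channels that carry annotation-symbol
## features.

#' FFC unit configuration
#'
#' @param channels total number of channels entering/leaving the unit.
#' @param alpha_global fraction of channels routed to the global (spectral)
#'   path; `0` degenerates to a plain convolution, `1` to a purely spectral
#'   unit.
#' @param kernel_size odd kernel size of the local-path convolutions.
#' @param se_reduction divisor for the SE excitation bottleneck width
#'   (`max(1, ceiling(C_g / se_reduction))`).
#' @param norm_epsilon batch-normalization stabilizer.
#' @return a validated `ffc_config` list.
#' @export
ffc_config <- function(channels, alpha_global = 0.5, kernel_size = 3L,
                       se_reduction = 16L, norm_epsilon = 1e-5) {
  stopifnot(channels >= 1, alpha_global >= 0, alpha_global <= 1,
            kernel_size >= 1, kernel_size %% 2 == 1, se_reduction >= 1,
            norm_epsilon > 0)
  cg <- as.integer(round(channels * alpha_global))
  cl <- as.integer(channels) - cg
  if (alpha_global > 0 && alpha_global < 1 && (cg < 1 || cl < 1))
    stop("ffc_config: both paths need at least one channel at alpha_global = ",
         alpha_global)
  structure(list(channels = as.integer(channels), alpha_global = alpha_global,
                 kernel_size = as.integer(kernel_size),
                 se_reduction = as.integer(se_reduction),
                 norm_epsilon = norm_epsilon, c_local = cl, c_global = cg),
            class = "ffc_config")
}

## Coerce an H x W x C array to the internal (H, W, N, C) batched layout;
## for a single image this is a pure reshape (same memory order).
as_ft <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1], d[2], 1L, d[3])
  ft_check(x)
  x
}

drop_batch <- function(y, had3) {
  if (had3) dim(y) <- dim(y)[c(1L, 2L, 4L)]
  y
}

## ---- spectral transform -------------------------------------------------

st_init <- function(c) {
  list(conv = conv_init(2L * c, 2L * c, 1L), bn = bn_init(2L * c))
}

## Five steps: real FFT; concatenate real/imaginary parts along channels
## (C -> 2C); 1x1 convolution + batch norm + ReLU in the frequency domain;
## split back to complex; inverse real FFT.
st_fwd <- function(p, x, train = FALSE, eps = 1e-5) {
  if (!all(is.finite(x))) stop("spectral_transform: non-finite input")
  d <- dim(x)
  cC <- d[4]
  y <- rfft2_batch(x)
  wh <- dim(y)[2]
  xr <- array(0, c(d[1], wh, d[3], 2L * cC))
  xr[, , , seq_len(cC)] <- Re(y)
  xr[, , , cC + seq_len(cC)] <- Im(y)
  cv <- conv_fwd(p$conv, xr)
  bn <- bn_fwd(p$bn, cv$y, train, eps = eps)
  p$bn <- bn$p
  rl <- relu_fwd(bn$y)
  re <- rl$y[, , , seq_len(cC), drop = FALSE]
  im <- rl$y[, , , cC + seq_len(cC), drop = FALSE]
  out <- irfft2_batch(re + 1i * im, d[2])
  list(y = out, p = p,
       cache = list(conv = cv$cache, bn = bn$cache, rl = rl$cache,
                    d = d, wh = wh))
}

st_bwd <- function(p, cache, dy) {
  d <- cache$d
  cC <- d[4]
  a <- irfft2_adjoint(dy, cache$wh)
  dr <- array(0, c(d[1], cache$wh, d[3], 2L * cC))
  dr[, , , seq_len(cC)] <- a$d_re
  dr[, , , cC + seq_len(cC)] <- a$d_im
  dr <- relu_bwd(cache$rl, dr)
  bb <- bn_bwd(p$bn, cache$bn, dr)
  cb <- conv_bwd(p$conv, cache$conv, bb$dx)
  dre <- cb$dx[, , , seq_len(cC), drop = FALSE]
  dim_ <- cb$dx[, , , cC + seq_len(cC), drop = FALSE]
  dx <- rfft2_adjoint(dre, dim_, d[2])
  list(dx = dx, g = list(conv = cb$g, bn = bb$g))
}

#' Create seeded weights for a stand-alone spectral transform
#'
#' @param channels number of input (= output) channels.
#' @param seed integer seed for the weight initialization.
#' @return a weight tree consumable by [spectral_transform()].
#' @export
spectral_transform_weights <- function(channels, seed = 1L) {
  with_seed(seed, st_init(as.integer(channels)))
}

#' Spectral transform of the FFC global path
#'
#' Applies, in order: real 2-D FFT over the spatial axes, concatenation of
#' the real and imaginary parts along channels, a 1x1 convolution with
#' batch normalization and ReLU in the frequency domain, a split back into
#' a complex spectrum, and the inverse real FFT. Output shape equals input
#' shape and the result is real.
#'
#' @param x `H x W x C` (or `H x W x C x N`) real array, `H, W >= 2`.
#' @param weights from [spectral_transform_weights()].
#' @param train logical; use batch statistics (and update running buffers)
#'   instead of the stored running statistics.
#' @return a real array shaped like `x`.
#' @export
spectral_transform <- function(x, weights, train = FALSE) {
  had3 <- length(dim(x)) == 3L
  x <- as_ft(x)
  stopifnot(dim(x)[1] >= 2, dim(x)[2] >= 2)
  drop_batch(st_fwd(weights, x, train = train)$y, had3)
}

#' Create seeded weights for a squeeze-and-excitation layer
#'
#' @param channels number of channels gated by the layer.
#' @param se_reduction excitation bottleneck divisor.
#' @param seed integer seed.
#' @return a weight tree consumable by [se_layer()].
#' @export
se_layer_weights <- function(channels, se_reduction = 16L, seed = 1L) {
  with_seed(seed, se_init(as.integer(channels), as.integer(se_reduction)))
}

#' Squeeze-and-excitation channel attention
#'
#' Squeeze: spatial mean per channel. Excitation: a `C -> C/r -> C`
#' bottleneck with ReLU then sigmoid, producing per-channel weights in
#' (0, 1). Reweight: channel-wise multiplication broadcast over space.
#'
#' @param x `H x W x C` (or 4-D) array.
#' @param weights from [se_layer_weights()].
#' @param return_weights also return the per-channel gate values.
#' @return the reweighted array, or (with `return_weights`) a list with
#'   elements `y` and `weights` (an `N x C` matrix of gates).
#' @export
se_layer <- function(x, weights, return_weights = FALSE) {
  had3 <- length(dim(x)) == 3L
  x <- as_ft(x)
  r <- se_fwd(weights, x)
  if (return_weights) list(y = drop_batch(r$y, had3), weights = r$weights)
  else drop_batch(r$y, had3)
}

## ---- FFC unit -----------------------------------------------------------

ffc_unit_init <- function(cfg) {
  cl <- cfg$c_local
  cg <- cfg$c_global
  k <- cfg$kernel_size
  p <- list()
  if (cl > 0L) {
    p$conv_ll <- conv_init(cl, cl, k)
    p$bn_l <- bn_init(cl)
    if (cg > 0L) p$conv_gl <- conv_init(cg, cl, k)
  }
  if (cg > 0L) {
    p$st <- st_init(cg)
    p$se <- se_init(cg, cfg$se_reduction)
    p$bn_g <- bn_init(cg)
    if (cl > 0L) p$conv_lg <- conv_init(cl, cg, k)
  }
  p
}

## Four cross-path transforms: local->local and global->local by k x k
## convolution, local->global by k x k convolution, global->global by the
## spectral transform followed by SE attention. Each path sums its inputs,
## then batch norm + ReLU.
ffc_unit_fwd <- function(p, cfg, xl, xg, train = FALSE) {
  k <- cfg$kernel_size
  pd <- (k - 1L) %/% 2L
  cache <- list()
  yl <- NULL
  yg <- NULL
  if (cfg$c_local > 0L) {
    cll <- conv_fwd(p$conv_ll, xl, pad = pd)
    cache$cll <- cll$cache
    sl <- cll$y
    if (cfg$c_global > 0L) {
      cgl <- conv_fwd(p$conv_gl, xg, pad = pd)
      cache$cgl <- cgl$cache
      sl <- sl + cgl$y
    }
    bnl <- bn_fwd(p$bn_l, sl, train, eps = cfg$norm_epsilon)
    p$bn_l <- bnl$p
    rll <- relu_fwd(bnl$y)
    cache$bn_l <- bnl$cache
    cache$rl_l <- rll$cache
    yl <- rll$y
  }
  if (cfg$c_global > 0L) {
    st <- st_fwd(p$st, xg, train, eps = cfg$norm_epsilon)
    p$st <- st$p
    se <- se_fwd(p$se, st$y)
    cache$st <- st$cache
    cache$se <- se$cache
    sg <- se$y
    if (cfg$c_local > 0L) {
      clg <- conv_fwd(p$conv_lg, xl, pad = pd)
      cache$clg <- clg$cache
      sg <- sg + clg$y
    }
    bng <- bn_fwd(p$bn_g, sg, train, eps = cfg$norm_epsilon)
    p$bn_g <- bng$p
    rlg <- relu_fwd(bng$y)
    cache$bn_g <- bng$cache
    cache$rl_g <- rlg$cache
    yg <- rlg$y
  }
  list(yl = yl, yg = yg, p = p, cache = cache)
}

ffc_unit_bwd <- function(p, cfg, cache, dyl, dyg) {
  g <- list()
  dxl <- NULL
  dxg <- NULL
  if (cfg$c_global > 0L) {
    dg <- relu_bwd(cache$rl_g, dyg)
    bb <- bn_bwd(p$bn_g, cache$bn_g, dg)
    g$bn_g <- bb$g
    if (cfg$c_local > 0L) {
      cb <- conv_bwd(p$conv_lg, cache$clg, bb$dx)
      g$conv_lg <- cb$g
      dxl <- cb$dx
    }
    sb <- se_bwd(p$se, cache$se, bb$dx)
    g$se <- sb$g
    stb <- st_bwd(p$st, cache$st, sb$dx)
    g$st <- stb$g
    dxg <- stb$dx
  }
  if (cfg$c_local > 0L) {
    dl <- relu_bwd(cache$rl_l, dyl)
    bb <- bn_bwd(p$bn_l, cache$bn_l, dl)
    g$bn_l <- bb$g
    cb <- conv_bwd(p$conv_ll, cache$cll, bb$dx)
    g$conv_ll <- cb$g
    dxl <- if (is.null(dxl)) cb$dx else dxl + cb$dx
    if (cfg$c_global > 0L) {
      cb2 <- conv_bwd(p$conv_gl, cache$cgl, bb$dx)
      g$conv_gl <- cb2$g
      dxg <- dxg + cb2$dx
    }
  }
  list(dxl = dxl, dxg = dxg, g = g)
}

## ---- FFC residual block --------------------------------------------------

ffc_block_init <- function(cfg) {
  list(u1 = ffc_unit_init(cfg), u2 = ffc_unit_init(cfg))
}

ffc_block_fwd <- function(p, cfg, xl, xg, train = FALSE) {
  u1 <- ffc_unit_fwd(p$u1, cfg, xl, xg, train)
  p$u1 <- u1$p
  u2 <- ffc_unit_fwd(p$u2, cfg, u1$yl, u1$yg, train)
  p$u2 <- u2$p
  yl <- if (cfg$c_local > 0L) xl + u2$yl else NULL
  yg <- if (cfg$c_global > 0L) xg + u2$yg else NULL
  list(yl = yl, yg = yg, p = p, cache = list(u1 = u1$cache, u2 = u2$cache))
}

ffc_block_bwd <- function(p, cfg, cache, dyl, dyg) {
  b2 <- ffc_unit_bwd(p$u2, cfg, cache$u2, dyl, dyg)
  b1 <- ffc_unit_bwd(p$u1, cfg, cache$u1, b2$dxl, b2$dxg)
  dxl <- if (cfg$c_local > 0L) dyl + b1$dxl else NULL
  dxg <- if (cfg$c_global > 0L) dyg + b1$dxg else NULL
  list(dxl = dxl, dxg = dxg, g = list(u1 = b1$g, u2 = b2$g))
}

## ---- user-facing wrappers over (local, global) channel pairs -------------

split_pair <- function(x, cfg) {
  x <- as_ft(x)
  stopifnot(dim(x)[4] == cfg$channels)
  list(local = if (cfg$c_local > 0L)
         x[, , , seq_len(cfg$c_local), drop = FALSE],
       global = if (cfg$c_global > 0L)
         x[, , , cfg$c_local + seq_len(cfg$c_global), drop = FALSE])
}

merge_pair <- function(yl, yg) {
  if (is.null(yg)) return(yl)
  if (is.null(yl)) return(yg)
  d <- dim(yl)
  ## channels are the last dim, so concatenation is contiguous
  array(c(yl, yg), c(d[1], d[2], d[3], d[4] + dim(yg)[4]))
}

#' Seeded weights for one FFC unit
#'
#' @param config an [ffc_config()].
#' @param seed integer seed.
#' @return weight tree for [ffc_unit()].
#' @export
ffc_unit_weights <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ffc_config"))
  with_seed(seed, ffc_unit_init(config))
}

#' Apply one fast Fourier convolution unit
#'
#' The input channels are split into a local part (first `C_l` channels)
#' and a global part; the four cross-path transforms are applied, each path
#' is normalized and activated, and (by default) the two paths are merged
#' back into a single `H x W x C` tensor.
#'
#' @param x `H x W x C` (or 4-D) array with `C = config$channels`.
#' @param weights from [ffc_unit_weights()].
#' @param config the [ffc_config()] the weights were built with.
#' @param train logical, batch-norm mode.
#' @param merge merge the local/global outputs back along channels; when
#'   `FALSE` a list with elements `local` and `global` is returned.
#' @return array (or pair list) with the same spatial size and `C` channels.
#' @export
ffc_unit <- function(x, weights, config, train = FALSE, merge = TRUE) {
  had3 <- length(dim(x)) == 3L
  pr <- split_pair(x, config)
  r <- ffc_unit_fwd(weights, config, pr$local, pr$global, train)
  if (merge) drop_batch(merge_pair(r$yl, r$yg), had3)
  else list(local = r$yl, global = r$yg)
}

#' Seeded weights for one FFC residual block
#'
#' @inheritParams ffc_unit_weights
#' @return weight tree for [ffc_resnet_block()].
#' @export
ffc_block_weights <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ffc_config"))
  with_seed(seed, ffc_block_init(config))
}

#' Apply one FFC residual block
#'
#' Two FFC units with an identity residual connection added to both the
#' local and the global path; shape preserving. Nine such blocks form the
#' generator trunk.
#'
#' @inheritParams ffc_unit
#' @return array with the same shape as `x`.
#' @export
ffc_resnet_block <- function(x, weights, config, train = FALSE) {
  had3 <- length(dim(x)) == 3L
  pr <- split_pair(x, config)
  r <- ffc_block_fwd(weights, config, pr$local, pr$global, train)
  drop_batch(merge_pair(r$yl, r$yg), had3)
}

#' Closed-form trainable-parameter count of an FFC unit
#'
#' Counts every weight, bias and batch-norm affine parameter of the four
#' cross-path transforms from the configuration alone (running statistics
#' are buffers, not parameters).
#'
#' @param config an [ffc_config()].
#' @return integer parameter count.
#' @export
ffc_unit_param_count <- function(config) {
  cl <- config$c_local
  cg <- config$c_global
  k <- config$kernel_size
  conv_n <- function(ci, co, kk) kk * kk * ci * co + co
  n <- 0L
  if (cl > 0L) {
    n <- n + conv_n(cl, cl, k) + 2L * cl            # conv_ll + bn_l affine
    if (cg > 0L) n <- n + conv_n(cg, cl, k)         # conv_gl
  }
  if (cg > 0L) {
    n <- n + conv_n(2L * cg, 2L * cg, 1L) + 2L * (2L * cg)  # spectral conv + bn
    cr <- se_bottleneck_width(cg, config$se_reduction)
    n <- n + (cg * cr + cr) + (cr * cg + cg)        # SE bottleneck
    n <- n + 2L * cg                                # bn_g affine
    if (cl > 0L) n <- n + conv_n(cl, cg, k)         # conv_lg
  }
  as.integer(n)
}
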