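## The mask-guided generator and the conditional patch discriminator.
##
## Generator: [corrupted image (+) mask channel] -> stem convolution ->
## three stride-2 downsampling convolutions -> nine FFC residual blocks ->
## three transposed-convolution upsampling stages -> output projection with
## a sigmoid squashing to [0, 1]. The mask enters as a fourth input channel
## ("mask-guided"): the corrupted image alone cannot distinguish true black
## pixels from holes.

#' Generator configuration
#'
#' @param channels four widths: the stem convolution and the three
#'   stride-2 downsampling stages (the last is the FFC trunk width).
#'   Default is the full-scale schedule; see [tiny_generator_config()] for
#'   a CPU-friendly preset.
#' @param n_ffc_blocks number of FFC residual blocks in the trunk.
#' @param alpha_global global-path channel fraction inside the trunk.
#' @param se_reduction SE bottleneck divisor inside the trunk.
#' @param input_includes_mask concatenate the hole mask as an input channel.
#' @return a `generator_config` list.
#' @export
generator_config <- function(channels = c(64L, 128L, 256L, 512L),
                             n_ffc_blocks = 9L, alpha_global = 0.5,
                             se_reduction = 16L, input_includes_mask = TRUE) {
  stopifnot(length(channels) == 4L, all(channels >= 1), n_ffc_blocks >= 1)
  structure(list(channels = as.integer(channels),
                 n_downsample = 3L,
                 n_ffc_blocks = as.integer(n_ffc_blocks),
                 alpha_global = alpha_global,
                 se_reduction = as.integer(se_reduction),
                 input_includes_mask = isTRUE(input_includes_mask),
                 ffc = ffc_config(channels[4], alpha_global,
                                  se_reduction = se_reduction)),
            class = "generator_config")
}

#' Desk-scale generator preset (16-channel stem, 64-channel trunk)
#'
#' @inheritParams generator_config
#' @return a `generator_config`.
#' @export
tiny_generator_config <- function(alpha_global = 0.5, se_reduction = 4L,
                                  n_ffc_blocks = 9L) {
  generator_config(channels = c(16L, 32L, 64L, 64L),
                   n_ffc_blocks = n_ffc_blocks,
                   alpha_global = alpha_global, se_reduction = se_reduction)
}

gen_init <- function(cfg) {
  ch <- cfg$channels
  cin <- 3L + as.integer(cfg$input_includes_mask)
  p <- list(
    stem = conv_init(cin, ch[1], 3L), bn_stem = bn_init(ch[1]),
    down1 = conv_init(ch[1], ch[2], 3L), bn_d1 = bn_init(ch[2]),
    down2 = conv_init(ch[2], ch[3], 3L), bn_d2 = bn_init(ch[3]),
    down3 = conv_init(ch[3], ch[4], 3L), bn_d3 = bn_init(ch[4]),
    blocks = lapply(seq_len(cfg$n_ffc_blocks),
                    function(i) ffc_block_init(cfg$ffc)),
    up3 = convt_init(ch[4], ch[3]), bn_u3 = bn_init(ch[3]),
    up2 = convt_init(ch[3], ch[2]), bn_u2 = bn_init(ch[2]),
    up1 = convt_init(ch[2], ch[1]), bn_u1 = bn_init(ch[1]),
    out = conv_init(ch[1], 3L, 3L, gain = 1)
  )
  names(p$blocks) <- paste0("b", seq_len(cfg$n_ffc_blocks))
  p
}

#' Seeded generator weights
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a weight tree for [generator_forward()].
#' @export
generator_weights <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, gen_init(config))
}

## conv + bn + relu stage helper
cbr_fwd <- function(pc, pb, x, stride, train, transpose = FALSE) {
  cv <- if (transpose) convt_fwd(pc, x, stride) else
    conv_fwd(pc, x, stride = stride, pad = 1L)
  bn <- bn_fwd(pb, cv$y, train)
  rl <- relu_fwd(bn$y)
  list(y = rl$y, pb = bn$p,
       cache = list(cv = cv$cache, bn = bn$cache, rl = rl$cache))
}

cbr_bwd <- function(pc, pb, cache, dy, transpose = FALSE) {
  dr <- relu_bwd(cache$rl, dy)
  bb <- bn_bwd(pb, cache$bn, dr)
  cb <- if (transpose) convt_bwd(pc, cache$cv, bb$dx) else
    conv_bwd(pc, cache$cv, bb$dx)
  list(dx = cb$dx, gc = cb$g, gb = bb$g)
}

gen_fwd <- function(p, cfg, x, train = FALSE) {
  ca <- list()
  s <- cbr_fwd(p$stem, p$bn_stem, x, 1L, train); p$bn_stem <- s$pb
  ca$stem <- s$cache
  d1 <- cbr_fwd(p$down1, p$bn_d1, s$y, 2L, train); p$bn_d1 <- d1$pb
  ca$d1 <- d1$cache
  d2 <- cbr_fwd(p$down2, p$bn_d2, d1$y, 2L, train); p$bn_d2 <- d2$pb
  ca$d2 <- d2$cache
  d3 <- cbr_fwd(p$down3, p$bn_d3, d2$y, 2L, train); p$bn_d3 <- d3$pb
  ca$d3 <- d3$cache
  pr <- split_pair(d3$y, cfg$ffc)
  xl <- pr$local; xg <- pr$global
  ca$blocks <- vector("list", cfg$n_ffc_blocks)
  for (i in seq_len(cfg$n_ffc_blocks)) {
    bf <- ffc_block_fwd(p$blocks[[i]], cfg$ffc, xl, xg, train)
    p$blocks[[i]] <- bf$p
    ca$blocks[[i]] <- bf$cache
    xl <- bf$yl; xg <- bf$yg
  }
  tr <- merge_pair(xl, xg)
  u3 <- cbr_fwd(p$up3, p$bn_u3, tr, 2L, train, transpose = TRUE)
  p$bn_u3 <- u3$pb; ca$u3 <- u3$cache
  u2 <- cbr_fwd(p$up2, p$bn_u2, u3$y, 2L, train, transpose = TRUE)
  p$bn_u2 <- u2$pb; ca$u2 <- u2$cache
  u1 <- cbr_fwd(p$up1, p$bn_u1, u2$y, 2L, train, transpose = TRUE)
  p$bn_u1 <- u1$pb; ca$u1 <- u1$cache
  oc <- conv_fwd(p$out, u1$y, pad = 1L)
  sg <- sigmoid_fwd(oc$y)
  ca$out <- oc$cache
  ca$sg <- sg$cache
  list(y = sg$y, p = p, cache = ca)
}

gen_bwd <- function(p, cfg, cache, dy) {
  g <- list()
  d <- sigmoid_bwd(cache$sg, dy)
  ob <- conv_bwd(p$out, cache$out, d)
  g$out <- ob$g
  b <- cbr_bwd(p$up1, p$bn_u1, cache$u1, ob$dx, transpose = TRUE)
  g$up1 <- b$gc; g$bn_u1 <- b$gb
  b <- cbr_bwd(p$up2, p$bn_u2, cache$u2, b$dx, transpose = TRUE)
  g$up2 <- b$gc; g$bn_u2 <- b$gb
  b <- cbr_bwd(p$up3, p$bn_u3, cache$u3, b$dx, transpose = TRUE)
  g$up3 <- b$gc; g$bn_u3 <- b$gb
  cg <- cfg$ffc$c_global
  cl <- cfg$ffc$c_local
  dxl <- if (cl > 0L) b$dx[, , , seq_len(cl), drop = FALSE]
  dxg <- if (cg > 0L) b$dx[, , , cl + seq_len(cg), drop = FALSE]
  g$blocks <- vector("list", cfg$n_ffc_blocks)
  names(g$blocks) <- names(p$blocks)
  for (i in rev(seq_len(cfg$n_ffc_blocks))) {
    bb <- ffc_block_bwd(p$blocks[[i]], cfg$ffc, cache$blocks[[i]], dxl, dxg)
    g$blocks[[i]] <- bb$g
    dxl <- bb$dxl; dxg <- bb$dxg
  }
  dtr <- merge_pair(dxl, dxg)
  b <- cbr_bwd(p$down3, p$bn_d3, cache$d3, dtr)
  g$down3 <- b$gc; g$bn_d3 <- b$gb
  b <- cbr_bwd(p$down2, p$bn_d2, cache$d2, b$dx)
  g$down2 <- b$gc; g$bn_d2 <- b$gb
  b <- cbr_bwd(p$down1, p$bn_d1, cache$d1, b$dx)
  g$down1 <- b$gc; g$bn_d1 <- b$gb
  b <- cbr_bwd(p$stem, p$bn_stem, cache$stem, b$dx)
  g$stem <- b$gc; g$bn_stem <- b$gb
  list(dx = b$dx, g = g)
}

## Stack image and mask (and optional extra image) along channels (the
## last dim of the (H, W, N, C) layout, so concatenation is contiguous).
concat_channels <- function(...) {
  parts <- lapply(list(...), function(x) {
    d <- dim(x)
    if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
    else if (length(d) == 3L) dim(x) <- c(d[1], d[2], 1L, d[3])
    x
  })
  d <- dim(parts[[1]])
  ctot <- sum(vapply(parts, function(x) dim(x)[4], integer(1)))
  array(unlist(parts, use.names = FALSE), c(d[1], d[2], d[3], ctot))
}

#' Generator forward pass
#'
#' Runs the corrupted image (with the hole mask as a fourth channel) through
#' the inpainting generator. Fully convolutional: one weight set serves any
#' input whose sides are divisible by `2^3 = 8`.
#'
#' @param i_in corrupted image, `H x W x 3` (or `H x W x 3 x N`), values in
#'   \[0, 1\], holes zeroed.
#' @param m binary hole mask `H x W` (or `H x W x 1 x N`), 1 = missing.
#' @param weights from [generator_weights()].
#' @param config the matching [generator_config()].
#' @param train logical, batch-norm mode; evaluation mode is deterministic.
#' @return the inpainted image, same shape as `i_in`, values in (0, 1).
#' @export
generator_forward <- function(i_in, m, weights, config, train = FALSE) {
  had3 <- length(dim(i_in)) == 3L
  x <- as_ft(i_in)
  d <- dim(x)
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L)
    stop("generator_forward: image sides must be divisible by 8 (three ",
         "stride-2 stages); got ", d[1], " x ", d[2])
  inp <- if (config$input_includes_mask) concat_channels(x, m) else x
  drop_batch(gen_fwd(weights, config, inp, train = train)$y, had3)
}

#' Composite known pixels over the generator prediction
#'
#' Returns `i_in + i_inp * m`: pixels outside the hole are copied from the
#' (corrupted) input, hole pixels come from the prediction.
#'
#' @param i_inp generator output.
#' @param i_in corrupted input (holes zeroed).
#' @param m binary hole mask, 1 = missing.
#' @return composited image shaped like `i_inp`.
#' @export
composite_output <- function(i_inp, i_in, m) {
  if (!identical(dim(i_inp), dim(i_in)))
    stop("composite_output: image shape mismatch")
  mm <- broadcast_mask(m, dim(i_inp))
  i_in + i_inp * mm
}

## Expand an H x W (or H x W x N x 1) mask to image dims, replicating over
## channels (and batch if the mask is unbatched). `d` may describe an
## H x W x C single image or an H x W x N x C batch.
broadcast_mask <- function(m, d) {
  dm <- dim(m)
  if (length(dm) == 2L) dim(m) <- c(dm, 1L, 1L)
  else if (length(dm) == 3L) dim(m) <- c(dm[1], dm[2], 1L, dm[3])
  dm <- dim(m)
  if (dm[1] != d[1] || dm[2] != d[2])
    stop("mask spatial size ", dm[1], " x ", dm[2],
         " does not match image ", d[1], " x ", d[2])
  nb <- if (length(d) >= 4L) d[3] else 1L
  nch <- if (length(d) >= 4L) d[4] else if (length(d) == 3L) d[3] else 1L
  base <- if (dm[3] == nb) m[, , , 1L]
  else array(rep(m[, , 1L, 1L], nb), c(d[1], d[2], nb))
  out <- array(rep(base, nch), c(d[1], d[2], nb, nch))
  if (length(d) == 3L) dim(out) <- d
  else if (length(d) == 2L) dim(out) <- c(d, 1L, 1L)
  out
}

## ---- discriminator -------------------------------------------------------

#' Discriminator configuration
#'
#' A conditional patch discriminator: it consumes the channel concatenation
#' of the judged image and the corrupted input, applies `n_layers` stride-2
#' convolutions with LeakyReLU, and emits a spatial map of realism logits
#' plus the per-layer feature maps (used by the discriminator-feature loss).
#'
#' @param n_layers number of stride-2 convolution stages (>= 3).
#' @param base_channels width of the first stage, doubling thereafter
#'   (capped at `8 * base_channels`).
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(n_layers = 4L, base_channels = 64L) {
  stopifnot(n_layers >= 3L, base_channels >= 1L)
  structure(list(n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels)),
            class = "discriminator_config")
}

disc_channels <- function(cfg) {
  pmin(cfg$base_channels * 2L^(seq_len(cfg$n_layers) - 1L),
       cfg$base_channels * 8L)
}

disc_init <- function(cfg) {
  ch <- disc_channels(cfg)
  cin <- 6L
  p <- list()
  for (i in seq_len(cfg$n_layers)) {
    p[[paste0("c", i)]] <- conv_init(cin, ch[i], 4L)
    cin <- ch[i]
  }
  p$score <- conv_init(cin, 1L, 3L, gain = 1)
  p
}

#' Seeded discriminator weights
#'
#' @param config a [discriminator_config()].
#' @param seed integer seed.
#' @return weight tree for [discriminator_forward()].
#' @export
discriminator_weights <- function(config, seed = 1L) {
  stopifnot(inherits(config, "discriminator_config"))
  with_seed(seed, disc_init(config))
}

disc_fwd <- function(p, cfg, x) {
  ca <- list(conv = vector("list", cfg$n_layers),
             act = vector("list", cfg$n_layers))
  feats <- vector("list", cfg$n_layers)
  h <- x
  for (i in seq_len(cfg$n_layers)) {
    cv <- conv_fwd(p[[paste0("c", i)]], h, stride = 2L, pad = 1L)
    ac <- lrelu_fwd(cv$y)
    ca$conv[[i]] <- cv$cache
    ca$act[[i]] <- ac$cache
    feats[[i]] <- ac$y
    h <- ac$y
  }
  sc <- conv_fwd(p$score, h, pad = 1L)
  ca$score <- sc$cache
  list(scores = sc$y, features = feats, cache = ca)
}

## dscore: gradient on the logit map; dfeats: optional list of gradients on
## the per-layer features (NULL entries allowed).
disc_bwd <- function(p, cfg, cache, dscore, dfeats = NULL) {
  g <- list()
  sb <- conv_bwd(p$score, cache$score, dscore)
  g$score <- sb$g
  dh <- sb$dx
  for (i in rev(seq_len(cfg$n_layers))) {
    if (!is.null(dfeats) && !is.null(dfeats[[i]])) dh <- dh + dfeats[[i]]
    da <- lrelu_bwd(cache$act[[i]], dh)
    cb <- conv_bwd(p[[paste0("c", i)]], cache$conv[[i]], da)
    g[[paste0("c", i)]] <- cb$g
    dh <- cb$dx
  }
  list(dx = dh, g = g)
}

#' Conditional discriminator forward pass
#'
#' @param img image to judge (original or inpainted), `H x W x 3` (or 4-D).
#' @param i_in the corrupted input the generator saw (the conditioning).
#' @param weights from [discriminator_weights()].
#' @param config the matching [discriminator_config()].
#' @return list with `scores` (patch logit map, spatial size
#'   `input / 2^n_layers`) and `features` (one feature map per stage, spatial
#'   sizes non-increasing).
#' @export
discriminator_forward <- function(img, i_in, weights, config) {
  if (!identical(dim(img), dim(i_in)))
    stop("discriminator_forward: image / conditioning shape mismatch")
  had3 <- length(dim(img)) == 3L
  x <- concat_channels(as_ft(img), as_ft(i_in))
  r <- disc_fwd(weights, config, x)
  list(scores = drop_batch(r$scores, had3),
       features = lapply(r$features, drop_batch, had3))
}
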