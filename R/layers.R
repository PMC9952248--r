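## Neural-network layer primitives. Every primitive exposes an init
## (parameter creation, caller controls the RNG), a forward returning
## list(y, cache [, p]) and a backward returning list(dx, g) where g is a
## gradient tree matching the trainable leaves of the parameter tree.
## Batch-norm running statistics are buffers: the forward in training mode
## returns an updated parameter list; they carry no gradient.

## He-normal initialized convolution. Weights are stored flattened as a
## (cin*k*k) x cout matrix whose row order (channel fastest) matches the
## im2col column order.
conv_init <- function(cin, cout, k, gain = 2) {
  fan_in <- k * k * cin
  list(w = matrix(stats::rnorm(fan_in * cout, sd = sqrt(gain / fan_in)),
                  nrow = fan_in, ncol = cout),
       b = numeric(cout),
       k = k, cin = cin, cout = cout)
}

conv_fwd <- function(p, x, stride = 1L, pad = 0L, dilation = 1L) {
  d <- dim(x)
  if (d[4] != p$cin)
    stop("conv: expected ", p$cin, " input channels, got ", d[4])
  ic <- im2col(x, p$k, stride, pad, dilation)
  y <- ic$cols %*% p$w
  if (any(p$b != 0)) y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(ic$ho, ic$wo, d[3], p$cout)
  list(y = y,
       cache = list(cols = ic$cols, idx = ic$idx, nr = ic$nr, hp = ic$hp,
                    wp = ic$wp, d = d, stride = stride, pad = pad,
                    dilation = dilation))
}

conv_bwd <- function(p, cache, dy) {
  dym <- dy
  dim(dym) <- c(cache$nr, p$cout)
  dw <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, p$w)
  dx <- col2im(dcols, cache, cache$d[1], cache$d[2], cache$d[3], p$cin,
               p$k, cache$stride, cache$pad, cache$dilation)
  list(dx = dx, g = list(w = dw, b = db))
}

## Transposed convolution with stride s, realized as zero-interleaving
## (factor s) followed by a k=3, stride-1, pad-1 convolution; output is
## exactly s * input size.
convt_init <- function(cin, cout, gain = 2) conv_init(cin, cout, 3L, gain)

zstuff <- function(x, s) {
  d <- dim(x)
  out <- array(0, c(d[1] * s, d[2] * s, d[3], d[4]))
  out[seq(1L, by = s, length.out = d[1]),
      seq(1L, by = s, length.out = d[2]), , ] <- x
  out
}

convt_fwd <- function(p, x, s = 2L) {
  xs <- zstuff(x, s)
  out <- conv_fwd(p, xs, stride = 1L, pad = 1L)
  out$cache$s <- s
  out$cache$din <- dim(x)
  out
}

convt_bwd <- function(p, cache, dy) {
  b <- conv_bwd(p, cache, dy)
  s <- cache$s
  din <- cache$din
  b$dx <- b$dx[seq(1L, by = s, length.out = din[1]),
               seq(1L, by = s, length.out = din[2]), , , drop = FALSE]
  list(dx = b$dx, g = b$g)
}

## ---- batch normalization ----------------------------------------------

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       rm = rep(0, c), rv = rep(1, c))
}

## Per-channel normalization over (H, W, N). In training mode batch
## statistics are used and the running buffers updated; in evaluation mode
## the running buffers are used, which makes inference deterministic.
bn_fwd <- function(p, x, train, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  m <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    va <- colMeans(xc * xc)
    p$rm <- (1 - momentum) * p$rm + momentum * mu
    p$rv <- (1 - momentum) * p$rv + momentum * va
  } else {
    mu <- p$rm
    va <- p$rv
    xc <- xm - rep(mu, each = m)
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(invstd, each = m)
  y <- xhat * rep(p$gamma, each = m) + rep(p$beta, each = m)
  dim(y) <- d
  list(y = y, p = p,
       cache = list(xhat = xhat, invstd = invstd, d = d, train = train))
}

bn_bwd <- function(p, cache, dy) {
  d <- cache$d
  dym <- dy
  dim(dym) <- c(d[1] * d[2] * d[3], d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$train) {
    m <- nrow(dym)
    t1 <- sweep(dym, 2L, dbeta / m)
    t2 <- sweep(cache$xhat, 2L, dgamma / m, `*`)
    dx <- sweep(t1 - t2, 2L, p$gamma * cache$invstd, `*`)
  } else {
    dx <- sweep(dym, 2L, p$gamma * cache$invstd, `*`)
  }
  dim(dx) <- d
  list(dx = dx, g = list(gamma = dgamma, beta = dbeta))
}

## ---- pointwise activations --------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dy) dy * cache

lrelu_fwd <- function(x, slope = 0.2) {
  f <- (x > 0) * (1 - slope) + slope
  list(y = x * f, cache = f)
}
lrelu_bwd <- function(cache, dy) dy * cache

sigmoid_fwd <- function(x) {
  y <- stats::plogis(x)
  list(y = y, cache = y)
}
sigmoid_bwd <- function(cache, dy) dy * cache * (1 - cache)

## ---- dense (used inside the SE bottleneck) -----------------------------

dense_init <- function(cin, cout, gain = 2) {
  list(w = matrix(stats::rnorm(cin * cout, sd = sqrt(gain / cin)),
                  nrow = cin, ncol = cout),
       b = numeric(cout))
}

dense_fwd <- function(p, x) {
  list(y = x %*% p$w + rep(p$b, each = nrow(x)), cache = x)
}

dense_bwd <- function(p, cache, dy) {
  list(dx = tcrossprod(dy, p$w),
       g = list(w = crossprod(cache, dy), b = colSums(dy)))
}

## ---- squeeze-and-excitation channel attention ---------------------------

#' @keywords internal
se_bottleneck_width <- function(c, reduction) max(1L, as.integer(ceiling(c / reduction)))

se_init <- function(c, reduction = 16L) {
  cr <- se_bottleneck_width(c, reduction)
  list(fc1 = dense_init(c, cr), fc2 = dense_init(cr, c, gain = 1))
}

## squeeze: global spatial mean per channel; excitation: C -> C/r -> C with
## ReLU then sigmoid; reweight: broadcast channel-wise multiplication.
se_fwd <- function(p, x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  ## (H*W) x (N*C) column means give the squeeze vector, N x C
  z <- matrix(colMeans(matrix(x, nrow = hw)), nrow = d[3])
  f1 <- dense_fwd(p$fc1, z)
  r1 <- relu_fwd(f1$y)
  f2 <- dense_fwd(p$fc2, r1$y)
  s2 <- sigmoid_fwd(f2$y)                               # N x C in (0,1)
  sf <- array(rep(as.vector(s2$y), each = hw), d)
  list(y = x * sf,
       cache = list(x = x, sf = sf, z = z, f1 = f1$cache, r1 = r1$cache,
                    f2 = f2$cache, s2 = s2$cache, d = d),
       weights = s2$y)
}

se_bwd <- function(p, cache, dy) {
  d <- cache$d
  hw <- d[1] * d[2]
  dx <- dy * cache$sf
  ds <- matrix(colSums(matrix(dy * cache$x, nrow = hw)), nrow = d[3])
  df2 <- sigmoid_bwd(cache$s2, ds)
  b2 <- dense_bwd(p$fc2, cache$f2, df2)
  dr1 <- relu_bwd(cache$r1, b2$dx)
  b1 <- dense_bwd(p$fc1, cache$f1, dr1)
  dz <- b1$dx
  dx <- dx + array(rep(as.vector(dz), each = hw), d) / hw
  list(dx = dx, g = list(fc1 = b1$g, fc2 = b2$g))
}

## ---- Adam -------------------------------------------------------------

adam_state <- function() list(t = 0L, m = NULL, v = NULL)

## One Adam update over a parameter tree; only leaves present in the
## gradient tree are touched (buffers such as BN running stats are not).
adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (is.null(state$m)) {
    state$m <- tree_map2(function(a, b) b * 0, params, grads)
    state$v <- tree_map2(function(a, b) b * 0, params, grads)
  }
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- function(pp, gg, mm, vv) {
    if (is.list(gg)) {
      for (nm in names(gg)) {
        r <- upd(pp[[nm]], gg[[nm]], mm[[nm]], vv[[nm]])
        pp[[nm]] <- r$p; mm[[nm]] <- r$m; vv[[nm]] <- r$v
      }
      return(list(p = pp, m = mm, v = vv))
    }
    mm <- beta1 * mm + (1 - beta1) * gg
    vv <- beta2 * vv + (1 - beta2) * gg * gg
    pp <- pp - lr * (mm / bc1) / (sqrt(vv / bc2) + eps)
    list(p = pp, m = mm, v = vv)
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

## Euclidean norm over all leaves of a gradient tree.
grad_norm <- function(g) sqrt(tree_sum(function(x) sum(x * x), g))
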