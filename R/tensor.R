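## Low-level tensor machinery for the network engine.
##
## Feature tensors are dense double arrays with dim c(H, W, N, C):
## spatial rows, spatial columns, batch, channels. Channels-last makes a
## single image's H x W x C array bit-compatible with the batched layout
## (N = 1 is a plain reshape) and lets convolution and batch-norm reshape
## with `dim<-` instead of aperm. Convolutions are evaluated as one BLAS
## matrix product after an im2col gather; the gather indices are cached per
## shape signature because they are pure integer arithmetic.

.idx_cache <- new.env(parent = emptyenv())

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

ft_check <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 4L)
  invisible(x)
}

## Zero-pad the two spatial dims symmetrically.
pad4 <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

unpad4 <- function(x, pad, h, w) {
  if (pad == 0L) return(x)
  x[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
}

conv_out_size <- function(hw, k, stride, pad, dilation) {
  span <- (k - 1L) * dilation + 1L
  (hw + 2L * pad - span) %/% stride + 1L
}

## Gather indices for im2col: rows ordered (i_out, j_out, n), columns
## ordered (c, ky, kx) — channel fastest, so the scatter-add in col2im
## works on contiguous column blocks, one per kernel offset.
im2col_index <- function(h, w, n, cin, k, stride, pad, dilation) {
  key <- paste(h, w, n, cin, k, stride, pad, dilation, sep = ".")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  ho <- conv_out_size(h, k, stride, pad, dilation)
  wo <- conv_out_size(w, k, stride, pad, dilation)
  io <- rep.int(seq_len(ho), wo * n)
  jo <- rep.int(rep(seq_len(wo), each = ho), n)
  nn <- rep(seq_len(n), each = ho * wo)
  rowbase <- as.integer((io - 1L) * stride + 1L +
                          (jo - 1L) * stride * hp +
                          (nn - 1L) * hp * wp)
  cc <- rep.int(seq_len(cin), k * k)
  ky <- rep.int(rep(seq_len(k), each = cin), k)
  kx <- rep(seq_len(k), each = cin * k)
  off <- as.integer((cc - 1L) * hp * wp * n +
                      (ky - 1L) * dilation + (kx - 1L) * dilation * hp)
  idx <- as.integer(outer(rowbase, off, "+"))
  out <- list(idx = idx, ho = ho, wo = wo, nr = length(rowbase),
              nc = length(off))
  .idx_cache[[key]] <- out
  out
}

## x: (H, W, N, Cin) -> cols matrix (N*Ho*Wo) x (Cin*k*k)
im2col <- function(x, k, stride, pad, dilation) {
  d <- dim(x)
  gi <- im2col_index(d[1], d[2], d[3], d[4], k, stride, pad, dilation)
  xp <- pad4(x, pad)
  cols <- cpp_gather(xp, gi$idx)
  dim(cols) <- c(gi$nr, gi$nc)
  list(cols = cols, ho = gi$ho, wo = gi$wo, idx = gi$idx,
       nr = gi$nr, hp = d[1] + 2L * pad, wp = d[2] + 2L * pad)
}

## Scatter-add adjoint of im2col. dcols: (N*Ho*Wo) x (Cin*k*k).
col2im <- function(dcols, meta, h, w, n, cin, k, stride, pad, dilation) {
  dxp <- cpp_col2im(dcols, meta$idx, meta$hp * meta$wp * n * cin)
  dim(dxp) <- c(meta$hp, meta$wp, n, cin)
  unpad4(dxp, pad, h, w)
}

## ---- batched 2-D FFT --------------------------------------------------

## Full complex 2-D FFT over the spatial dims, all channels and batch
## members at once (two mvfft passes; unnormalized, matching stats::fft).
fft2_batch <- function(x, inverse = FALSE) {
  d <- dim(x)
  m <- stats::mvfft(matrix(x, nrow = d[1]), inverse = inverse)
  x2 <- aperm(array(m, d), c(2L, 1L, 3L, 4L))
  m2 <- stats::mvfft(matrix(x2, nrow = d[2]), inverse = inverse)
  aperm(array(m2, d[c(2L, 1L, 3L, 4L)]), c(2L, 1L, 3L, 4L))
}

## One-sided real 2-D FFT: keeps the first floor(W/2)+1 frequency columns.
rfft2_batch <- function(x) {
  d <- dim(x)
  wh <- d[2] %/% 2L + 1L
  fft2_batch(x)[, seq_len(wh), , , drop = FALSE]
}

## Inverse of rfft2_batch: rebuild the full spectrum by Hermitian symmetry
## along both spatial axes, then inverse transform; the real part is exact
## for spectra arising from real inputs and defines a linear map otherwise.
irfft2_batch <- function(y, w) {
  d <- dim(y)
  h <- d[1]; wh <- d[2]
  z <- array(0i, c(h, w, d[3], d[4]))
  z[, seq_len(wh), , ] <- y
  if (w > wh) {
    jdst <- (wh + 1L):w
    jsrc <- w + 2L - jdst
    rmir <- c(1L, if (h > 1L) h:2L)
    z[, jdst, , ] <- Conj(y[rmir, jsrc, , , drop = FALSE])
  }
  Re(fft2_batch(z, inverse = TRUE)) / (h * w)
}

## Adjoint of rfft2_batch as a map real(H,W) -> (Re, Im) of the kept bins.
## The DFT matrix is symmetric, so the adjoint is Re(F %*% conj(grad))
## with the dropped columns zero-padded.
rfft2_adjoint <- function(d_re, d_im, w) {
  d <- dim(d_re)
  g <- array(0i, c(d[1], w, d[3], d[4]))
  g[, seq_len(d[2]), , ] <- d_re - 1i * d_im
  Re(fft2_batch(g))
}

## Adjoint of irfft2_batch as a map complex(H,Wh) -> real(H,W): returns the
## (Re, Im) gradients of the kept bins.
irfft2_adjoint <- function(dx, wh) {
  d <- dim(dx)
  h <- d[1]; w <- d[2]
  dz <- fft2_batch(dx) / (h * w)
  dy <- dz[, seq_len(wh), , , drop = FALSE]
  if (w > wh) {
    jdst <- (wh + 1L):w
    jsrc <- w + 2L - jdst
    rmir <- c(1L, if (h > 1L) h:2L)
    dy[rmir, jsrc, , ] <- dy[rmir, jsrc, , , drop = FALSE] +
      Conj(dz[, jdst, , , drop = FALSE])
  }
  list(d_re = Re(dy), d_im = Im(dy))
}

## Recursive map over matching (parameter, gradient) trees.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in names(b)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

## Sum of a function applied to every leaf of a tree.
tree_sum <- function(f, tr) {
  if (is.list(tr)) sum(vapply(tr, function(e) tree_sum(f, e), numeric(1)))
  else f(tr)
}

## Elementwise addition of two grad trees with identical structure.
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(`+`, a, b)
}

## Total number of scalar parameters in a tree.
tree_count <- function(tr) tree_sum(length, tr)
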