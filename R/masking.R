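## Irregular free-form mask generation (seeded random-walk brush strokes)
## and the symbol-aware training-mask composition: training masks are
## sampled anywhere in the frame and the symbol (prior) region is subtracted,
## so the network is never asked to reconstruct pixels whose true background
## is unknown.

#' Brush-stroke parameters for irregular mask generation
#'
#' Defaults are stated at a 256 x 256 frame and scale linearly with the
#' frame side.
#'
#' @param n_strokes integer range `c(lo, hi)` of stroke count.
#' @param vertices_per_stroke integer range of chained segments per stroke.
#' @param stroke_length pixel range of each segment length.
#' @param thickness pixel range of the stroke thickness (sampled once per
#'   stroke).
#' @param angle_jitter maximal per-vertex heading change in radians.
#' @param max_mask_fraction cap on the masked area fraction; strokes that
#'   would exceed it are rejected.
#' @return a validated `brush_params` list.
#' @export
brush_params <- function(n_strokes = c(1L, 4L),
                         vertices_per_stroke = c(4L, 12L),
                         stroke_length = c(16L, 60L),
                         thickness = c(8L, 24L),
                         angle_jitter = pi / 4,
                         max_mask_fraction = 0.35) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  stopifnot(rng_ok(n_strokes), n_strokes[1] >= 0,
            rng_ok(vertices_per_stroke), vertices_per_stroke[1] >= 1,
            rng_ok(stroke_length), stroke_length[1] >= 1,
            rng_ok(thickness), thickness[1] >= 1,
            angle_jitter >= 0,
            max_mask_fraction > 0, max_mask_fraction < 1)
  structure(list(n_strokes = as.integer(n_strokes),
                 vertices_per_stroke = as.integer(vertices_per_stroke),
                 stroke_length = as.integer(stroke_length),
                 thickness = as.integer(thickness),
                 angle_jitter = angle_jitter,
                 max_mask_fraction = max_mask_fraction),
            class = "brush_params")
}

## Rescale the pixel-unit brush defaults from their 256-px reference frame.
scale_brush_params <- function(params, side) {
  f <- side / 256
  params$stroke_length <- pmax(1L, as.integer(round(params$stroke_length * f)))
  params$thickness <- pmax(1L, as.integer(round(params$thickness * f)))
  params
}

## Integer pixels of the line segment from (i0, j0) to (i1, j1)
## (Bresenham; max(|di|, |dj|) + 1 pixels).
bresenham_pixels <- function(i0, j0, i1, j1) {
  di <- i1 - i0
  dj <- j1 - j0
  n <- max(abs(di), abs(dj))
  if (n == 0L) return(cbind(i0, j0))
  t <- seq(0L, n) / n
  cbind(round(i0 + t * di), round(j0 + t * dj))
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else
  sample(seq(r[1], r[2]), 1L)

#' Generate a seeded irregular free-form mask
#'
#' Random-walk brush strokes: each stroke starts at a uniform point and
#' chains segments whose headings drift by at most `angle_jitter`; each
#' stroke is rasterized at a sampled thickness. A stroke is rejected if it
#' would push the masked fraction past `max_mask_fraction`.
#'
#' @param h,w mask size in pixels (>= 8).
#' @param params a [brush_params()]; pixel ranges are taken as given (the
#'   training pipeline rescales its defaults from their 256-px reference to
#'   the frame side before calling this).
#' @param seed integer seed; same inputs + seed give an identical mask.
#' @return an `h x w` matrix in `{0, 1}`, 1 = missing pixel.
#' @export
generate_irregular_mask <- function(h, w, params = brush_params(),
                                    seed = 1L) {
  stopifnot(inherits(params, "brush_params"), h >= 8, w >= 8)
  cap <- params$max_mask_fraction * h * w
  with_seed(seed, {
    m <- matrix(FALSE, h, w)
    ns <- sample_range(params$n_strokes)
    for (s in seq_len(ns)) {
      nv <- sample_range(params$vertices_per_stroke)
      th <- sample_range(params$thickness)
      i <- stats::runif(1, 1, h)
      j <- stats::runif(1, 1, w)
      ang <- stats::runif(1, 0, 2 * pi)
      stroke <- matrix(FALSE, h, w)
      for (v in seq_len(nv)) {
        len <- sample_range(params$stroke_length)
        ang <- ang + stats::runif(1, -params$angle_jitter,
                                  params$angle_jitter)
        i1 <- min(max(i + len * sin(ang), 1), h)
        j1 <- min(max(j + len * cos(ang), 1), w)
        px <- bresenham_pixels(round(i), round(j), round(i1), round(j1))
        stroke <- stroke | stamp_points(h, w, px, th)
        i <- i1; j <- j1
      }
      if (sum(m | stroke) <= cap) m <- m | stroke
    }
    out <- matrix(0, h, w)
    out[m] <- 1
    out
  })
}

#' Compose the training mask from a generated and a prior mask
#'
#' Clamped set difference `m = max(m_gen - m_prior, 0)`: a pixel is a
#' training hole iff the brush generator marked it and it is not an
#' annotation-symbol pixel. Guarantees `m * m_prior == 0` everywhere, so no
#' training hole ever asks the model to reconstruct a pixel without ground
#' truth.
#'
#' @param m_gen generated irregular mask (`{0,1}` matrix).
#' @param m_prior symbol prior mask of the same shape.
#' @return binary mask of the same shape.
#' @export
compose_training_mask <- function(m_gen, m_prior) {
  if (!identical(dim(m_gen), dim(m_prior)))
    stop("compose_training_mask: shape mismatch")
  m_gen * (1 - m_prior)
}

#' Corrupt an image by zeroing the hole pixels
#'
#' `I_in = I_ori * (1 - m)` on every channel.
#'
#' @param i_ori image (`H x W x C` or with batch dim, or plain matrix).
#' @param m binary mask, 1 = missing pixel.
#' @return image of the same shape with holes zeroed.
#' @export
corrupt <- function(i_ori, m) {
  if (!all(m %in% c(0, 1))) stop("corrupt: mask must be binary")
  d <- dim(i_ori)
  if (is.null(d)) stop("corrupt: image must be an array")
  if (length(d) == 2L) {
    if (!identical(d, dim(m))) stop("corrupt: shape mismatch")
    return(i_ori * (1 - m))
  }
  keep <- 1 - broadcast_mask(m, d)
  if (length(d) == 3L) dim(keep) <- d
  i_ori * keep
}

## ---- mask serialization -----------------------------------------------

#' Write a binary mask as a single-channel 0/255 PNG
#'
#' @param m binary mask matrix.
#' @param path output file.
#' @export
write_mask <- function(m, path) {
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask from a PNG (values > 127 map to 1)
#'
#' @param path PNG file; multi-channel files are reduced by their first
#'   channel.
#' @return `{0,1}` matrix.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x > 127 / 255) * 1
}
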