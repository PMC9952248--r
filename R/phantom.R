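## Synthetic ultrasound phantoms: a speckled gray tissue background with a
## darker elliptical lesion, plus overlaid clinician-style annotation
## symbols (a yellow dashed outline tracing the lesion boundary, caliper
## crosses at boundary points, letter/digit glyphs near the corners) and the
## exact binary mask of every drawn pixel. The triplets stand in for a real
## annotated ultrasound dataset: the "prior mask" marks pixels whose true
## background is unknown.

#' Phantom specification
#'
#' @param height,width frame size in pixels; at least 64 and divisible by 8
#'   (the generator has three stride-2 stages).
#' @param lesion_center `(row, col)` center as fractions of the frame.
#' @param lesion_axes `(a, b)` semi-axes as fractions of frame height and
#'   width; the ellipse must lie fully inside the frame.
#' @param speckle_strength multiplicative speckle contrast (standard
#'   deviation of the relative intensity fluctuation). Clinical B-mode
#'   exports are scan-converter smoothed, so the default is well below raw
#'   fully-developed speckle.
#' @param background_level,lesion_level tissue and lesion gray levels in
#'   \[0, 1\]; the lesion (e.g. an anechoic cyst) is darker.
#' @param seed integer seed controlling the speckle field.
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         lesion_center = c(0.5, 0.5),
                         lesion_axes = c(0.22, 0.28),
                         speckle_strength = 0.08,
                         background_level = 0.6,
                         lesion_level = 0.15,
                         seed = 1L) {
  fail <- function(field, why) stop("phantom_spec: invalid `", field, "`: ",
                                    why, call. = FALSE)
  if (height < 64 || height %% 8 != 0)
    fail("height", "must be >= 64 and divisible by 8")
  if (width < 64 || width %% 8 != 0)
    fail("width", "must be >= 64 and divisible by 8")
  if (length(lesion_center) != 2 || any(lesion_center <= 0) ||
      any(lesion_center >= 1))
    fail("lesion_center", "must be two fractions in (0, 1)")
  if (length(lesion_axes) != 2 || any(lesion_axes <= 0))
    fail("lesion_axes", "must be two positive fractions")
  if (lesion_center[1] - lesion_axes[1] <= 0 ||
      lesion_center[1] + lesion_axes[1] >= 1 ||
      lesion_center[2] - lesion_axes[2] <= 0 ||
      lesion_center[2] + lesion_axes[2] >= 1)
    fail("lesion_axes", "lesion ellipse must lie fully inside the frame")
  if (speckle_strength < 0) fail("speckle_strength", "must be >= 0")
  if (background_level > 1) fail("background_level", "must be <= 1")
  if (lesion_level < 0) fail("lesion_level", "must be >= 0")
  if (lesion_level >= background_level)
    fail("lesion_level", "must be strictly below background_level")
  structure(list(height = as.integer(height), width = as.integer(width),
                 lesion_center = lesion_center, lesion_axes = lesion_axes,
                 speckle_strength = speckle_strength,
                 background_level = background_level,
                 lesion_level = lesion_level, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Normalized elliptical radius of every pixel: < 1 inside the lesion.
ellipse_radius <- function(spec) {
  h <- spec$height; w <- spec$width
  cy <- spec$lesion_center[1] * h
  cx <- spec$lesion_center[2] * w
  ay <- spec$lesion_axes[1] * h
  bx <- spec$lesion_axes[2] * w
  ry <- (seq_len(h) - cy) / ay
  rx <- (seq_len(w) - cx) / bx
  sqrt(outer(ry^2, rx^2, `+`))
}

## Boundary ramp width in normalized radius units (about a 2-pixel band).
ellipse_band_width <- function(spec) {
  2 / min(spec$lesion_axes[1] * spec$height, spec$lesion_axes[2] * spec$width)
}

#' Synthesize a clean ultrasound phantom
#'
#' Smooth background at `background_level`, an elliptical lesion at
#' `lesion_level` with a linear ~2-pixel boundary ramp, multiplied by a
#' seeded multiplicative speckle field `1 + speckle_strength * g` (g
#' standard normal) and clipped to \[0, 1\]. All three channels are equal.
#'
#' @param spec a [phantom_spec()].
#' @return `H x W x 3` image array with the spec attached as attribute
#'   `phantom_spec`.
#' @export
synth_clean_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- ellipse_radius(spec)
  wb <- ellipse_band_width(spec)
  ramp <- pmin(pmax((r - 1) / wb, 0), 1)
  gray <- spec$lesion_level +
    (spec$background_level - spec$lesion_level) * ramp
  if (spec$speckle_strength > 0) {
    g <- with_seed(spec$seed,
                   matrix(stats::rnorm(spec$height * spec$width),
                          spec$height, spec$width))
    gray <- gray * (1 + spec$speckle_strength * g)
  }
  gray <- pmin(pmax(gray, 0), 1)
  img <- array(gray, c(spec$height, spec$width, 3L))
  attr(img, "phantom_spec") <- spec
  img
}

## ---- symbol overlay -------------------------------------------------------

#' Annotation-symbol specification
#'
#' @param draw_outline draw a dashed ellipse tracing the lesion boundary.
#' @param n_crosses number of caliper crosses placed at random boundary
#'   points.
#' @param cross_arm half-length of each cross arm in pixels.
#' @param n_glyphs number of letter/digit glyphs (5x7 bitmap font, scaled)
#'   placed near the frame corners.
#' @param symbol_color RGB triple in \[0, 1\] (default annotation yellow).
#' @param line_thickness stroke thickness in pixels (>= 1).
#' @param dilation pixels added around every drawn stroke when forming the
#'   prior mask (a safety margin covering the full stroke support).
#' @return a validated `symbol_spec` list.
#' @export
symbol_spec <- function(draw_outline = TRUE, n_crosses = 2L, cross_arm = 6L,
                        n_glyphs = 2L, symbol_color = c(1, 1, 0),
                        line_thickness = 1L, dilation = 1L) {
  stopifnot(n_crosses >= 0, n_glyphs >= 0, cross_arm >= 1,
            line_thickness >= 1, dilation >= 0,
            length(symbol_color) == 3, all(symbol_color >= 0),
            all(symbol_color <= 1))
  structure(list(draw_outline = isTRUE(draw_outline),
                 n_crosses = as.integer(n_crosses),
                 cross_arm = as.integer(cross_arm),
                 n_glyphs = as.integer(n_glyphs),
                 symbol_color = symbol_color,
                 line_thickness = as.integer(line_thickness),
                 dilation = as.integer(dilation)),
            class = "symbol_spec")
}

## 5x7 bitmap glyphs ('#' = on). Deterministic across platforms: no font
## files involved.
.glyph_font <- local({
  def <- c(
    "0" = "#####|#...#|#...#|#...#|#...#|#...#|#####",
    "1" = "..#..|.##..|..#..|..#..|..#..|..#..|.###.",
    "2" = "#####|....#|....#|#####|#....|#....|#####",
    "3" = "#####|....#|....#|.####|....#|....#|#####",
    "4" = "#...#|#...#|#...#|#####|....#|....#|....#",
    "5" = "#####|#....|#....|#####|....#|....#|#####",
    "6" = "#####|#....|#....|#####|#...#|#...#|#####",
    "7" = "#####|....#|...#.|..#..|..#..|..#..|..#..",
    "8" = "#####|#...#|#...#|#####|#...#|#...#|#####",
    "9" = "#####|#...#|#...#|#####|....#|....#|#####",
    "L" = "#....|#....|#....|#....|#....|#....|#####",
    "R" = "####.|#...#|#...#|####.|#.#..|#..#.|#...#",
    "A" = ".###.|#...#|#...#|#####|#...#|#...#|#...#",
    "B" = "####.|#...#|#...#|####.|#...#|#...#|####.",
    "C" = ".####|#....|#....|#....|#....|#....|.####",
    "D" = "####.|#...#|#...#|#...#|#...#|#...#|####.",
    "X" = "#...#|#...#|.#.#.|..#..|.#.#.|#...#|#...#",
    "+" = ".....|..#..|..#..|#####|..#..|..#..|....."
  )
  lapply(def, function(s) {
    rows <- strsplit(s, "|", fixed = TRUE)[[1]]
    do.call(rbind, lapply(rows, function(r)
      strsplit(r, "")[[1]] == "#"))
  })
})

## Chebyshev (square) binary dilation by radius r.
dilate_mask <- function(m, r) {
  if (r == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    ys <- pmin(pmax(seq_len(h) + dy, 1L), h)
    xs <- pmin(pmax(seq_len(w) + dx, 1L), w)
    out <- out | m[ys, xs]
  }
  out
}

## Stamp a set of (row, col) pixels with a square pen of the given
## thickness; returns a logical H x W mask. Thickness 1 stamps the pixels
## themselves.
stamp_points <- function(h, w, ij, thickness = 1L) {
  m <- matrix(FALSE, h, w)
  if (nrow(ij) == 0L) return(m)
  r <- (thickness - 1L) %/% 2L
  r2 <- thickness - 1L - r
  for (dy in (-r):r2) for (dx in (-r):r2) {
    yy <- ij[, 1] + dy
    xx <- ij[, 2] + dx
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    m[cbind(yy[ok], xx[ok])] <- TRUE
  }
  m
}

## Pixels of a dashed ellipse along the lesion boundary (6 px on / 4 px off
## by arc length).
dashed_ellipse_pixels <- function(spec) {
  h <- spec$height; w <- spec$width
  cy <- spec$lesion_center[1] * h
  cx <- spec$lesion_center[2] * w
  ay <- spec$lesion_axes[1] * h
  bx <- spec$lesion_axes[2] * w
  nsamp <- max(512L, as.integer(8 * pi * max(ay, bx)))
  th <- seq(0, 2 * pi, length.out = nsamp + 1L)[-(nsamp + 1L)]
  py <- cy + ay * sin(th)
  px <- cx + bx * cos(th)
  seg <- sqrt(diff(c(py, py[1]))^2 + diff(c(px, px[1]))^2)
  arc <- cumsum(c(0, seg[-nsamp]))
  on <- (arc %% 10) < 6
  ij <- unique(cbind(round(py[on]), round(px[on])))
  ij[ij[, 1] >= 1 & ij[, 1] <= h & ij[, 2] >= 1 & ij[, 2] <= w, ,
     drop = FALSE]
}

## Pixels of a caliper cross: horizontal and vertical arms of half-length
## `arm` sharing their center.
cross_pixels <- function(center, arm) {
  i <- center[1]; j <- center[2]
  rbind(cbind(i, (j - arm):(j + arm)),
        cbind(setdiff((i - arm):(i + arm), i), j))
}

## Pixels of a glyph bitmap scaled by an integer factor, top-left at (i, j).
glyph_pixels <- function(ch, i, j, scale = 2L) {
  bm <- .glyph_font[[ch]]
  on <- which(bm, arr.ind = TRUE)
  out <- vector("list", nrow(on))
  for (k in seq_len(nrow(on))) {
    ys <- i + (on[k, 1] - 1L) * scale + seq_len(scale) - 1L
    xs <- j + (on[k, 2] - 1L) * scale + seq_len(scale) - 1L
    out[[k]] <- as.matrix(expand.grid(ys, xs))
  }
  do.call(rbind, out)
}

#' Overlay annotation symbols on a clean phantom
#'
#' Draws (in this order) a dashed ellipse on the lesion boundary, caliper
#' crosses at seeded random boundary points, and glyphs near the frame
#' corners, all in `symbol_color`. The prior mask is the union of every
#' drawn pixel, dilated by `sym$dilation`.
#'
#' @param clean clean image from [synth_clean_phantom()] (the attached
#'   `phantom_spec` attribute supplies the lesion geometry; a `spec`
#'   argument overrides it).
#' @param sym a [symbol_spec()].
#' @param seed integer seed for symbol placement.
#' @param spec optional [phantom_spec()] if `clean` carries no attribute.
#' @return a `phantom_triplet`: list with `clean`, `original`, `prior_mask`
#'   (0/1 matrix) and `mask_fraction` (exact mean of the prior mask).
#' @export
overlay_symbols <- function(clean, sym, seed = 1L, spec = NULL) {
  stopifnot(inherits(sym, "symbol_spec"))
  if (is.null(spec)) spec <- attr(clean, "phantom_spec")
  if (is.null(spec))
    stop("overlay_symbols: no phantom_spec available for lesion geometry")
  if (min(clean) < 0 || max(clean) > 1)
    stop("overlay_symbols: clean image must lie in [0, 1]")
  h <- spec$height; w <- spec$width
  drawn <- matrix(FALSE, h, w)
  with_seed(seed, {
    if (sym$draw_outline) {
      ij <- dashed_ellipse_pixels(spec)
      drawn <- drawn | stamp_points(h, w, ij, sym$line_thickness)
    }
    if (sym$n_crosses > 0L) {
      cy <- spec$lesion_center[1] * h
      cx <- spec$lesion_center[2] * w
      ay <- spec$lesion_axes[1] * h
      bx <- spec$lesion_axes[2] * w
      th <- stats::runif(sym$n_crosses, 0, 2 * pi)
      for (t in th) {
        ci <- round(cy + ay * sin(t))
        cj <- round(cx + bx * cos(t))
        if (ci - sym$cross_arm < 1 || ci + sym$cross_arm > h ||
            cj - sym$cross_arm < 1 || cj + sym$cross_arm > w)
          stop("overlay_symbols: cross at boundary point (", ci, ", ", cj,
               ") does not fit in the frame")
        drawn <- drawn |
          stamp_points(h, w, cross_pixels(c(ci, cj), sym$cross_arm),
                       sym$line_thickness)
      }
    }
    if (sym$n_glyphs > 0L) {
      scale <- 2L
      gh <- 7L * scale; gw <- 5L * scale
      margin <- 4L
      corners <- list(c(margin, margin),
                      c(margin, w - gw - margin),
                      c(h - gh - margin, margin),
                      c(h - gh - margin, w - gw - margin))
      if (any(vapply(corners, function(cc) cc[1] < 1 || cc[2] < 1,
                     logical(1))))
        stop("overlay_symbols: frame too small to place glyphs")
      chars <- sample(names(.glyph_font), sym$n_glyphs, replace = TRUE)
      for (k in seq_len(sym$n_glyphs)) {
        cc <- corners[[(k - 1L) %% 4L + 1L]]
        jit <- sample(0:2, 2, replace = TRUE) * (1 + (k - 1L) %/% 4L)
        i0 <- min(cc[1] + jit[1], h - gh)
        j0 <- min(cc[2] + jit[2], w - gw)
        drawn <- drawn |
          stamp_points(h, w, glyph_pixels(chars[k], i0, j0, scale), 1L)
      }
    }
  })
  original <- clean
  attr(original, "phantom_spec") <- NULL
  cl <- clean
  attr(cl, "phantom_spec") <- NULL
  if (any(drawn)) {
    idx <- which(drawn)
    hw <- h * w
    for (ch in 1:3) original[idx + (ch - 1L) * hw] <- sym$symbol_color[ch]
  }
  prior <- dilate_mask(drawn, sym$dilation)
  prior_mask <- matrix(0, h, w)
  prior_mask[prior] <- 1
  structure(list(clean = cl, original = original, prior_mask = prior_mask,
                 mask_fraction = mean(prior_mask)),
            class = "phantom_triplet")
}

#' Generate a full phantom triplet in one call
#'
#' @param spec a [phantom_spec()].
#' @param sym a [symbol_spec()].
#' @param seed seed for symbol placement (the speckle seed lives in `spec`).
#' @return a `phantom_triplet` (see [overlay_symbols()]).
#' @export
phantom_triplet <- function(spec = phantom_spec(), sym = symbol_spec(),
                            seed = 1L) {
  overlay_symbols(synth_clean_phantom(spec), sym, seed = seed, spec = spec)
}

## Seeded randomized phantom parameters for fixture i of a run.
random_phantom_spec <- function(size, seed) {
  with_seed(seed, {
    ctr <- stats::runif(2, 0.42, 0.58)
    ax <- stats::runif(2, 0.16, 0.3)
    phantom_spec(height = size, width = size,
                 lesion_center = ctr, lesion_axes = ax,
                 seed = seed)
  })
}

#' Write a directory of phantom fixtures
#'
#' Writes `clean/NNN.png`, `orig/NNN.png` and `prior/NNN.png` (8-bit PNG;
#' masks 0/255) plus a `manifest.tsv` with the per-image seeds and lesion
#' parameters. Same `(n, size, seed)` reproduces the files bit-exactly.
#'
#' @param n number of triplets.
#' @param size frame side (e.g. 64, 256, 512; divisible by 8).
#' @param seed master seed; image i uses `seed + i`.
#' @param out_dir output directory (created if needed).
#' @param sym a [symbol_spec()] shared by all images.
#' @return the manifest as a data.frame, invisibly.
#' @export
make_fixtures <- function(n, size = 256L, seed = 1L, out_dir,
                          sym = symbol_spec()) {
  for (sub in c("clean", "orig", "prior"))
    dir.create(file.path(out_dir, sub), recursive = TRUE,
               showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- seed + i
    spec <- random_phantom_spec(size, si)
    tri <- phantom_triplet(spec, sym, seed = si)
    nm <- sprintf("%03d.png", i)
    png::writePNG(tri$clean, file.path(out_dir, "clean", nm))
    png::writePNG(tri$original, file.path(out_dir, "orig", nm))
    png::writePNG(tri$prior_mask, file.path(out_dir, "prior", nm))
    rows[[i]] <- data.frame(
      id = i, file = nm, seed = si,
      center_r = spec$lesion_center[1], center_c = spec$lesion_center[2],
      axis_a = spec$lesion_axes[1], axis_b = spec$lesion_axes[2],
      mask_fraction = tri$mask_fraction)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
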