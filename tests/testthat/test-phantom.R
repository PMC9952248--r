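# Synthetic phantom generator: specification validation, clean-image
# construction, symbol drawing primitives, triplet invariants, fixtures.

test_that("phantom_spec rejects invalid fields with the field named", {
  expect_error(phantom_spec(height = 60L), "height")
  expect_error(phantom_spec(width = 100L), "width")
  expect_error(phantom_spec(lesion_center = c(0, 0.5)), "lesion_center")
  expect_error(phantom_spec(lesion_axes = c(0.5, 0.5)), "lesion_axes")
  expect_error(phantom_spec(speckle_strength = -1), "speckle_strength")
  expect_error(phantom_spec(lesion_level = 0.7), "lesion_level")
})

test_that("clean phantom has the documented shape, range and determinism", {
  spec <- phantom_spec(height = 64L, width = 64L, seed = 5L)
  img <- synth_clean_phantom(spec)
  expect_identical(dim(img), c(64L, 64L, 3L))
  expect_true(min(img) >= 0 && max(img) <= 1)
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 1], img[, , 3])
  expect_identical(attr(img, "phantom_spec"), spec)
  expect_identical(img, synth_clean_phantom(spec))
  img2 <- synth_clean_phantom(phantom_spec(height = 64L, width = 64L,
                                           seed = 6L))
  expect_false(identical(img[, , 1], img2[, , 1]))
})

test_that("noise-free phantom hits the exact lesion and background levels", {
  spec <- phantom_spec(height = 64L, width = 64L, speckle_strength = 0,
                       background_level = 0.6, lesion_level = 0.15)
  img <- synth_clean_phantom(spec)
  expect_equal(img[32, 32, 1], 0.15)   # lesion center
  expect_equal(img[1, 1, 1], 0.6)      # far corner
})

test_that("cross pixels count 2*(2*arm+1) - 1 with a shared center", {
  for (arm in c(2L, 6L, 9L)) {
    px <- usginpaint:::cross_pixels(c(20L, 30L), arm)
    expect_identical(nrow(px), 2L * (2L * arm + 1L) - 1L)
    expect_identical(nrow(unique(px)), nrow(px))
    expect_true(any(px[, 1] == 20 & px[, 2] == 30))
  }
})

test_that("glyph pixels scale quadratically with the integer scale", {
  bm <- usginpaint:::.glyph_font[["+"]]
  n_on <- sum(bm)
  for (s in 1:3) {
    px <- usginpaint:::glyph_pixels("+", 5L, 5L, s)
    expect_identical(nrow(px), n_on * s * s)
  }
})

test_that("dilation of a single pixel is a (2r+1)^2 square", {
  m <- matrix(FALSE, 11, 11)
  m[6, 6] <- TRUE
  for (r in 0:2)
    expect_identical(sum(usginpaint:::dilate_mask(m, r)),
                     as.integer((2L * r + 1L)^2))
})

test_that("bresenham segment pixel count is max(|di|, |dj|) + 1", {
  cases <- list(c(1, 1, 1, 1), c(1, 1, 1, 9), c(2, 3, 8, 3), c(1, 1, 6, 9),
                c(9, 9, 2, 4))
  for (cs in cases) {
    px <- usginpaint:::bresenham_pixels(cs[1], cs[2], cs[3], cs[4])
    expect_identical(nrow(px),
                     as.integer(max(abs(cs[3] - cs[1]),
                                    abs(cs[4] - cs[2])) + 1L))
    expect_true(all(px[1, ] == cs[1:2]))
    expect_true(all(px[nrow(px), ] == cs[3:4]))
  }
})

test_that("triplet: prior mask covers every changed pixel exactly", {
  tri <- phantom_triplet(phantom_spec(height = 64L, width = 64L, seed = 2L),
                         symbol_spec(), seed = 2L)
  changed <- apply(abs(tri$original - tri$clean) > 0, c(1, 2), any)
  # every changed pixel is masked; the mask is the drawn set dilated by 1
  expect_true(all(tri$prior_mask[changed] == 1))
  expect_true(all(tri$prior_mask %in% c(0, 1)))
  expect_equal(tri$mask_fraction, mean(tri$prior_mask))
  expect_gt(tri$mask_fraction, 0)
  # changed pixels carry the symbol color (annotation yellow)
  idx <- which(changed)
  hw <- 64L * 64L
  expect_true(all(tri$original[idx] == 1))
  expect_true(all(tri$original[idx + hw] == 1))
  expect_true(all(tri$original[idx + 2L * hw] == 0))
})

test_that("triplets are seed-deterministic and seed-sensitive", {
  spec <- phantom_spec(height = 64L, width = 64L, seed = 3L)
  t1 <- phantom_triplet(spec, symbol_spec(), seed = 3L)
  t2 <- phantom_triplet(spec, symbol_spec(), seed = 3L)
  t3 <- phantom_triplet(spec, symbol_spec(), seed = 4L)
  expect_identical(t1$original, t2$original)
  expect_identical(t1$prior_mask, t2$prior_mask)
  expect_false(identical(t1$prior_mask, t3$prior_mask))
})

test_that("symbol_spec toggles control what is drawn", {
  spec <- phantom_spec(height = 64L, width = 64L, seed = 1L)
  none <- phantom_triplet(spec, symbol_spec(draw_outline = FALSE,
                                            n_crosses = 0L, n_glyphs = 0L),
                          seed = 1L)
  expect_identical(none$original, none$clean)
  expect_identical(sum(none$prior_mask), 0)
  only_glyphs <- phantom_triplet(spec,
                                 symbol_spec(draw_outline = FALSE,
                                             n_crosses = 0L, n_glyphs = 4L),
                                 seed = 1L)
  expect_gt(sum(only_glyphs$prior_mask), 0)
})

test_that("make_fixtures writes a reproducible dataset directory", {
  d1 <- withr_like_tempdir("fx1")
  d2 <- withr_like_tempdir("fx2")
  mf1 <- make_fixtures(3, size = 64L, seed = 9L, out_dir = d1)
  mf2 <- make_fixtures(3, size = 64L, seed = 9L, out_dir = d2)
  expect_identical(mf1, mf2)
  expect_identical(nrow(mf1), 3L)
  for (sub in c("clean", "orig", "prior")) {
    f1 <- file.path(d1, sub, mf1$file)
    expect_true(all(file.exists(f1)))
    expect_identical(unname(tools::md5sum(f1)),
                     unname(tools::md5sum(file.path(d2, sub, mf1$file))))
  }
  # masks survive the 0/255 PNG round trip
  m <- read_mask(file.path(d1, "prior", mf1$file[1]))
  expect_true(all(m %in% c(0, 1)))
  expect_identical(file.exists(file.path(d1, "manifest.tsv")), TRUE)
  unlink(c(d1, d2), recursive = TRUE)
})
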