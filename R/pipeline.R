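## Training loop, inference and evaluation. One training step performs one
## discriminator update then one generator update with the four-term total
## loss; training masks are always composed against the symbol prior masks
## so no hole ever overlaps a symbol. Every random choice (weight init,
## batch order, brush masks, flips) is derived from the run seed, making
## deterministic runs exactly resumable.

#' Training run configuration
#'
#' Defaults follow the full-scale regime (Adam, initial learning rate 1e-4,
#' batch 16, 1000 epochs, eta = (10, 10, 30, 100)); see [tiny_run_config()]
#' for the CPU desk-scale preset used throughout the test suite.
#'
#' @param image_size frame side, divisible by 8 (256 or 512 at full scale).
#' @param batch_size images per step (>= 1).
#' @param learning_rate Adam learning rate (> 0) of the generator.
#' @param disc_lr_factor discriminator learning rate as a fraction of
#'   `learning_rate`. At 1 the two networks train at the same rate; small
#'   adversarial runs are stabler with a slowed discriminator, which keeps
#'   the adversarial gradient informative instead of saturating (the
#'   reconstruction, perceptual and feature terms then dominate early
#'   training).
#' @param epochs training epochs.
#' @param weights a [loss_weights()].
#' @param brush a [brush_params()]; its pixel ranges are rescaled from the
#'   256-px reference to `image_size`.
#' @param generator a [generator_config()].
#' @param discriminator a [discriminator_config()].
#' @param extractor_seed seed of the frozen HRF feature extractor.
#' @param augment_hflip random horizontal flips (off in deterministic runs).
#' @param seed master run seed.
#' @param test_seed_offset disjoint seed namespace for evaluation masks, so
#'   test-time masks are fixed and reproducible.
#' @param checkpoint_dir directory for per-epoch checkpoints (NULL = none).
#' @return a `run_config` list.
#' @export
run_config <- function(image_size = 256L, batch_size = 16L,
                       learning_rate = 1e-4, disc_lr_factor = 1,
                       epochs = 1000L,
                       weights = loss_weights(), brush = brush_params(),
                       generator = generator_config(),
                       discriminator = discriminator_config(),
                       extractor_seed = 7L, augment_hflip = FALSE,
                       seed = 1L, test_seed_offset = 1000000L,
                       checkpoint_dir = NULL) {
  stopifnot(image_size %% 8 == 0, batch_size >= 1, learning_rate > 0,
            disc_lr_factor > 0,
            epochs >= 1, inherits(weights, "loss_weights"),
            inherits(brush, "brush_params"),
            inherits(generator, "generator_config"),
            inherits(discriminator, "discriminator_config"))
  structure(list(image_size = as.integer(image_size),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 disc_lr_factor = disc_lr_factor,
                 epochs = as.integer(epochs),
                 weights = weights, brush = brush, generator = generator,
                 discriminator = discriminator,
                 extractor_seed = as.integer(extractor_seed),
                 augment_hflip = isTRUE(augment_hflip),
                 seed = as.integer(seed),
                 test_seed_offset = as.integer(test_seed_offset),
                 checkpoint_dir = checkpoint_dir),
            class = "run_config")
}

#' Desk-scale training preset
#'
#' A 16-channel generator at 64 x 64 with batch 4 and generator learning
#' rate 2e-3 — sized so a few hundred steps on one CPU visibly close the
#' hole error. The discriminator trains at a tenth of the generator rate:
#' at this scale an evenly matched discriminator saturates within about a
#' hundred steps and its gradient then swamps the reconstruction terms.
#'
#' @param epochs training epochs.
#' @param seed master run seed.
#' @param ... overrides passed to [run_config()].
#' @return a `run_config`.
#' @export
tiny_run_config <- function(epochs = 5L, seed = 1L, ...) {
  preset <- list(image_size = 64L, batch_size = 4L, learning_rate = 2e-3,
                 disc_lr_factor = 0.1,
                 epochs = epochs,
                 generator = tiny_generator_config(),
                 discriminator = discriminator_config(base_channels = 16L),
                 seed = seed)
  overrides <- list(...)
  preset[names(overrides)] <- overrides
  do.call(run_config, preset)
}

#' Initialize a training state
#'
#' @param config a [run_config()].
#' @return a `train_state`: seeded generator/discriminator weights, Adam
#'   states, the frozen extractor, and zeroed counters.
#' @export
init_train_state <- function(config) {
  structure(list(
    step = 0L, epoch = 0L,
    gen = generator_weights(config$generator, seed = config$seed),
    disc = discriminator_weights(config$discriminator,
                                 seed = config$seed + 1L),
    opt_g = adam_state(), opt_d = adam_state(),
    extractor = feature_extractor("seeded", seed = config$extractor_seed),
    history = list(), mask_overlap_violations = 0L),
    class = "train_state")
}

## Deterministic per-(step, sample) mask seed, below 2^31.
mask_seed <- function(config, step, i) {
  (config$seed * 97L + step * 131L + i * 7L) %% 2000000000L
}

## Build the composed training masks for a batch; errors if composition
## ever overlaps the prior (it cannot, by construction — audited anyway).
batch_masks <- function(config, prior, step) {
  d <- dim(prior)
  brush <- scale_brush_params(config$brush, config$image_size)
  m <- array(0, d)
  for (i in seq_len(d[3])) {
    mg <- generate_irregular_mask(d[1], d[2], brush,
                                  seed = mask_seed(config, step, i))
    mi <- compose_training_mask(mg, prior[, , i, 1L])
    if (any(mi * prior[, , i, 1L] != 0))
      stop("training mask overlaps prior mask at step ", step)
    m[, , i, 1L] <- mi
  }
  m
}

#' One adversarial training step
#'
#' One discriminator update (real vs fake, fake detached) followed by one
#' generator update with the weighted total of L1, non-saturating
#' adversarial, HRF perceptual and discriminator-feature losses.
#'
#' @param batch list with `ori` (`H x W x N x 3` images) and `prior`
#'   (`H x W x N x 1` symbol masks).
#' @param state a `train_state`.
#' @param config the [run_config()].
#' @return the advanced state; the loss report (components, total,
#'   discriminator loss, gradient norms) is appended to `state$history` and
#'   returned in `state$last_report`.
#' @export
train_step <- function(batch, state, config) {
  w <- config$weights
  ori <- batch$ori
  prior <- batch$prior
  m <- batch_masks(config, prior, state$step)
  keep <- 1 - broadcast_mask(m, dim(ori))
  i_in <- ori * keep
  gin <- concat_channels(i_in, m)

  gf <- gen_fwd(state$gen, config$generator, gin, train = TRUE)
  state$gen <- gf$p
  fake <- gf$y

  ## Both updates draw on the same pair of discriminator forwards (the
  ## generator's gradients use the pre-update discriminator); the parameter
  ## updates are then applied discriminator first, generator second.
  real_in <- concat_channels(ori, i_in)
  fake_in <- concat_channels(fake, i_in)
  dr <- disc_fwd(state$disc, config$discriminator, real_in)
  df <- disc_fwd(state$disc, config$discriminator, fake_in)
  adv <- adversarial_losses(dr$scores, df$scores)
  if (!is.finite(adv$loss_d)) stop("non-finite loss: adversarial (D)")

  ## discriminator parameter gradients (fake detached)
  gd <- adv_grad_d(dr$scores, df$scores)
  br <- disc_bwd(state$disc, config$discriminator, dr$cache, gd$d_real)
  bf <- disc_bwd(state$disc, config$discriminator, df$cache, gd$d_fake)
  dgrads <- tree_add(br$g, bf$g)
  d_gnorm <- grad_norm(dgrads)

  ## generator losses and input gradients through the discriminator
  l_adv_g <- adv$loss_g
  l_l1 <- l1_loss(ori, fake)
  fa <- fx_fwd(state$extractor, ori)
  fb <- fx_fwd(state$extractor, fake)
  l_hrf <- stack_msq(fa$features, fb$features)
  l_feat <- stack_msq(dr$features, df$features)
  parts <- c(l_l1, l_adv_g, l_hrf, l_feat)
  names(parts) <- c("l1", "adv", "hrf", "disc_feat")
  bad <- which(!is.finite(parts))
  if (length(bad))
    stop("non-finite loss component: ", paste(names(parts)[bad],
                                              collapse = ", "))
  total <- total_loss(parts, w)

  dscore <- w$eta2 * adv_grad_g(df$scores)
  dfeats <- stack_msq_grad(dr$features, df$features)
  dfeats <- lapply(dfeats, function(x) w$eta4 * x)
  bD <- disc_bwd(state$disc, config$discriminator, df$cache, dscore, dfeats)
  dfake <- bD$dx[, , , 1:3, drop = FALSE]
  dfake <- dfake + w$eta1 * l1_loss_grad(ori, fake)
  dhrf <- stack_msq_grad(fa$features, fb$features)
  dhrf <- lapply(dhrf, function(x) w$eta3 * x)
  dfake <- dfake + fx_bwd(state$extractor, fb$cache, dhrf)
  gb <- gen_bwd(state$gen, config$generator, gf$cache, dfake)
  g_gnorm <- grad_norm(gb$g)

  ## apply the updates: discriminator, then generator
  ud <- adam_update(state$disc, dgrads, state$opt_d,
                    config$learning_rate * config$disc_lr_factor)
  state$disc <- ud$params
  state$opt_d <- ud$state
  ug <- adam_update(state$gen, gb$g, state$opt_g, config$learning_rate)
  state$gen <- ug$params
  state$opt_g <- ug$state

  state$step <- state$step + 1L
  report <- list(step = state$step, epoch = state$epoch,
                 l1 = l_l1, adv = l_adv_g, hrf = l_hrf, disc_feat = l_feat,
                 total = total, loss_d = adv$loss_d,
                 grad_norm_g = g_gnorm, grad_norm_d = d_gnorm,
                 mask_fraction = mean(m))
  state$last_report <- report
  state$history[[length(state$history) + 1L]] <- report
  state
}

## ---- dataset ----------------------------------------------------------------

#' Load a fixture-style dataset directory
#'
#' Expects `manifest.tsv` plus `orig/`, `prior/` and (optionally) `clean/`
#' subdirectories as written by [make_fixtures()].
#'
#' @param dir dataset directory.
#' @return list of per-image lists with `ori`, `prior` and optional `clean`.
#' @export
load_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf_path))
    stop("load_dataset: no manifest.tsv in ", dir)
  mf <- utils::read.delim(mf_path)
  missing <- character(0)
  data <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    fo <- file.path(dir, "orig", mf$file[i])
    fp <- file.path(dir, "prior", mf$file[i])
    fc <- file.path(dir, "clean", mf$file[i])
    if (!file.exists(fo)) missing <- c(missing, fo)
    if (!file.exists(fp)) missing <- c(missing, fp)
    if (length(missing)) next
    data[[i]] <- list(ori = read_image(fo), prior = read_mask(fp),
                      clean = if (file.exists(fc)) read_image(fc))
  }
  if (length(missing))
    stop("load_dataset: missing files:\n  ", paste(missing, collapse = "\n  "))
  data
}

#' Read an image PNG as an H x W x 3 array in \[0, 1\]
#'
#' Grayscale images are replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path PNG file.
#' @return `H x W x 3` array.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 2L) x <- array(rep(x[, , 1], 3L), c(dim(x)[1:2], 3L))
  x
}

## Assemble a batch array from dataset entries.
stack_batch <- function(entries, flips = NULL) {
  d <- dim(entries[[1]]$ori)
  n <- length(entries)
  ori <- array(0, c(d[1], d[2], n, 3L))
  prior <- array(0, c(d[1], d[2], n, 1L))
  for (i in seq_len(n)) {
    oi <- entries[[i]]$ori
    pi <- entries[[i]]$prior
    if (!is.null(flips) && flips[i]) {
      oi <- oi[, d[2]:1, , drop = FALSE]
      pi <- pi[, d[2]:1, drop = FALSE]
    }
    ori[, , i, ] <- oi
    prior[, , i, 1L] <- pi
  }
  list(ori = ori, prior = prior)
}

## Mean hole-region L1 of the (evaluation-mode) generator over a dataset,
## with the symbol prior masks as holes, against the clean images when
## available.
eval_hole_l1 <- function(state, config, data) {
  errs <- vapply(data, function(e) {
    target <- if (!is.null(e$clean)) e$clean else e$ori
    m <- e$prior
    i_in <- corrupt(e$ori, m)
    y <- generator_forward(i_in, m, state$gen, config$generator,
                           train = FALSE)
    hole_l1(target, y, m)
  }, numeric(1))
  mean(errs)
}

#' Mean absolute error restricted to hole pixels
#'
#' @param a,b images of identical shape.
#' @param m binary mask; only pixels with `m == 1` enter the mean.
#' @return scalar, or `NA` for an empty mask.
#' @export
hole_l1 <- function(a, b, m) {
  mm <- broadcast_mask(m, dim(a)) == 1
  dim(mm) <- dim(a)
  if (!any(mm)) return(NA_real_)
  mean(abs(a[mm] - b[mm]))
}

## ---- checkpointing -----------------------------------------------------------

#' Save a training checkpoint
#'
#' A single archive holding the generator and discriminator weights, both
#' optimizer states, an echo of the configuration, the step/epoch counters
#' and the current RNG state.
#'
#' @param state a `train_state`.
#' @param config the [run_config()].
#' @param path output file.
#' @export
save_checkpoint <- function(state, config, path) {
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(state = state, config = config, rng = rng,
               package_version = as.character(utils::packageVersion("usginpaint"))),
          path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param restore_rng restore the saved RNG state (bit-identical resumption
#'   in deterministic mode).
#' @return list with `state` and `config`.
#' @export
load_checkpoint <- function(path, restore_rng = TRUE) {
  ck <- readRDS(path)
  if (restore_rng && !is.null(ck$rng))
    assign(".Random.seed", ck$rng, envir = globalenv())
  ck
}

## ---- training loop -----------------------------------------------------------

#' Train the inpainting model on a dataset directory
#'
#' Runs `config$epochs` epochs of [train_step()] over the dataset, with
#' per-epoch hole-L1 evaluation (symbol masks as holes), optional per-epoch
#' checkpointing, and exact resumption from a checkpoint.
#'
#' @param dataset_dir directory readable by [load_dataset()].
#' @param config a [run_config()].
#' @param resume_from optional checkpoint path; training continues after the
#'   stored epoch with identical results to an uninterrupted run.
#' @param quiet suppress the per-epoch progress line.
#' @return the final `train_state` (invisibly), with `epoch_log` attached.
#' @export
train <- function(dataset_dir, config, resume_from = NULL, quiet = TRUE) {
  data <- load_dataset(dataset_dir)
  n <- length(data)
  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from)
    state <- ck$state
    config <- ck$config
  } else {
    state <- init_train_state(config)
  }
  order0 <- with_seed(config$seed + 13L, sample.int(n))
  epoch_log <- if (!is.null(state$epoch_log)) state$epoch_log else list()
  first_epoch <- state$epoch + 1L
  for (ep in seq(first_epoch, length.out = config$epochs - state$epoch)) {
    state$epoch <- ep
    flips <- if (config$augment_hflip)
      with_seed(config$seed + 1000L + ep, stats::runif(n) < 0.5)
    else rep(FALSE, n)
    idx <- order0
    for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
      batch <- stack_batch(data[b], flips[b])
      state <- train_step(batch, state, config)
    }
    hl1 <- eval_hole_l1(state, config, data)
    epoch_log[[length(epoch_log) + 1L]] <-
      list(epoch = ep, hole_l1 = hl1,
           total = state$last_report$total)
    if (!quiet)
      message(sprintf("epoch %d  hole_l1 %.5f  total %.3f", ep, hl1,
                      state$last_report$total))
    state$epoch_log <- epoch_log
    if (!is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, recursive = TRUE,
                 showWarnings = FALSE)
      save_checkpoint(state, config,
                      file.path(config$checkpoint_dir,
                                sprintf("epoch_%04d.rds", ep)))
    }
  }
  invisible(state)
}

## ---- inference ----------------------------------------------------------------

## Reflection-pad an image (and mask) so both sides are divisible by 8.
reflect_pad8 <- function(x) {
  d <- dim(x)
  ph <- (8 - d[1] %% 8) %% 8
  pw <- (8 - d[2] %% 8) %% 8
  if (ph == 0 && pw == 0) return(list(x = x, ph = 0L, pw = 0L))
  ri <- c(seq_len(d[1]), rev(seq_len(d[1]))[seq_len(ph)])
  ci <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(pw)])
  y <- if (length(d) == 2L) x[ri, ci] else x[ri, ci, , drop = FALSE]
  list(x = y, ph = ph, pw = pw)
}

#' Inpaint one image with a trained checkpoint
#'
#' Reads the image, obtains the hole mask (from a mask file, the symbol
#' prior mask, or a seeded generated mask), runs the generator in
#' evaluation mode, optionally composites the known pixels back over the
#' prediction, and writes the PNG plus a JSON sidecar recording the
#' checkpoint hash, mask source and composite flag. Images whose sides are
#' not divisible by 8 are reflection-padded and cropped back.
#'
#' @param image_path input PNG.
#' @param mask_source `"file"`, `"prior"` (both read `mask_path`; "prior"
#'   declares the mask to be the annotation-symbol mask, the mode that
#'   removes symbols) or `"generated"`.
#' @param checkpoint checkpoint path from [save_checkpoint()].
#' @param out_path output PNG (default: input name + `_inpainted`).
#' @param mask_path mask PNG for `"file"`/`"prior"`.
#' @param composite copy known pixels from the input over the prediction.
#' @param seed seed for `"generated"` masks.
#' @return invisibly, a list with `out_path`, `sidecar` and the metadata.
#' @export
inpaint <- function(image_path, mask_source = c("file", "prior", "generated"),
                    checkpoint, out_path = NULL, mask_path = NULL,
                    composite = TRUE, seed = 1L) {
  mask_source <- match.arg(mask_source)
  ck <- load_checkpoint(checkpoint, restore_rng = FALSE)
  img <- read_image(image_path)
  d0 <- dim(img)
  m <- switch(mask_source,
              file = ,
              prior = {
                if (is.null(mask_path))
                  stop("inpaint: mask_path required for mask_source = \"",
                       mask_source, "\"")
                read_mask(mask_path)
              },
              generated = generate_irregular_mask(
                d0[1], d0[2],
                scale_brush_params(ck$config$brush, min(d0[1], d0[2])),
                seed = seed + ck$config$test_seed_offset))
  if (!identical(dim(m), d0[1:2]))
    stop("inpaint: mask size ", paste(dim(m), collapse = "x"),
         " does not match image ", paste(d0[1:2], collapse = "x"))
  pi_ <- reflect_pad8(img)
  pm <- reflect_pad8(m)
  i_in <- corrupt(pi_$x, pm$x)
  y <- generator_forward(i_in, pm$x, ck$state$gen, ck$config$generator,
                         train = FALSE)
  if (composite) y <- composite_output(y, i_in, pm$x)
  y <- y[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE]
  y <- pmin(pmax(y, 0), 1)
  if (is.null(out_path))
    out_path <- sub("\\.png$", "_inpainted.png", image_path,
                    ignore.case = TRUE)
  png::writePNG(y, out_path)
  meta <- list(image = image_path,
               checkpoint_md5 = unname(tools::md5sum(checkpoint)),
               mask_source = mask_source, composite = composite,
               padded = c(pi_$ph, pi_$pw), size = d0[1:2])
  sidecar <- paste0(out_path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(out_path = out_path, sidecar = sidecar, meta = meta))
}

## ---- corpus evaluation ----------------------------------------------------------

## Pooled feature embedding of one image: spatial mean of every extractor
## layer, concatenated.
pooled_features <- function(img, extractor) {
  fs <- fx_fwd(extractor, as_ft(img))$features
  unlist(lapply(fs, function(f) {
    d <- dim(f)
    colMeans(matrix(f, ncol = d[4]))
  }))
}

#' Evaluate two image directories against each other
#'
#' Computes per-image SSIM and the LPIPS-form distance, plus the corpus
#' Frechet distance over pooled extractor features, and mean / variance /
#' 95% confidence-interval summaries. With a mask directory the comparison
#' is restricted to hole regions: outside the holes the second image is
#' replaced by the first before the metrics are computed.
#'
#' @param dir_gt,dir_pred directories of identically named PNGs.
#' @param mask_dir optional directory of 0/255 mask PNGs (same names).
#' @param extractor a [feature_extractor()] for LPIPS and FID embeddings.
#' @param out_tsv optional path for the per-image TSV.
#' @return list with `per_image` (data.frame), `fid`, and `summary`.
#' @export
evaluate_dirs <- function(dir_gt, dir_pred, mask_dir = NULL,
                          extractor = feature_extractor(), out_tsv = NULL) {
  files <- sort(list.files(dir_gt, pattern = "\\.png$"))
  if (!length(files)) stop("evaluate_dirs: no PNGs in ", dir_gt)
  rows <- vector("list", length(files))
  fg <- fp <- vector("list", length(files))
  for (i in seq_along(files)) {
    a <- read_image(file.path(dir_gt, files[i]))
    b <- read_image(file.path(dir_pred, files[i]))
    if (!is.null(mask_dir)) {
      m <- read_mask(file.path(mask_dir, files[i]))
      mb <- broadcast_mask(m, dim(a))
      dim(mb) <- dim(a)
      b <- a * (1 - mb) + b * mb
    }
    rows[[i]] <- data.frame(file = files[i],
                            ssim = ssim(a, b),
                            lpips = lpips(a, b, extractor))
    fg[[i]] <- pooled_features(a, extractor)
    fp[[i]] <- pooled_features(b, extractor)
  }
  per_image <- do.call(rbind, rows)
  fid_val <- if (length(files) >= 2) {
    fid(feature_stats(do.call(rbind, fg)), feature_stats(do.call(rbind, fp)))
  } else NA_real_
  summarize <- function(v) {
    n <- length(v)
    se <- stats::sd(v) / sqrt(n)
    ci <- if (n > 1) stats::qt(0.975, n - 1) * se else NA_real_
    c(mean = mean(v), variance = stats::var(v),
      ci_lo = mean(v) - ci, ci_hi = mean(v) + ci)
  }
  summary <- rbind(ssim = summarize(per_image$ssim),
                   lpips = summarize(per_image$lpips))
  if (!is.null(out_tsv))
    utils::write.table(per_image, out_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(per_image = per_image, fid = fid_val, summary = summary)
}
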