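## The four training losses: pixel L1, adversarial (non-saturating GAN in
## the sigmoid parameterization), high-receptive-field (HRF) perceptual loss
## over a dilated-convolution feature extractor, and a perceptual loss over
## the discriminator's own feature stack. The weighted total uses
## eta = (10, 10, 30, 100) by default.

#' Loss weights for the four-term total
#'
#' @param eta1 weight of the pixel L1 loss (default 10).
#' @param eta2 weight of the adversarial loss (default 10).
#' @param eta3 weight of the HRF perceptual loss (default 30).
#' @param eta4 weight of the discriminator feature loss (default 100).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(eta1 = 10, eta2 = 10, eta3 = 30, eta4 = 100) {
  stopifnot(eta1 >= 0, eta2 >= 0, eta3 >= 0, eta4 >= 0)
  structure(list(eta1 = eta1, eta2 = eta2, eta3 = eta3, eta4 = eta4),
            class = "loss_weights")
}

#' Mean absolute pixel difference
#'
#' @param i_ori,i_inp images of identical shape.
#' @return scalar mean of `|i_ori - i_inp|` over all pixels and channels.
#' @export
l1_loss <- function(i_ori, i_inp) {
  if (!identical(dim(i_ori), dim(i_inp)))
    stop("l1_loss: shape mismatch")
  mean(abs(i_ori - i_inp))
}

l1_loss_grad <- function(i_ori, i_inp) {
  sign(i_inp - i_ori) / length(i_inp)
}

#' Adversarial losses from discriminator logit maps
#'
#' The discriminator objective (its maximization written as a minimized
#' negative) and the generator's non-saturating complement:
#' `loss_d = -mean(log sigma(d_real) + log(1 - sigma(d_fake)))`,
#' `loss_g = -mean(log sigma(d_fake))`.
#'
#' @param d_real_scores,d_fake_scores logit maps from
#'   [discriminator_forward()] on the original and the inpainted image.
#' @return list with scalars `loss_d` and `loss_g`.
#' @export
adversarial_losses <- function(d_real_scores, d_fake_scores) {
  if (!all(is.finite(d_real_scores)) || !all(is.finite(d_fake_scores)))
    stop("adversarial_losses: non-finite scores")
  ## log sigma(x) and log(1 - sigma(x)) in numerically stable form
  loss_d <- -(mean(stats::plogis(d_real_scores, log.p = TRUE)) +
                mean(stats::plogis(-d_fake_scores, log.p = TRUE)))
  loss_g <- -mean(stats::plogis(d_fake_scores, log.p = TRUE))
  list(loss_d = loss_d, loss_g = loss_g)
}

## Gradients of the adversarial losses w.r.t. the logit maps.
adv_grad_d <- function(d_real_scores, d_fake_scores) {
  list(d_real = -(1 - stats::plogis(d_real_scores)) / length(d_real_scores),
       d_fake = stats::plogis(d_fake_scores) / length(d_fake_scores))
}

adv_grad_g <- function(d_fake_scores) {
  -(1 - stats::plogis(d_fake_scores)) / length(d_fake_scores)
}

## ---- feature extractor ----------------------------------------------------

#' Pluggable feature extractor for perceptual losses and embeddings
#'
#' `kind = "seeded"` builds a small frozen dilated-convolution network
#' (dilations 1, 2, 4 — a high-receptive-field pyramid) with weights drawn
#' from a fixed seed, so every perceptual quantity in the package is
#' bit-reproducible without any external weight file. `kind = "identity"`
#' returns the image itself as the single feature layer, which reduces the
#' perceptual loss to a plain mean squared error (useful for analytic
#' checks).
#'
#' @param kind `"seeded"` or `"identity"`.
#' @param seed integer seed for the frozen weights.
#' @param channels widths of the tapped stages.
#' @param dilations dilation of each stage's 3x3 convolution.
#' @param strides stride of each stage (the default halves the resolution
#'   once before the dilated stages).
#' @return a `feature_extractor` object.
#' @export
feature_extractor <- function(kind = c("seeded", "identity"), seed = 7L,
                              channels = c(8L, 16L, 16L),
                              dilations = c(1L, 2L, 4L),
                              strides = c(2L, 1L, 1L)) {
  kind <- match.arg(kind)
  ex <- list(kind = kind, n_layers = 1L)
  if (kind == "seeded") {
    stopifnot(length(channels) == length(dilations),
              length(strides) == length(dilations))
    cin <- 3L
    params <- vector("list", length(channels))
    with_seed(seed, for (i in seq_along(channels)) {
      params[[i]] <- conv_init(cin, channels[i], 3L)
      cin <- channels[i]
    })
    ex$params <- params
    ex$dilations <- as.integer(dilations)
    ex$strides <- as.integer(strides)
    ex$n_layers <- length(channels)
  }
  structure(ex, class = "feature_extractor")
}

fx_fwd <- function(ex, x) {
  if (ex$kind == "identity")
    return(list(features = list(x), cache = NULL))
  feats <- vector("list", ex$n_layers)
  caches <- vector("list", ex$n_layers)
  h <- x
  for (i in seq_len(ex$n_layers)) {
    dl <- ex$dilations[i]
    cv <- conv_fwd(ex$params[[i]], h, stride = ex$strides[i], pad = dl,
                   dilation = dl)
    ac <- relu_fwd(cv$y)
    feats[[i]] <- ac$y
    caches[[i]] <- list(cv = cv$cache, ac = ac$cache)
    h <- ac$y
  }
  list(features = feats, cache = caches)
}

## Backpropagate per-layer feature gradients to the input image.
fx_bwd <- function(ex, cache, dfeats) {
  if (ex$kind == "identity") return(dfeats[[1]])
  dh <- NULL
  for (i in rev(seq_len(ex$n_layers))) {
    d <- dfeats[[i]]
    dh <- if (is.null(dh)) d else if (is.null(d)) dh else dh + d
    da <- relu_bwd(cache[[i]]$ac, dh)
    cb <- conv_bwd(ex$params[[i]], cache[[i]]$cv, da)
    dh <- cb$dx
  }
  dh
}

## Intra-layer mean of squared differences, then inter-layer mean.
stack_msq <- function(fa, fb) {
  if (length(fa) != length(fb))
    stop("feature stack length mismatch: ", length(fa), " vs ", length(fb))
  per <- mapply(function(a, b) mean((a - b)^2), fa, fb)
  mean(per)
}

## Gradient of stack_msq w.r.t. the second stack.
stack_msq_grad <- function(fa, fb) {
  nl <- length(fa)
  mapply(function(a, b) 2 * (b - a) / (length(b) * nl), fa, fb,
         SIMPLIFY = FALSE)
}

#' High-receptive-field perceptual loss
#'
#' Feature-space distance over the extractor's tapped layers: within each
#' layer the squared differences are averaged, then the layer values are
#' averaged (the inter-layer mean after the intra-layer mean).
#'
#' @param i_ori,i_inp images of identical shape.
#' @param extractor a [feature_extractor()].
#' @return scalar loss, 0 for identical images.
#' @export
hrf_perceptual_loss <- function(i_ori, i_inp, extractor) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (!identical(dim(i_ori), dim(i_inp)))
    stop("hrf_perceptual_loss: shape mismatch")
  a <- fx_fwd(extractor, as_ft(i_ori))
  b <- fx_fwd(extractor, as_ft(i_inp))
  stack_msq(a$features, b$features)
}

#' Discriminator feature-matching loss
#'
#' Same intra-layer-then-inter-layer mean of squared differences as the HRF
#' perceptual loss, computed over the discriminator's per-layer feature
#' stacks for the original and the inpainted image.
#'
#' @param features_real,features_fake equal-length lists of feature maps
#'   from [discriminator_forward()].
#' @return scalar loss, 0 for identical stacks.
#' @export
disc_feature_loss <- function(features_real, features_fake) {
  stack_msq(features_real, features_fake)
}

#' Weighted total training loss
#'
#' `eta1 * L1 + eta2 * L_adv + eta3 * L_perc + eta4 * L_feat`.
#'
#' @param parts numeric vector or list of the four components, in the order
#'   L1, adversarial, HRF perceptual, discriminator feature.
#' @param w a [loss_weights()].
#' @return scalar total.
#' @export
total_loss <- function(parts, w = loss_weights()) {
  parts <- unlist(parts, use.names = FALSE)
  stopifnot(length(parts) == 4L)
  if (!all(is.finite(parts))) stop("total_loss: non-finite loss component")
  unname(w$eta1 * parts[1] + w$eta2 * parts[2] + w$eta3 * parts[3] +
           w$eta4 * parts[4])
}
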