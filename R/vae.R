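#' VAE training configuration
#'
#' Hyperparameters of the one-class VAE.  The defaults are the setting
#' that performed best in cross-validation on annotated Pap-smear cells:
#' a beta-TCVAE with `beta = 4` and latent dimension 8, with
#' `alpha = gamma = 1`.
#'
#' @param latent_dim Latent dimension (the study grid used 8, 32, 128).
#' @param beta Weight of the KL / total-correlation term (grid: 1, 4, 16).
#' @param alpha Weight of the index-code mutual-information term
#'   (beta-TCVAE only).
#' @param gamma Weight of the dimension-wise KL term (beta-TCVAE only).
#' @param loss One of `"vae"`, `"beta-vae"`, `"beta-tcvae"`.
#' @param augment An [augmentation_mode()] applied afresh each epoch.
#' @param epochs Number of training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param hidden Width of the single hidden layer in encoder and decoder.
#' @param model_size Side of the model input window in pixels.
#' @param dataset_size Total dataset size `N` used by the beta-TCVAE
#'   minibatch-weighted-sampling estimator; filled in automatically by
#'   [vae_occ()].
#' @param seed Integer seed governing initialisation, shuffling,
#'   augmentation draws and the reparameterisation noise.
#' @return An object of class `"vae_config"`.
#' @export
vae_config <- function(latent_dim = 8, beta = 4, alpha = 1, gamma = 1,
                       loss = c("beta-tcvae", "beta-vae", "vae"),
                       augment = augmentation_mode("none"),
                       epochs = 20, batch_size = 64, learning_rate = 1e-3,
                       hidden = 256, model_size = 64, dataset_size = NULL,
                       seed = 1) {
  loss <- match.arg(loss)
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  if (latent_dim < 1) stop("`latent_dim` must be >= 1", call. = FALSE)
  structure(list(latent_dim = latent_dim, beta = beta, alpha = alpha,
                 gamma = gamma, loss = loss, augment = augment,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, hidden = hidden,
                 model_size = model_size, dataset_size = dataset_size,
                 seed = seed),
            class = "vae_config")
}

#' Reparameterisation transform
#'
#' Expresses a latent draw as a deterministic function of the posterior
#' parameters and external noise: `z = mean + stddev * eps`, elementwise,
#' so gradients pass through the sampling step.
#'
#' @param posterior A [latent_posterior()].
#' @param eps Numeric noise vector of the same length as the posterior
#'   mean (standard normal draws in training).
#' @return Latent vector `z`.
#' @export
reparameterize <- function(posterior, eps) {
  stopifnot(inherits(posterior, "latent_posterior"))
  if (length(eps) != length(posterior$mean))
    stop("`eps` must have length ", length(posterior$mean), call. = FALSE)
  posterior$mean + posterior$stddev * eps
}

#' KL divergence from a diagonal Gaussian posterior to the prior
#'
#' Closed form of `KL(q || N(0, I))` for a diagonal Gaussian `q`:
#' `sum_j 0.5 * (mu_j^2 + sigma_j^2 - 1 - log sigma_j^2)`, in nats.
#'
#' @param posterior A [latent_posterior()] or [latent_posteriors()] set.
#' @return Scalar (or vector, one value per posterior in a set).
#' @export
kl_diag_gaussian <- function(posterior) {
  if (inherits(posterior, "latent_posteriors")) {
    if (nrow(posterior$mean) == 0) return(numeric(0))
    return(rowSums(0.5 * (posterior$mean^2 + posterior$stddev^2 - 1 -
                            2 * log(posterior$stddev))))
  }
  stopifnot(inherits(posterior, "latent_posterior"))
  sum(0.5 * (posterior$mean^2 + posterior$stddev^2 - 1 -
               2 * log(posterior$stddev)))
}

## Coerce images (list of [h,w,3] arrays or an n x D matrix) to a flat
## minibatch matrix for a given model input size.
.flatten_images <- function(images, model_size) {
  D <- model_size * model_size * 3
  if (is.matrix(images)) {
    if (ncol(images) != D)
      stop("input matrix must have ", D, " columns (", model_size, "x",
           model_size, "x3 images)", call. = FALSE)
    return(images)
  }
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  X <- matrix(0, length(images), D)
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (!all(dim(im) == c(model_size, model_size, 3)))
      stop("image ", i, " is not ", model_size, "x", model_size, "x3",
           call. = FALSE)
    X[i, ] <- as.vector(im)
  }
  X
}

#' Negative ELBO for the VAE and beta-VAE objectives
#'
#' Computes the per-batch negative evidence lower bound: a Gaussian
#' (unit-variance) reconstruction term — half the summed squared pixel
#' error — plus `beta` times the mean KL from the posterior to the
#' standard-normal prior (`beta = 1` for the plain VAE).
#'
#' @param batch Images (list of arrays or `n x D` matrix, see
#'   [vae_occ()]).
#' @param state A fitted or initialised `vae_occ` model (or its internal
#'   parameter list as stored in `$state`).
#' @param config A [vae_config()] with `loss` `"vae"` or `"beta-vae"`.
#' @param eps Optional `n x d` noise matrix; drawn from `N(0, 1)` when
#'   `NULL`.
#' @return List with `total` (scalar loss) and `terms`
#'   (`reconstruction`, `kl`).
#' @export
loss_elbo <- function(batch, state, config = NULL, eps = NULL) {
  st <- .as_state(state)
  config <- config %||% st$config
  if (!config$loss %in% c("vae", "beta-vae"))
    stop("loss_elbo() handles the `vae` and `beta-vae` variants; use ",
         "loss_beta_tcvae() for the total-correlation objective",
         call. = FALSE)
  X <- .flatten_images(batch, st$model_size)
  if (is.null(eps))
    eps <- matrix(stats::rnorm(nrow(X) * st$dims$d), nrow(X), st$dims$d)
  out <- .vae_loss_grad(st$params, X, eps, config)
  list(total = out$total, terms = out$terms)
}

#' Negative ELBO for the beta-TCVAE objective
#'
#' Decomposes the KL term into index-code mutual information, total
#' correlation and dimension-wise KL via the minibatch-weighted-sampling
#' estimator, and returns
#' `Lr + alpha * MI + beta * TC + gamma * dimension-wise KL`.
#'
#' @inheritParams loss_elbo
#' @param config A [vae_config()] with `loss = "beta-tcvae"`; its
#'   `dataset_size` is the `N` of the estimator (defaults to the batch
#'   size when unset).
#' @return List with `total` and `terms` (`reconstruction`, `mi`, `tc`,
#'   `dwkl`).
#' @export
loss_beta_tcvae <- function(batch, state, config = NULL, eps = NULL) {
  st <- .as_state(state)
  config <- config %||% st$config
  if (config$loss != "beta-tcvae")
    stop("`config$loss` must be \"beta-tcvae\"", call. = FALSE)
  X <- .flatten_images(batch, st$model_size)
  if (nrow(X) < 2)
    stop("the beta-TCVAE minibatch estimator is undefined for a batch of ",
         "one sample; provide at least 2", call. = FALSE)
  if (is.null(eps))
    eps <- matrix(stats::rnorm(nrow(X) * st$dims$d), nrow(X), st$dims$d)
  out <- .vae_loss_grad(st$params, X, eps, config)
  list(total = out$total, terms = out$terms)
}

.as_state <- function(x) {
  if (inherits(x, "vae_occ")) return(x$state)
  if (is.list(x) && !is.null(x$params) && !is.null(x$dims)) return(x)
  stop("expected a `vae_occ` model or an internal state object",
       call. = FALSE)
}

## Training-time augmentation: operate on the stored source crop (possibly
## larger than the model window) so rotation never imports background into
## the centre window, then cut the centred model-size window.
.augmented_view <- function(img, mode, model_size) {
  side <- dim(img)[1]
  if (mode$mode == "none") {
    if (side == model_size) return(img)
    ctr <- (side - model_size) %/% 2 + seq_len(model_size)
    return(img[ctr, ctr, , drop = FALSE])
  }
  work <- img
  if (side < 2.5 * model_size) {       # small input: reflect-pad for validity
    pad <- ceiling(model_size)
    work <- .pad_reflect(img, pad)
  } else if (side > 2.5 * model_size) { # large input: pre-crop for speed
    keep <- ceiling(2.5 * model_size)
    off <- (side - keep) %/% 2
    work <- img[off + seq_len(keep), off + seq_len(keep), , drop = FALSE]
  }
  p <- .draw_augment_params(mode)
  shift <- round(stats::runif(2, -mode$translation, mode$translation) *
                   model_size)
  out <- .augment_geometry(work, p$flip_h, p$flip_v, p$angle,
                           shift[1], shift[2])
  wside <- dim(out)[1]
  ctr <- (wside - model_size) %/% 2 + seq_len(model_size)
  pmin(pmax(out[ctr, ctr, , drop = FALSE] * p$bfac, 0), 1)
}

## Core training loop.  `images` is a list of [h,w,3] arrays (any size at
## least model_size); returns the internal state with loss history.
.train_vae <- function(images, config) {
  n <- length(images)
  if (n == 0) stop("training set is empty", call. = FALSE)
  d <- config$latent_dim
  D <- config$model_size^2 * 3
  H <- config$hidden
  config$dataset_size <- config$dataset_size %||% n
  params <- .init_params(D, H, d, config$seed)
  opt <- .adam_init(params)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed + 1)

  history <- vector("list", config$epochs)
  no_aug <- config$augment$mode == "none"
  X0 <- if (no_aug)
    .flatten_images(lapply(images, .augmented_view, mode = config$augment,
                           model_size = config$model_size),
                    config$model_size)
  for (ep in seq_len(config$epochs)) {
    X <- if (no_aug) X0 else
      .flatten_images(lapply(images, .augmented_view, mode = config$augment,
                             model_size = config$model_size),
                      config$model_size)
    ord <- sample.int(n)
    tot <- 0; terms_acc <- NULL; nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      if (config$loss == "beta-tcvae" && length(idx) < 2) next
      Xb <- X[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * d), length(idx), d)
      out <- .vae_loss_grad(params, Xb, eps, config)
      stepres <- .adam_step(params, out$grads, opt,
                            lr = config$learning_rate)
      params <- stepres$params; opt <- stepres$state
      tot <- tot + out$total; nb <- nb + 1
      terms_acc <- if (is.null(terms_acc)) unlist(out$terms) else
        terms_acc + unlist(out$terms)
    }
    history[[ep]] <- c(epoch = ep, loss = tot / nb, terms_acc / nb)
  }
  hist_df <- if (config$epochs > 0)
    as.data.frame(do.call(rbind, history)) else
      data.frame(epoch = numeric(0), loss = numeric(0))
  list(params = params, dims = list(D = D, H = H, d = d),
       model_size = config$model_size, config = config,
       epoch = config$epochs, loss_history = hist_df)
}

#' Encode images to latent posteriors
#'
#' Runs the trained probabilistic encoder on a batch of model-sized
#' images, returning one diagonal Gaussian posterior per image in input
#' order.
#'
#' @param images List of `model_size x model_size x 3` arrays in
#'   `[0, 1]`, a single such array, or an `n x D` matrix of flattened
#'   images.
#' @param state A fitted [vae_occ()] model (or its internal state).
#' @return A [latent_posteriors()] set.
#' @export
encode <- function(images, state) {
  st <- .as_state(state)
  X <- .flatten_images(images, st$model_size)
  enc <- .encoder_forward(st$params, X)
  latent_posteriors(enc$mu, exp(0.5 * enc$logvar))
}

#' Decode latent vectors to images
#'
#' Runs the decoder mean on a matrix of latent vectors.
#'
#' @param z Latent vector of length `d` or `n x d` matrix.
#' @param state A fitted [vae_occ()] model (or its internal state).
#' @return List of decoded `[h, w, 3]` arrays.
#' @export
decode <- function(z, state) {
  st <- .as_state(state)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != st$dims$d)
    stop("`z` must have ", st$dims$d, " columns", call. = FALSE)
  dec <- .decoder_forward(st$params, z)
  m <- st$model_size
  lapply(seq_len(nrow(z)), function(i) array(dec$Xhat[i, ], c(m, m, 3)))
}
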