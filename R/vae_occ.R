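#' Fit a one-class VAE abnormality model to normal cell images
#'
#' Trains a variational autoencoder (plain VAE, beta-VAE or beta-TCVAE)
#' on images of normal cells only, then estimates a full-covariance
#' multivariate normal over the latent means of normal cells.  Abnormality
#' of a new image is scored by [predict()] as the negative log-likelihood
#' of its latent representation under that fitted Gaussian, so the model
#' never sees an abnormal example during fitting — the one-class
#' contract is enforced: any non-normal label in `labels` is an error.
#'
#' @param x Training images: a list of `[h, w, 3]` arrays in `[0, 1]`
#'   (any side of at least `model_size`; larger crops are centre-cropped,
#'   and augmented before cropping when `augment` is active).
#' @param labels Optional class labels for `x`.  All must be `"NILM"`
#'   (or `FALSE` for a logical abnormality flag); otherwise fitting is
#'   refused.
#' @param latent_dim,beta,alpha,gamma,loss,augment,epochs,batch_size,seed
#'   Passed to [vae_config()]; defaults are the best cross-validated
#'   setting (beta-TCVAE, `beta = 4`, latent dimension 8).
#' @param gaussian_x Optional held-out normal images used to estimate the
#'   latent Gaussian separately from the images the encoder was trained
#'   on (recommended; defaults to `x` with a message).
#' @param ridge Ridge added to the covariance diagonal in
#'   [fit_gaussian()]; `NULL` for the default `1e-6 * trace/d`.
#' @param ... Further arguments to [vae_config()] (`hidden`,
#'   `learning_rate`, `model_size`, ...).
#' @return An object of class `"vae_occ"`: a list with the trained
#'   encoder/decoder `state`, the fitted normal-class `density`
#'   ([gaussian_density()]), `loss_history`, the resolved `config` and
#'   the matched `call`.  Supports `print`, `summary`, `predict`,
#'   `plot`, `residuals`, `simulate` and `coef`.
#' @examples
#' \donttest{
#' pop <- generate_population(population_spec(40, 0, image_size = 96))
#' fit <- vae_occ(pop$images, latent_dim = 4, epochs = 2,
#'                model_size = 64, hidden = 32, seed = 1)
#' print(fit)
#' }
#' @export
vae_occ <- function(x, labels = NULL, latent_dim = 8, beta = 4, alpha = 1,
                    gamma = 1, loss = "beta-tcvae",
                    augment = augmentation_mode("none"), epochs = 20,
                    batch_size = 64, seed = 1, gaussian_x = NULL,
                    ridge = NULL, ...) {
  cl <- match.call()
  if (length(x) == 0) stop("training set is empty", call. = FALSE)
  if (!is.null(labels)) {
    bad <- if (is.logical(labels)) labels else labels != "NILM"
    if (any(bad))
      stop("one-class contract: training images must all be normal ",
           "(NILM); found ", sum(bad), " abnormal label(s)", call. = FALSE)
  }
  config <- vae_config(latent_dim = latent_dim, beta = beta, alpha = alpha,
                       gamma = gamma, loss = loss, augment = augment,
                       epochs = epochs, batch_size = batch_size,
                       seed = seed, ...)
  state <- .train_vae(x, config)

  if (is.null(gaussian_x)) {
    message("`gaussian_x` not supplied; estimating the normal-class ",
            "Gaussian from the training images")
    gaussian_x <- x
  }
  gx <- lapply(gaussian_x, .augmented_view,
               mode = augmentation_mode("none"),
               model_size = config$model_size)
  post <- encode(gx, state)
  density <- fit_gaussian(post$mean, ridge = ridge)

  structure(list(state = state, config = state$config, density = density,
                 gaussian_posteriors = post,
                 loss_history = state$loss_history, call = cl),
            class = "vae_occ")
}

#' @export
print.vae_occ <- function(x, ...) {
  cfg <- x$config
  cat("One-class VAE abnormality model\n")
  cat("  objective: ", cfg$loss, " (beta = ", cfg$beta, ", alpha = ",
      cfg$alpha, ", gamma = ", cfg$gamma, ")\n", sep = "")
  cat("  latent dimension:", cfg$latent_dim,
      " | input:", cfg$model_size, "x", cfg$model_size, "x3\n")
  cat("  augmentation:", cfg$augment$mode, "| epochs:", cfg$epochs, "\n")
  h <- x$loss_history
  if (nrow(h) > 0)
    cat("  loss: first epoch ", signif(h$loss[1], 5), ", final epoch ",
        signif(h$loss[nrow(h)], 5), "\n", sep = "")
  else cat("  untrained (0 epochs): randomly initialised encoder\n")
  invisible(x)
}

#' @export
summary.vae_occ <- function(object, ...) {
  out <- list(config = object$config,
              loss_history = object$loss_history,
              density_mean_norm = sqrt(sum(object$density$mean^2)),
              density_logdet =
                2 * sum(log(diag(object$density$chol))),
              mean_posterior_stddev =
                mean(object$gaussian_posteriors$stddev))
  class(out) <- "summary.vae_occ"
  out
}

#' @export
print.summary.vae_occ <- function(x, ...) {
  cat("One-class VAE abnormality model\n\nLoss history (per epoch):\n")
  print(utils::head(x$loss_history, 3), row.names = FALSE)
  if (nrow(x$loss_history) > 3) {
    cat("  ...\n")
    print(utils::tail(x$loss_history, 2), row.names = FALSE)
  }
  cat("\nFitted normal-class latent Gaussian:\n")
  cat("  ||mean||:", signif(x$density_mean_norm, 5),
      " log|V|:", signif(x$density_logdet, 5), "\n")
  cat("  mean posterior stddev:", signif(x$mean_posterior_stddev, 4), "\n")
  invisible(x)
}

#' Predict abnormality scores, latents or reconstructions
#'
#' @param object A fitted [vae_occ()] model.
#' @param newdata Images as in [vae_occ()].
#' @param type `"score"` for the abnormality score (negative
#'   log-likelihood of the latent under the fitted normal-class Gaussian,
#'   in nats), `"latent"` for latent vectors, `"posterior"` for the full
#'   [latent_posteriors()], `"reconstruction"` for decoded images.
#' @param score_latent Whether the scored latent is the posterior mean
#'   (default, deterministic) or a single reparameterised sample.
#' @param seed Seed for `score_latent = "sample"`.
#' @param ... Unused.
#' @return Numeric vector of scores, a matrix of latents, a
#'   `latent_posteriors` set, or a list of images, matching `type`.
#' @export
predict.vae_occ <- function(object, newdata,
                            type = c("score", "latent", "posterior",
                                     "reconstruction"),
                            score_latent = c("mean", "sample"), seed = 1,
                            ...) {
  type <- match.arg(type)
  score_latent <- match.arg(score_latent)
  imgs <- if (is.matrix(newdata)) newdata else
    lapply(if (is.list(newdata)) newdata else list(newdata),
           .augmented_view, mode = augmentation_mode("none"),
           model_size = object$config$model_size)
  post <- encode(imgs, object$state)
  if (type == "posterior") return(post)
  z <- post$mean
  if (score_latent == "sample") {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    z <- post$mean + post$stddev * matrix(stats::rnorm(length(post$mean)),
                                          nrow(post$mean))
  }
  if (type == "latent") return(z)
  if (type == "reconstruction") return(decode(z, object$state))
  abnormality_score(z, object$density)
}

#' @export
coef.vae_occ <- function(object, ...) {
  list(mean = object$density$mean, covariance = object$density$covariance)
}

#' Reconstruction residuals of a one-class VAE
#'
#' Mean squared pixel error between each image and its reconstruction
#' through the posterior mean.
#'
#' @param object A fitted [vae_occ()] model.
#' @param newdata Images to reconstruct (required).
#' @param ... Unused.
#' @return Numeric vector of per-image mean squared errors.
#' @export
residuals.vae_occ <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    stop("`newdata` is required: the fitted object does not retain ",
         "training pixels", call. = FALSE)
  imgs <- lapply(if (is.list(newdata)) newdata else list(newdata),
                 .augmented_view, mode = augmentation_mode("none"),
                 model_size = object$config$model_size)
  X <- .flatten_images(imgs, object$config$model_size)
  post <- encode(X, object$state)
  dec <- .decoder_forward(object$state$params, post$mean)
  rowMeans((dec$Xhat - X)^2)
}

#' Simulate images from the fitted generative model
#'
#' Draws latent vectors from the fitted normal-class Gaussian and decodes
#' them.
#'
#' @param object A fitted [vae_occ()] model.
#' @param nsim Number of images.
#' @param seed Integer seed.
#' @param from `"density"` to sample from the fitted normal-class
#'   Gaussian, `"prior"` for the standard-normal prior.
#' @param ... Unused.
#' @return List of `[h, w, 3]` arrays.
#' @export
simulate.vae_occ <- function(object, nsim = 1, seed = 1,
                             from = c("density", "prior"), ...) {
  from <- match.arg(from)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  d <- object$config$latent_dim
  z <- if (from == "prior") matrix(stats::rnorm(nsim * d), nsim, d) else
    MASS::mvrnorm(nsim, object$density$mean, object$density$covariance,
                  empirical = FALSE)
  if (nsim == 1) z <- matrix(z, 1)
  decode(z, object$state)
}

#' Plot latent traversals of a fitted one-class VAE
#'
#' Renders the decoder output along an even grid in each latent
#' dimension, holding the other coordinates at the centre of the fitted
#' normal-class distribution — the visual read-out of what each latent
#' dimension encodes.
#'
#' @param x A fitted [vae_occ()] model.
#' @param dims Latent dimensions to traverse (default: all).
#' @param steps,span Grid resolution and half-width in standard
#'   deviations, see [latent_traversal()].
#' @param ... Unused.
#' @return Invisibly, the list of [latent_traversal()] grids.
#' @export
plot.vae_occ <- function(x, dims = seq_len(x$config$latent_dim),
                         steps = 10, span = 4, ...) {
  ctr <- colMeans(x$gaussian_posteriors$mean)
  sds <- apply(x$gaussian_posteriors$mean, 2, stats::sd)
  grids <- lapply(dims, function(j)
    latent_traversal(x, center = ctr, stddevs = sds, dim = j,
                     steps = steps, span = span))
  oldpar <- graphics::par(mfrow = c(length(dims), 1),
                          mar = c(0.3, 2, 0.3, 0.3))
  on.exit(graphics::par(oldpar))
  for (g in grids) plot(g, add_label = TRUE)
  invisible(grids)
}
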