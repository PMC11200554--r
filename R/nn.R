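## Fully connected encoder/decoder with analytic gradients.
##
## Encoder: x -> relu(x W1 + b1) -> (mu = h W2 + b2, logvar = h W3 + b3)
## Decoder: z -> relu(z W4 + b4) -> xhat = sigmoid(g W5 + b5)
##
## All minibatch tensors are row-major (one sample per row).  Gradients are
## derived by hand and verified against finite differences in the test
## suite; correctness there is what permits trusting the training loop.

.init_params <- function(D, H, d, seed) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  rn <- function(n1, n2, scale) {
    matrix(stats::rnorm(n1 * n2, 0, scale), n1, n2)
  }
  list(
    W1 = rn(D, H, sqrt(2 / D)), b1 = numeric(H),
    W2 = rn(H, d, sqrt(1 / H)), b2 = numeric(d),
    W3 = matrix(0, H, d),       b3 = numeric(d),   # logvar head: start at N(0,1)
    W4 = rn(d, H, sqrt(2 / d)), b4 = numeric(H),
    W5 = rn(H, D, sqrt(1 / H)), b5 = numeric(D)
  )
}

.addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

.encoder_forward <- function(params, X) {
  pre1 <- .addb(X %*% params$W1, params$b1)
  H1 <- pmax(pre1, 0)
  mu <- .addb(H1 %*% params$W2, params$b2)
  logvar <- .addb(H1 %*% params$W3, params$b3)
  logvar <- pmax(pmin(logvar, 30), -30)   # overflow guard, inactive in practice
  list(pre1 = pre1, H1 = H1, mu = mu, logvar = logvar)
}

.decoder_forward <- function(params, Z) {
  pre4 <- .addb(Z %*% params$W4, params$b4)
  G <- pmax(pre4, 0)
  pre5 <- .addb(G %*% params$W5, params$b5)
  Xhat <- stats::plogis(pre5)
  list(pre4 = pre4, G = G, Xhat = Xhat)
}

## Importance weights for estimating the aggregate posterior q(z) from a
## minibatch of M posteriors drawn from a dataset of size N: each row sums
## to one, the own-sample component gets weight 1/N (it is always present
## in the minibatch), one stratum element absorbs the remainder.
.mws_log_weights <- function(M, N) {
  Mm <- M - 1
  W <- matrix(1 / Mm, M, M)
  diag(W) <- 1 / N
  strat <- (N - Mm) / (N * Mm)
  if (strat <= 0) strat <- 1 / (N * Mm)   # degenerate N < M guard
  for (i in seq_len(M)) W[i, (i %% M) + 1] <- strat
  log(W)
}

## beta-TCVAE latent terms via minibatch-weighted sampling, with analytic
## gradients of mean_i [ alpha*logq(z_i|x_i) + (beta-alpha)*logq(z_i)
##   + (gamma-beta)*logqprod(z_i) - gamma*logp(z_i) ]
## with respect to z, and to the posterior parameters (mu, logvar) of every
## batch member appearing inside the mixture densities.
.tc_terms <- function(Z, mu, logvar, s, alpha, beta, gamma, N) {
  M <- nrow(Z); d <- ncol(Z)
  if (M < 2)
    stop("the minibatch estimator for the beta-TCVAE terms needs a batch ",
         "of at least 2 samples; increase the batch size", call. = FALSE)
  LOG2PI_H <- 0.5 * log(2 * pi)
  iv <- 1 / s^2
  logW <- .mws_log_weights(M, N)
  S <- logW
  Alist <- vector("list", d)
  for (k in seq_len(d)) {
    Dz <- outer(Z[, k], mu[, k], "-")
    IV <- matrix(iv[, k], M, M, byrow = TRUE)
    a <- -LOG2PI_H - 0.5 * matrix(logvar[, k], M, M, byrow = TRUE) -
      0.5 * Dz^2 * IV
    Alist[[k]] <- a
    S <- S + a
  }
  row_lse <- function(Mx) {
    mx <- apply(Mx, 1, max)
    mx + log(rowSums(exp(Mx - mx)))
  }
  lseS <- row_lse(S)
  logqzx <- diag(S) - diag(logW)
  logqz <- lseS
  w <- exp(S - lseS)
  lse_k <- matrix(0, M, d)
  logpz <- rowSums(-LOG2PI_H - 0.5 * Z^2)

  cA <- alpha; cB <- beta - alpha; cC <- gamma - beta; cP <- -gamma
  dZ <- matrix(0, M, d); dMu <- matrix(0, M, d); dLv <- matrix(0, M, d)
  for (k in seq_len(d)) {
    a <- Alist[[k]]
    lk <- row_lse(a + logW)
    lse_k[, k] <- lk
    v <- exp(a + logW - lk)
    Dz <- outer(Z[, k], mu[, k], "-")
    IV <- matrix(iv[, k], M, M, byrow = TRUE)
    Gk <- Dz * IV                       # d a_ij / d mu_jk  (= -d a/d z_ik)
    Hk <- -0.5 + 0.5 * Dz^2 * IV        # d a_ij / d logvar_jk
    dZ[, k] <- (cA * (-diag(Gk)) + cB * rowSums(w * (-Gk)) +
                  cC * rowSums(v * (-Gk)) - cP * Z[, k]) / M
    dMu[, k] <- (cA * diag(Gk) + cB * colSums(w * Gk) +
                   cC * colSums(v * Gk)) / M
    dLv[, k] <- (cA * diag(Hk) + cB * colSums(w * Hk) +
                   cC * colSums(v * Hk)) / M
  }
  logqz_prod <- rowSums(lse_k)
  list(mi = mean(logqzx - logqz),
       tc = mean(logqz - logqz_prod),
       dwkl = mean(logqz_prod - logpz),
       dZ = dZ, dMu = dMu, dLv = dLv)
}

## One forward+backward pass.  Returns total loss, term breakdown, and
## gradients for every parameter.
.vae_loss_grad <- function(params, X, eps, config) {
  M <- nrow(X)
  enc <- .encoder_forward(params, X)
  mu <- enc$mu; logvar <- enc$logvar
  s <- exp(0.5 * logvar)
  Z <- mu + s * eps
  dec <- .decoder_forward(params, Z)
  Xhat <- dec$Xhat

  Lr_i <- 0.5 * rowSums((Xhat - X)^2)
  Lr <- mean(Lr_i)
  kl_i <- rowSums(0.5 * (mu^2 + s^2 - 1 - logvar))
  kl <- mean(kl_i)

  variant <- config$loss
  beta <- config$beta
  if (variant == "vae") beta <- 1

  ## --- backward: reconstruction path ---
  dXhat <- (Xhat - X) / M
  dpre5 <- dXhat * Xhat * (1 - Xhat)
  gW5 <- crossprod(dec$G, dpre5); gb5 <- colSums(dpre5)
  dG <- tcrossprod(dpre5, params$W5)
  dpre4 <- dG * (dec$pre4 > 0)
  gW4 <- crossprod(Z, dpre4); gb4 <- colSums(dpre4)
  dZ <- tcrossprod(dpre4, params$W4)

  if (variant %in% c("vae", "beta-vae")) {
    terms <- list(reconstruction = Lr, kl = kl)
    total <- Lr + beta * kl
    dmu <- dZ + beta * mu / M
    dlogvar <- dZ * (0.5 * s * eps) + beta * 0.5 * (s^2 - 1) / M
  } else if (variant == "beta-tcvae") {
    N <- config$dataset_size %||% M
    tc <- .tc_terms(Z, mu, logvar, s, config$alpha, beta, config$gamma, N)
    terms <- list(reconstruction = Lr, mi = tc$mi, tc = tc$tc,
                  dwkl = tc$dwkl)
    total <- Lr + config$alpha * tc$mi + beta * tc$tc + config$gamma * tc$dwkl
    dZ <- dZ + tc$dZ
    dmu <- dZ + tc$dMu
    dlogvar <- dZ * (0.5 * s * eps) + tc$dLv
  } else stop("unknown loss variant: ", variant, call. = FALSE)

  ## --- backward: encoder ---
  clip <- abs(logvar) < 30        # gradient of the overflow guard
  dlogvar <- dlogvar * clip
  gW2 <- crossprod(enc$H1, dmu); gb2 <- colSums(dmu)
  gW3 <- crossprod(enc$H1, dlogvar); gb3 <- colSums(dlogvar)
  dH1 <- tcrossprod(dmu, params$W2) + tcrossprod(dlogvar, params$W3)
  dpre1 <- dH1 * (enc$pre1 > 0)
  gW1 <- crossprod(X, dpre1); gb1 <- colSums(dpre1)

  list(total = total, terms = terms,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4,
                    W5 = gW5, b5 = gb5))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
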