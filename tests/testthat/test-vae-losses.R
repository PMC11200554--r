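make_tiny_state <- function(D = 12, H = 7, d = 3, seed = 7, jitter = 0.1) {
  ns <- asNamespace("cytovae")
  params <- ns$.init_params(D, H, d, seed)
  set.seed(seed + 1)
  for (nm in names(params))
    params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), 0, jitter)
  list(params = params, dims = list(D = D, H = H, d = d),
       model_size = sqrt(D / 3), config = NULL)
}

test_that("reparameterisation is the affine noise transform", {
  p <- latent_posterior(c(1, -2, 0.5), c(0.5, 2, 1))
  expect_equal(reparameterize(p, c(0, 0, 0)), p$mean)
  p2 <- latent_posterior(c(0, 0), c(1, 1))
  expect_equal(reparameterize(p2, c(0.3, -1.2)), c(0.3, -1.2))
  expect_error(reparameterize(p, c(0, 0)), "length")

  ## Monte-Carlo moments of z = mean + stddev * eps
  set.seed(1)
  n <- 1e5
  eps <- matrix(rnorm(n * 3), n, 3)
  z <- t(apply(eps, 1, function(e) reparameterize(p, e)))
  for (j in 1:3) {
    se_m <- p$stddev[j] / sqrt(n)
    expect_lt(abs(mean(z[, j]) - p$mean[j]), 3 * se_m)
    se_s <- p$stddev[j] / sqrt(2 * (n - 1))
    expect_lt(abs(sd(z[, j]) - p$stddev[j]), 3 * se_s)
  }
})

test_that("diagonal-Gaussian KL matches theory and Monte Carlo", {
  expect_equal(kl_diag_gaussian(latent_posterior(rep(0, 5), rep(1, 5))), 0)
  expect_equal(kl_diag_gaussian(latent_posterior(1, 1)), 0.5)
  expect_error(latent_posterior(0, -1), "positive")

  ## Monte-Carlo oracle E_q[log q - log p] on a random posterior
  set.seed(2)
  p <- latent_posterior(rnorm(3), exp(rnorm(3, 0, 0.3)))
  n <- 2e5
  z <- sweep(sweep(matrix(rnorm(n * 3), n, 3), 2, p$stddev, "*"),
             2, p$mean, "+")
  lq <- rowSums(sapply(1:3, function(j)
    dnorm(z[, j], p$mean[j], p$stddev[j], log = TRUE)))
  lp <- rowSums(dnorm(z, log = TRUE))
  diff <- lq - lp
  expect_lt(abs(kl_diag_gaussian(p) - mean(diff)),
            3 * sd(diff) / sqrt(n))

  ## non-negativity across random posteriors
  set.seed(3)
  for (i in 1:50) {
    d <- sample(1:8, 1)
    expect_gte(kl_diag_gaussian(
      latent_posterior(rnorm(d, 0, 2), exp(rnorm(d, 0, 1)))), 0)
  }
})

test_that("beta-VAE loss reduces to the VAE loss at beta = 1 and is
           linear in beta", {
  st <- make_tiny_state()
  set.seed(4)
  X <- matrix(runif(6 * 12), 6, 12)
  eps <- matrix(rnorm(6 * 3), 6, 3)
  cfg_v <- vae_config(latent_dim = 3, beta = 1, loss = "vae")
  cfg_b1 <- vae_config(latent_dim = 3, beta = 1, loss = "beta-vae")
  cfg_b2 <- vae_config(latent_dim = 3, beta = 2, loss = "beta-vae")
  l_v <- loss_elbo(X, st, cfg_v, eps = eps)
  l_b1 <- loss_elbo(X, st, cfg_b1, eps = eps)
  l_b2 <- loss_elbo(X, st, cfg_b2, eps = eps)
  expect_identical(l_v$total, l_b1$total)
  expect_equal(l_b2$total - l_b1$total, l_b1$terms$kl, tolerance = 1e-12)
})

test_that("posteriors forced to the prior zero the KL term", {
  st <- make_tiny_state()
  st$params$W2[] <- 0; st$params$b2[] <- 0
  st$params$W3[] <- 0; st$params$b3[] <- 0
  set.seed(5)
  X <- matrix(runif(5 * 12), 5, 12)
  eps <- matrix(rnorm(5 * 3), 5, 3)
  l <- loss_elbo(X, st, vae_config(latent_dim = 3, beta = 4,
                                   loss = "beta-vae"), eps = eps)
  expect_equal(l$terms$kl, 0)
  expect_equal(l$total, l$terms$reconstruction)
})

test_that("beta-TCVAE decomposition is consistent with the plain KL", {
  st <- make_tiny_state()
  set.seed(6)
  M <- 1024
  X <- matrix(runif(M * 12), M, 12)
  eps <- matrix(rnorm(M * 3), M, 3)
  cfg <- vae_config(latent_dim = 3, beta = 1, alpha = 1, gamma = 1,
                    loss = "beta-tcvae", dataset_size = M)
  l <- loss_beta_tcvae(X, st, cfg, eps = eps)
  ## the three decomposition terms against the closed-form batch KL
  post <- encode(X, st)
  kl <- mean(kl_diag_gaussian(post))
  est <- l$terms$mi + l$terms$tc + l$terms$dwkl
  expect_lt(abs(est - kl) / kl, 0.05)

  ## increasing beta increases the loss when the TC estimate is positive;
  ## tie all posterior-mean dimensions together so the total correlation
  ## is genuinely positive
  st2 <- st
  st2$params$W2 <- matrix(st$params$W2[, 1], nrow(st$params$W2), 3)
  st2$params$b2[] <- 0
  st2$params$W3[] <- 0; st2$params$b3[] <- 0
  l1c <- loss_beta_tcvae(X, st2, cfg, eps = eps)
  cfg4 <- vae_config(latent_dim = 3, beta = 4, alpha = 1, gamma = 1,
                     loss = "beta-tcvae", dataset_size = M)
  l4 <- loss_beta_tcvae(X, st2, cfg4, eps = eps)
  expect_gt(l1c$terms$tc, 0)
  expect_gt(l4$total, l1c$total)
  expect_equal(l4$total - l1c$total, 3 * l1c$terms$tc, tolerance = 1e-10)

  ## prior-collapsed posteriors: every decomposition term near zero
  st0 <- st
  st0$params$W2[] <- 0; st0$params$b2[] <- 0
  st0$params$W3[] <- 0; st0$params$b3[] <- 0
  l0 <- loss_beta_tcvae(X, st0, cfg, eps = eps)
  expect_lt(abs(l0$terms$mi), 0.05)
  expect_lt(abs(l0$terms$tc), 0.05)
  expect_lt(abs(l0$terms$dwkl), 0.05)

  ## the estimator refuses a batch of one
  expect_error(loss_beta_tcvae(X[1, , drop = FALSE], st, cfg),
               "at least 2")
})

test_that("analytic gradients match finite differences for all variants", {
  ns <- asNamespace("cytovae")
  st <- make_tiny_state(D = 6, H = 5, d = 2, seed = 11)
  set.seed(12)
  M <- 5
  X <- matrix(runif(M * 6), M, 6)
  eps <- matrix(rnorm(M * 2), M, 2)
  for (variant in c("vae", "beta-vae", "beta-tcvae")) {
    cfg <- list(loss = variant, beta = 2.5, alpha = 0.7, gamma = 1.3,
                dataset_size = 40)
    out <- ns$.vae_loss_grad(st$params, X, eps, cfg)
    f <- function(p) ns$.vae_loss_grad(p, X, eps, cfg)$total
    for (nm in names(st$params)) {
      g <- out$grads[[nm]]
      idx <- sample(length(g), min(5, length(g)))
      for (i in idx) {
        p2 <- st$params; p2[[nm]][i] <- p2[[nm]][i] + 1e-6
        p3 <- st$params; p3[[nm]][i] <- p3[[nm]][i] - 1e-6
        num <- (f(p2) - f(p3)) / 2e-6
        expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])),
                  1e-4)
      }
    }
  }
})

test_that("encoding preserves order, length and determinism", {
  fit <- tiny_fit()
  pop <- tiny_pop()
  imgs <- lapply(pop$images[1:4], extract_crop,
                 record = list(center_x = 48, center_y = 48),
                 model_size = 32)
  post <- encode(imgs, fit)
  expect_s3_class(post, "latent_posteriors")
  expect_equal(length(post), 4)
  dup <- encode(list(imgs[[2]], imgs[[2]]), fit)
  expect_identical(dup$mean[1, ], dup$mean[2, ])
  expect_identical(dup$stddev[1, ], dup$stddev[2, ])
  expect_error(encode(array(0, c(16, 16, 3)), fit), "32")
})
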