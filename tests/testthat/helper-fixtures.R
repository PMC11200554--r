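## Shared fixtures and independent oracles for the test suite.

.cache <- new.env(parent = emptyenv())

## Small synthetic population reused across files (built once per run).
tiny_pop <- function() {
  if (is.null(.cache$pop))
    .cache$pop <- generate_population(
      population_spec(60, 20, image_size = 96, seed = 101))
  .cache$pop
}

## Small trained model on normal crops of the tiny population.
tiny_fit <- function() {
  if (is.null(.cache$fit)) {
    pop <- tiny_pop()
    norm <- which(pop$annotations$class == "NILM")
    .cache$fit <- suppressMessages(vae_occ(
      pop$images[norm[1:40]], latent_dim = 4, beta = 4,
      loss = "beta-tcvae", epochs = 6, batch_size = 32, hidden = 32,
      model_size = 32, seed = 7, gaussian_x = pop$images[norm[41:60]]))
  }
  .cache$fit
}

## Untrained counterpart (identical architecture, 0 epochs).
tiny_fit0 <- function() {
  if (is.null(.cache$fit0)) {
    pop <- tiny_pop()
    norm <- which(pop$annotations$class == "NILM")
    .cache$fit0 <- suppressMessages(vae_occ(
      pop$images[norm[1:40]], latent_dim = 4, beta = 4,
      loss = "beta-tcvae", epochs = 0, batch_size = 32, hidden = 32,
      model_size = 32, seed = 7, gaussian_x = pop$images[norm[41:60]]))
  }
  .cache$fit0
}

rand_pd <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(0.5, d)
}

## Independent multivariate-normal log-density (solve/det route, distinct
## from the package's Cholesky/backsolve route).
mvn_logpdf_oracle <- function(z, mean, V) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  d <- length(mean)
  Vi <- solve(V)
  dev <- sweep(z, 2, mean)
  quad <- rowSums((dev %*% Vi) * dev)
  -0.5 * (d * log(2 * pi) + as.numeric(determinant(V)$modulus) + quad)
}

## Monte-Carlo cross-entropy -E_r[log q] with standard error.
ce_mc_oracle <- function(mr, Vr, mq, Vq, n = 1e5) {
  X <- MASS::mvrnorm(n, mr, Vr)
  v <- -mvn_logpdf_oracle(X, mq, Vq)
  list(est = mean(v), se = sd(v) / sqrt(n))
}

## Brute-force homogeneity/completeness/V via explicit loops over the
## class/cluster contingency (independent of the package's table route).
brute_hcv <- function(true, pred) {
  n <- length(true)
  cls <- unique(true); ks <- unique(pred)
  ent <- function(p) ifelse(p > 0, -p * log(p), 0)
  Hc <- sum(sapply(cls, function(cc) ent(sum(true == cc) / n)))
  Hk <- sum(sapply(ks, function(kk) ent(sum(pred == kk) / n)))
  Hck <- 0; Hkc <- 0
  for (kk in ks) {
    nk <- sum(pred == kk)
    for (cc in cls) {
      nck <- sum(true == cc & pred == kk)
      if (nck > 0) Hck <- Hck - nck / n * log(nck / nk)
    }
  }
  for (cc in cls) {
    nc <- sum(true == cc)
    for (kk in ks) {
      nck <- sum(true == cc & pred == kk)
      if (nck > 0) Hkc <- Hkc - nck / n * log(nck / nc)
    }
  }
  h <- if (Hc > 0) 1 - Hck / Hc else 1
  cm <- if (Hk > 0) 1 - Hkc / Hk else 1
  v <- if (h + cm > 0) 2 * h * cm / (h + cm) else 0
  c(homogeneity = h, completeness = cm, v_measure = v)
}

## Segmented nucleus area: count of clearly dark pixels.
nucleus_area <- function(img, threshold = 0.5) {
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  sum(lum < threshold)
}
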