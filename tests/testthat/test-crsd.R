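test_that("Gaussian cross-entropy matches closed-form anchors", {
  std1 <- gaussian_density(0, matrix(1))
  expect_equal(cross_entropy_gaussian(std1, std1),
               0.5 * log(2 * pi * exp(1)))
  q <- gaussian_density(2, matrix(1))
  expect_equal(cross_entropy_gaussian(std1, q), 0.5 * log(2 * pi) + 2.5)

  ## accepts diagonal posteriors directly
  p <- latent_posterior(c(0, 0), c(1, 1))
  expect_equal(cross_entropy_gaussian(p, p), log(2 * pi * exp(1)))
  expect_error(cross_entropy_gaussian(std1, p), "dimension")
})

test_that("Gaussian cross-entropy agrees with a Monte-Carlo oracle", {
  set.seed(7)
  for (i in 1:5) {
    d <- sample(1:3, 1)
    mr <- rnorm(d); Vr <- rand_pd(d)
    mq <- rnorm(d); Vq <- rand_pd(d)
    mc <- ce_mc_oracle(mr, Vr, mq, Vq, n = 1e5)
    ce <- cross_entropy_gaussian(gaussian_density(mr, Vr),
                                 gaussian_density(mq, Vq))
    expect_lt(abs(ce - mc$est), 3 * mc$se)
  }
})

test_that("cross-entropy obeys Gibbs' inequality", {
  set.seed(8)
  for (i in 1:20) {
    d <- sample(1:4, 1)
    Vr <- rand_pd(d)
    r <- gaussian_density(rnorm(d), Vr)
    q <- gaussian_density(rnorm(d), rand_pd(d))
    H_r <- cross_entropy_gaussian(r, r)   # entropy
    expect_gte(cross_entropy_gaussian(r, q) + 1e-12, H_r)
  }
})

test_that("CRSD zeros: identical densities and the mirrored-mean pair", {
  set.seed(9)
  r <- gaussian_density(rnorm(3), rand_pd(3))
  p <- gaussian_density(rnorm(3), rand_pd(3))
  expect_equal(crsd_single(p, p, r), 0)

  ## p = N(+mu, I), q = N(-mu, I), r = N(0, I): distance 0 though p != q
  mu <- c(1.3, -0.4, 2)
  I3 <- diag(3)
  expect_equal(crsd_single(gaussian_density(mu, I3),
                           gaussian_density(-mu, I3),
                           gaussian_density(rep(0, 3), I3)), 0)
})

test_that("CRSD reproduces the hand-computed shifted-Gaussian value", {
  r <- gaussian_density(0, matrix(1))
  p <- gaussian_density(1, matrix(1))
  q <- gaussian_density(2, matrix(1))
  expect_equal(crsd_single(p, q, r), 1.5)
})

test_that("CRSD is a pseudometric over random Gaussian triples", {
  set.seed(10)
  for (i in 1:200) {
    d <- sample(c(1, 4), 1)
    p <- gaussian_density(rnorm(d), rand_pd(d))
    q <- gaussian_density(rnorm(d), rand_pd(d))
    s <- gaussian_density(rnorm(d), rand_pd(d))
    r <- gaussian_density(rnorm(d), rand_pd(d))
    dpq <- crsd_single(p, q, r)
    expect_gte(dpq, 0)
    expect_equal(dpq, crsd_single(q, p, r))
    expect_lte(dpq, crsd_single(p, s, r) + crsd_single(s, q, r) + 1e-9)
  }
})

test_that("multi-reference CRSD is additive over the reference set", {
  set.seed(11)
  p <- gaussian_density(rnorm(2), rand_pd(2))
  q <- gaussian_density(rnorm(2), rand_pd(2))
  r <- gaussian_density(rnorm(2), rand_pd(2))
  expect_equal(crsd_multi(p, q, list(r, r)), 2 * crsd_single(p, q, r))
  expect_equal(crsd_multi(p, p, list(r, q)), 0)
  expect_error(crsd_multi(p, q, list()), "non-empty")
})

test_that("the CRSD matrix matches the scalar path and its symmetry", {
  set.seed(12)
  fx <- generate_latent_fixture(
    8, 3, component_means = list(c(0, 0, 0), c(2, -1, 1)),
    component_stddevs = list(c(0.5, 1, 2), c(1, 0.3, 0.8)), seed = 5)
  post <- fx$posteriors
  R <- list(post[[1]], post[[4]], post[[7]])
  D <- crsd_matrix(post, R)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  ## element-by-element agreement with the scalar closed form
  for (i in c(1, 3)) for (j in c(2, 6)) {
    expect_equal(D[i, j], crsd_multi(post[[i]], post[[j]], R),
                 tolerance = 1e-10)
  }
  expect_equal(dim(crsd_matrix(latent_posteriors(matrix(0, 1, 2),
                                                 matrix(1, 1, 2)))),
               c(1, 1))
})

test_that("equal-covariance posteriors give the quadratic-form CRSD", {
  ## shared diagonal covariance S and r = N(0, I):
  ## CE(r, p_i) differs only through mu_i' S^-1 mu_i, so
  ## d(p_i, p_j; r) = 0.5 |mu_i' S^-1 mu_i - mu_j' S^-1 mu_j|
  set.seed(13)
  n <- 6; d <- 4
  mu <- matrix(rnorm(n * d), n, d)
  svec <- c(0.5, 1, 2, 0.8)
  post <- latent_posteriors(mu, matrix(svec, n, d, byrow = TRUE))
  r <- latent_posterior(rep(0, d), rep(1, d))
  D <- crsd_matrix(post, list(r))
  qf <- rowSums(sweep(mu^2, 2, svec^2, "/"))
  expect_equal(D, 0.5 * abs(outer(qf, qf, "-")), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("agglomerative clustering on CRSD recovers planted structure", {
  set.seed(14)
  fx <- generate_latent_fixture(
    30, 4, component_means = list(rep(0, 4), rep(50, 4)),
    component_stddevs = list(rep(0.5, 4), rep(0.5, 4)), seed = 6)
  D <- crsd_matrix(fx$posteriors)
  res <- agglomerative_crsd(D, n_clusters = 2)
  expect_equal(unname(clustering_metrics(fx$labels, res$labels)),
               c(1, 1, 1))

  ## n_clusters = n: every point its own cluster
  res_n <- agglomerative_crsd(D, n_clusters = 30)
  expect_equal(length(unique(res_n$labels)), 30)
  expect_error(agglomerative_crsd(D, n_clusters = 31), "exceeds")

  ## permutation equivariance: permuting the input permutes the labels
  perm <- sample(30)
  res_p <- agglomerative_crsd(D[perm, perm], n_clusters = 2)
  expect_equal(unname(clustering_metrics(res$labels[perm], res_p$labels)),
               c(1, 1, 1))
})

test_that("baseline clusterers behave on canonical inputs", {
  set.seed(15)
  X <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 8, 0.2), 20, 2))
  truth <- rep(1:2, each = 20)
  km <- baseline_cluster(X, "kmeans", n_clusters = 2)
  expect_equal(unname(clustering_metrics(truth, km$labels)), c(1, 1, 1))
  sp <- baseline_cluster(X, "spectral", n_clusters = 2)
  expect_equal(unname(clustering_metrics(truth, sp$labels)), c(1, 1, 1))
  ag <- baseline_cluster(X, "agglomerative-euclidean", n_clusters = 2)
  expect_equal(unname(clustering_metrics(truth, ag$labels)), c(1, 1, 1))

  ## dbscan: identical points collapse to one cluster
  db <- baseline_cluster(matrix(1, 10, 2), "dbscan")
  expect_equal(length(unique(db$labels)), 1)
  ## dbscan separates the two tight blobs as well
  db2 <- baseline_cluster(X, "dbscan", eps = 0.5, min_pts = 5)
  expect_equal(unname(clustering_metrics(truth, db2$labels)), c(1, 1, 1))

  expect_error(baseline_cluster(X, "affinity"))
})

test_that("agglomerative paths agree between precomputed and fixed-point
           routes on separated data", {
  set.seed(16)
  X <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
             matrix(rnorm(30, 10, 0.3), 15, 2))
  Dm <- as.matrix(dist(X))
  via_matrix <- agglomerative_crsd(Dm, n_clusters = 2)
  via_points <- baseline_cluster(X, "agglomerative-euclidean",
                                 n_clusters = 2)
  expect_equal(unname(clustering_metrics(via_matrix$labels,
                                         via_points$labels)), c(1, 1, 1))
})

test_that("clustering metrics match brute-force entropy computations", {
  truth <- c("a", "a", "b", "b")
  expect_equal(unname(clustering_metrics(truth, c(2, 2, 1, 1))),
               c(1, 1, 1))   # pure relabeling
  m <- clustering_metrics(truth, c(1, 1, 1, 1))
  expect_equal(unname(m[c("homogeneity", "completeness")]), c(0, 1))

  set.seed(17)
  for (i in 1:5) {
    truth <- sample(letters[1:3], 60, replace = TRUE)
    pred <- sample(1:5, 60, replace = TRUE)
    expect_equal(clustering_metrics(truth, pred), brute_hcv(truth, pred),
                 tolerance = 1e-10)
  }
  expect_error(clustering_metrics(character(0), integer(0)), "empty")
  expect_error(clustering_metrics(truth, 1:3), "equal length")
})

test_that("posterior spread that carries group structure helps the
           distributional clustering", {
  ## two groups share the same mean distribution; only the posterior
  ## stddevs differ by group, so fixed-point clustering sees noise while
  ## the CRSD sees the groups
  vs <- numeric(0); ve <- numeric(0)
  for (s in 1:3) {
    fx <- generate_latent_fixture(
      40, 4, component_means = list(rep(0, 4), rep(0, 4)),
      component_stddevs = list(rep(0.4, 4), rep(1.6, 4)), seed = 100 + s)
    sm <- agglomerative_crsd(crsd_matrix(fx$posteriors), n_clusters = 2)
    em <- baseline_cluster(fx$posteriors, "agglomerative-euclidean",
                           n_clusters = 2)
    vs <- c(vs, clustering_metrics(fx$labels, sm$labels)[["v_measure"]])
    ve <- c(ve, clustering_metrics(fx$labels, em$labels)[["v_measure"]])
  }
  expect_gte(mean(vs), mean(ve))
})
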