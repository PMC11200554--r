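#' Cross-entropy between two multivariate normals
#'
#' Closed form of the Gaussian cross-entropy
#' `CE(r, q) = -E_r[log q(X)]
#'   = 0.5 * [log det(2 pi Sq) + tr(Sq^{-1} Sr) + (mr - mq)' Sq^{-1} (mr - mq)]`
#' in nats.  By Gibbs' inequality `CE(r, q) >= H(r)` with equality iff
#' `q = r`.
#'
#' @param r,q [gaussian_density()] or [latent_posterior()] objects of a
#'   common dimension; `q` must have positive-definite covariance.
#' @return Scalar cross-entropy in nats.
#' @export
cross_entropy_gaussian <- function(r, q) {
  r <- as_gaussian_density(r); q <- as_gaussian_density(q)
  d <- length(r$mean)
  if (length(q$mean) != d)
    stop("`r` and `q` must have equal dimension", call. = FALSE)
  ch <- q$chol
  logdet <- d * log(2 * pi) + 2 * sum(log(diag(ch)))
  ## tr(Sq^-1 Sr) and the Mahalanobis term via triangular solves
  Sri <- backsolve(ch, backsolve(ch, r$covariance, transpose = TRUE))
  dev <- backsolve(ch, r$mean - q$mean, transpose = TRUE)
  0.5 * (logdet + sum(diag(Sri)) + sum(dev^2))
}

#' Cross-entropy-based referenced statistical distance (single reference)
#'
#' The CRSD of densities `p` and `q` with respect to a reference density
#' `r`: `d(p, q; r) = |CE(r, q) - CE(r, p)|`.  It is symmetric in
#' `(p, q)`, non-negative, zero when `p = q`, and satisfies the triangle
#' inequality — a pseudometric, not a metric: distinct densities whose
#' cross-entropies against `r` coincide (for example unit-covariance
#' Gaussians with means `+mu` and `-mu` against `r` centred at the
#' origin) are at distance zero.
#'
#' @param p,q,r Densities ([gaussian_density()] or [latent_posterior()]).
#' @return Non-negative scalar in nats.
#' @export
crsd_single <- function(p, q, r) {
  abs(cross_entropy_gaussian(r, q) - cross_entropy_gaussian(r, p))
}

#' CRSD with respect to a finite reference set
#'
#' `d(p, q; R) = sum_{r in R} |CE(r, q) - CE(r, p)|`.
#'
#' @param p,q Densities.
#' @param R Non-empty list of reference densities, or a
#'   [latent_posteriors()] set.
#' @return Non-negative scalar in nats.
#' @export
crsd_multi <- function(p, q, R) {
  if (inherits(R, "latent_posteriors"))
    R <- lapply(seq_len(nrow(R$mean)), function(i) R[[i]])
  if (!is.list(R) || length(R) == 0)
    stop("`R` must be a non-empty list of reference densities",
         call. = FALSE)
  sum(vapply(R, function(r) crsd_single(p, q, r), numeric(1)))
}

#' Pairwise CRSD dissimilarity matrix over latent posteriors
#'
#' Computes the symmetric `n x n` matrix with entry `(i, j)` equal to
#' `crsd_multi(p_i, p_j; R)` for diagonal Gaussian posteriors, using the
#' vectorised closed form.  Cost is `O(n^2 |R|)`; for large sets the
#' reference set can be subsampled (seeded) with `max_ref`.
#'
#' @param posteriors A [latent_posteriors()] set (or list of
#'   [latent_posterior()]).
#' @param R Reference set: a `latent_posteriors` set or list of diagonal
#'   densities.  Defaults to `posteriors` itself — the posteriors of the
#'   evaluated fold act as their own references.
#' @param max_ref Optional cap on the number of references; a larger `R`
#'   is subsampled without replacement using `seed`.
#' @param seed Seed for the subsampling.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
crsd_matrix <- function(posteriors, R = posteriors, max_ref = NULL,
                        seed = 1) {
  P <- .diag_gaussians(posteriors)
  Rg <- .diag_gaussians(R)
  if (!is.null(max_ref) && nrow(Rg$mean) > max_ref) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    keep <- sample.int(nrow(Rg$mean), max_ref)
    Rg$mean <- Rg$mean[keep, , drop = FALSE]
    Rg$var <- Rg$var[keep, , drop = FALSE]
  }
  n <- nrow(P$mean)
  if (ncol(Rg$mean) != ncol(P$mean))
    stop("posteriors and references must share one dimension",
         call. = FALSE)
  ## CE(r_a, p_i) for all references a and posteriors i:
  ## 0.5 [ sum_d log(2 pi v_id) + sum_d (vr_ad + (mr_ad - m_id)^2) / v_id ]
  IV <- 1 / P$var                                 # n x d
  const_i <- rowSums(log(2 * pi * P$var))         # n
  C <- Rg$var %*% t(IV) +                         # a x n: tr term
    (Rg$mean^2) %*% t(IV) -
    2 * Rg$mean %*% t(P$mean * IV) +
    matrix(1, nrow(Rg$mean), 1) %*% t(rowSums(P$mean^2 * IV))
  C <- 0.5 * (C + matrix(const_i, nrow(Rg$mean), n, byrow = TRUE))
  D <- matrix(0, n, n)
  for (a in seq_len(nrow(C)))
    D <- D + abs(outer(C[a, ], C[a, ], "-"))
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Cluster-analysis result container
#'
#' @param labels Integer cluster labels in `1..n_clusters`.
#' @param n_clusters Number of clusters requested.
#' @param method Descriptive method name.
#' @param dissimilarity Optional `n x n` dissimilarity matrix used.
#' @param linkage Optional linkage name for agglomerative methods.
#' @return An object of class `"cluster_result"`.
#' @export
cluster_result <- function(labels, n_clusters, method,
                           dissimilarity = NULL, linkage = NULL) {
  structure(list(labels = as.integer(labels), n_clusters = n_clusters,
                 method = method, dissimilarity = dissimilarity,
                 linkage = linkage),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Clustering (", x$method, "): ", length(x$labels), " samples, ",
      length(unique(x$labels)), " clusters\n", sep = "")
  invisible(x)
}

#' Agglomerative clustering on a CRSD dissimilarity matrix
#'
#' Hierarchical agglomeration on a precomputed CRSD (or any) dissimilarity
#' matrix.  Average linkage is the default: centroid- or Ward-type
#' linkages need coordinates, which a precomputed pseudometric does not
#' supply.  Merging follows `stats::hclust`, whose tie-breaking (first
#' minimal entry in scan order) makes the result deterministic.
#'
#' @param dissimilarity Symmetric matrix with zero diagonal, e.g. from
#'   [crsd_matrix()].
#' @param n_clusters Number of clusters to cut the tree into (the study
#'   design used 100 on the full dataset).
#' @param linkage `hclust` linkage name.
#' @return A [cluster_result()].
#' @export
agglomerative_crsd <- function(dissimilarity, n_clusters = 100,
                               linkage = "average") {
  dissimilarity <- as.matrix(dissimilarity)
  n <- nrow(dissimilarity)
  if (n_clusters > n)
    stop("`n_clusters` (", n_clusters, ") exceeds the number of samples (",
         n, ")", call. = FALSE)
  if (max(abs(dissimilarity - t(dissimilarity))) >
      1e-8 * (1 + max(abs(dissimilarity))))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dissimilarity), method = linkage)
  cluster_result(stats::cutree(hc, k = n_clusters), n_clusters,
                 method = "agglomerative-crsd",
                 dissimilarity = dissimilarity, linkage = linkage)
}

## Plain DBSCAN on a Euclidean distance matrix (no pre-installed R
## implementation exists in this stack).  Border points join the first
## core cluster that reaches them; noise points are labelled 0 and then
## remapped to singleton clusters so every sample carries a label.
.dbscan <- function(X, eps = 0.5, min_pts = 5) {
  n <- nrow(X)
  Dm <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(Dm[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)          # 0 = unassigned/noise
  cl <- 0
  for (i in seq_len(n)) {
    if (labels[i] != 0 || !core[i]) next
    cl <- cl + 1
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == 0) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  if (any(labels == 0)) {
    noise <- which(labels == 0)
    labels[noise] <- cl + seq_along(noise)
  }
  labels
}

#' Baseline clusterers on latent means (fixed points)
#'
#' The conventional clustering algorithms the CRSD approach is compared
#' against, all operating on posterior means as fixed points:
#' agglomerative clustering with Euclidean distance (Ward linkage, the
#' common library default), k-means, spectral clustering and DBSCAN
#' (`eps = 0.5`, `min_pts = 5`, the common library defaults).
#'
#' @param latent_means `n x d` matrix of posterior means (or a
#'   [latent_posteriors()] set, whose means are used).
#' @param algorithm One of `"agglomerative-euclidean"`, `"kmeans"`,
#'   `"spectral"`, `"dbscan"`.
#' @param n_clusters Number of clusters (ignored by DBSCAN).
#' @param eps,min_pts DBSCAN parameters.
#' @param seed Seed for the stochastic algorithms (k-means, spectral).
#' @return A [cluster_result()].
#' @export
baseline_cluster <- function(latent_means,
                             algorithm = c("agglomerative-euclidean",
                                           "kmeans", "spectral", "dbscan"),
                             n_clusters = 100, eps = 0.5, min_pts = 5,
                             seed = 1) {
  algorithm <- match.arg(algorithm)
  if (inherits(latent_means, "latent_posteriors"))
    latent_means <- latent_means$mean
  X <- as.matrix(latent_means)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  labels <- switch(
    algorithm,
    "agglomerative-euclidean" = {
      hc <- stats::hclust(stats::dist(X), method = "ward.D2")
      stats::cutree(hc, k = n_clusters)
    },
    "kmeans" = stats::kmeans(X, centers = n_clusters, nstart = 10,
                             iter.max = 100)$cluster,
    "spectral" = as.integer(
      kernlab::specc(X, centers = n_clusters)),
    "dbscan" = .dbscan(X, eps = eps, min_pts = min_pts))
  cluster_result(labels, n_clusters, method = algorithm)
}

#' Homogeneity, completeness and V-measure
#'
#' Entropy-based external clustering scores: homogeneity
#' `h = 1 - H(C|K)/H(C)` (each cluster contains members of a single
#' class), completeness `c = 1 - H(K|C)/H(K)` (members of a class fall in
#' a single cluster), and the V-measure, their harmonic mean.  All lie in
#' `[0, 1]`; degenerate zero-entropy cases follow the usual convention
#' (`h = 1` when there is a single class, `c = 1` for a single cluster).
#'
#' @param labels_true Ground-truth class labels.
#' @param labels_pred Predicted cluster labels (same length).
#' @return Named numeric vector `c(homogeneity, completeness, v_measure)`.
#' @export
clustering_metrics <- function(labels_true, labels_pred) {
  if (length(labels_true) == 0)
    stop("empty label vectors", call. = FALSE)
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(labels_true)
  tab <- table(labels_true, labels_pred)
  pc <- rowSums(tab) / n
  pk <- colSums(tab) / n
  Hc <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  Hk <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  p <- tab / n
  ## conditional entropies from the joint
  Hck <- -sum(p[p > 0] * log(p[p > 0])) - Hk   # H(C|K) = H(C,K) - H(K)
  Hkc <- -sum(p[p > 0] * log(p[p > 0])) - Hc
  h <- if (Hc > 0) 1 - Hck / Hc else 1
  cm <- if (Hk > 0) 1 - Hkc / Hk else 1
  v <- if (h + cm > 0) 2 * h * cm / (h + cm) else 0
  c(homogeneity = h, completeness = cm, v_measure = v)
}
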