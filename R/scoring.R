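#' Estimate the normal-class latent Gaussian
#'
#' Fits a full multivariate normal to the latent means of normal cells:
#' sample mean and unbiased (`n - 1`) sample covariance, plus
#' `ridge * I`.  With fewer than `d + 1` samples the covariance is
#' rank-deficient, so the estimate falls back to the diagonal of the
#' sample covariance (plus ridge).
#'
#' @param latent_means `n x d` matrix (or list of vectors) of latent
#'   means of normal-class images.
#' @param ridge Non-negative ridge added to the diagonal; `NULL` selects
#'   `1e-6 * trace(V)/d`.
#' @return A [gaussian_density()].
#' @export
fit_gaussian <- function(latent_means, ridge = NULL) {
  if (is.list(latent_means)) latent_means <- do.call(rbind, latent_means)
  latent_means <- as.matrix(latent_means)
  n <- nrow(latent_means); d <- ncol(latent_means)
  if (n < 2)
    stop("at least 2 samples are needed to estimate a covariance",
         call. = FALSE)
  mu <- colMeans(latent_means)
  V <- stats::cov(latent_means)
  if (n < d + 1) V <- diag(diag(V), nrow = d)   # diagonal fallback
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(V)) / d
  if (ridge < 0) stop("`ridge` must be non-negative", call. = FALSE)
  V <- V + diag(ridge, d)
  dens <- tryCatch(gaussian_density(mu, V), error = function(e) NULL)
  if (is.null(dens))
    stop("sample covariance is singular; supply a positive `ridge`",
         call. = FALSE)
  dens
}

#' Abnormality score: negative Gaussian log-likelihood
#'
#' Scores a latent vector against the fitted normal-class density as
#' `s(z) = -log N(z | mu, V)
#'       = 0.5 * [(z - mu)' V^{-1} (z - mu) + log det(2 pi V)]`
#' in nats.  Larger scores mean further from the normal class.
#'
#' @param z Latent vector of length `d`, or an `n x d` matrix.
#' @param density A [gaussian_density()] fitted by [fit_gaussian()].
#' @return Scalar or length-`n` numeric vector of scores.
#' @export
abnormality_score <- function(z, density) {
  stopifnot(inherits(density, "gaussian_density"))
  d <- length(density$mean)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != d)
    stop("`z` has dimension ", ncol(z), " but the density has ", d,
         call. = FALSE)
  ch <- density$chol
  dev <- sweep(z, 2, density$mean)
  ## Mahalanobis term via triangular solve against the Cholesky factor
  y <- backsolve(ch, t(dev), transpose = TRUE)
  maha <- colSums(y^2)
  logdet2pi <- d * log(2 * pi) + 2 * sum(log(diag(ch)))
  out <- 0.5 * (maha + logdet2pi)
  if (length(out) == 1) out[[1]] else out
}

#' Area under the ROC curve for abnormality scores
#'
#' Threshold-free ranking performance with the abnormal class as
#' positive; ties are handled by the midrank (Mann-Whitney) convention.
#'
#' @param scores_normal,scores_abnormal Non-empty numeric score vectors.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores_normal, scores_abnormal) {
  n0 <- length(scores_normal); n1 <- length(scores_abnormal)
  if (n0 == 0 || n1 == 0)
    stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(scores_abnormal, scores_normal))   # midranks
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Threshold-based classification metrics for abnormality scores
#'
#' Computes accuracy, F1 (abnormal = positive), sensitivity and
#' specificity at a score threshold, plus the threshold-free AUROC.  The
#' default rule picks the threshold maximising Youden's J
#' (sensitivity + specificity - 1) on a supplied validation split, or on
#' the evaluation data itself when no split is given.
#'
#' @param scores Numeric scores, larger = more abnormal.
#' @param labels Binary labels: `TRUE`/`"ABNORMAL"`-style abnormal flag;
#'   anything equal to `"NILM"`, `FALSE` or `0` is treated as normal.
#' @param threshold Fixed threshold; overrides the rule.
#' @param validation_scores,validation_labels Optional independent split
#'   on which the Youden threshold is chosen.
#' @return An object of class `"score_report"`: list with `metrics`
#'   (named numeric vector: accuracy, auroc, f1, sensitivity,
#'   specificity), `threshold` and the per-sample `scores`/`labels`.
#' @export
classwise_metrics <- function(scores, labels, threshold = NULL,
                              validation_scores = NULL,
                              validation_labels = NULL) {
  ab <- .as_abnormal(labels)
  if (length(unique(ab)) < 2)
    stop("both classes must be present to compute threshold metrics",
         call. = FALSE)
  if (is.null(threshold)) {
    vs <- validation_scores %||% scores
    vl <- if (is.null(validation_scores)) ab else
      .as_abnormal(validation_labels)
    threshold <- .youden_threshold(vs, vl)
  }
  pred <- scores > threshold
  tp <- sum(pred & ab); tn <- sum(!pred & !ab)
  fp <- sum(pred & !ab); fn <- sum(!pred & ab)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  metrics <- c(accuracy = (tp + tn) / length(ab),
               auroc = roc_auc(scores[!ab], scores[ab]),
               f1 = f1, sensitivity = sens, specificity = spec)
  structure(list(metrics = metrics, threshold = threshold,
                 scores = scores, labels = ab),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("Abnormality score report (threshold =", signif(x$threshold, 5),
      ")\n")
  print(round(x$metrics, 4))
  invisible(x)
}

.as_abnormal <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  !(labels %in% c("NILM", "normal", "NORMAL"))
}

.youden_threshold <- function(scores, abnormal) {
  cand <- sort(unique(scores))
  if (length(cand) > 1)
    cand <- (cand[-1] + cand[-length(cand)]) / 2   # midpoints
  j <- vapply(cand, function(t) {
    pred <- scores > t
    sens <- sum(pred & abnormal) / sum(abnormal)
    spec <- sum(!pred & !abnormal) / sum(!abnormal)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Cross-validated one-class evaluation
#'
#' Evaluation protocol for the one-class pipeline: the encoder is trained
#' once on a dedicated split of the normal images; the remaining normal
#' images and all abnormal images are each partitioned into `k` folds.
#' In fold `i` the normal-class Gaussian is estimated on the held-in
#' normal folds (always separate from the encoder-training images) and
#' scores of the held-out normal and abnormal fold are compared.
#'
#' @param images List of image arrays.
#' @param labels Class labels aligned with `images` (`"NILM"` = normal).
#' @param k Number of folds (>= 2).
#' @param train_fraction Fraction of normal images reserved for encoder
#'   training.
#' @param seed Seed for the fold assignment.
#' @param fit Optional pre-fitted [vae_occ()] model; when supplied, all
#'   normal images go to the Gaussian-estimation folds.
#' @param ... Passed to [vae_occ()] when `fit` is `NULL`.
#' @return List with `folds` (per-fold [classwise_metrics()] reports),
#'   `mean` and `sd` (aggregate metric vectors) and the `fit`.
#' @export
crossval_occ <- function(images, labels, k = 5, train_fraction = 0.5,
                         seed = 1, fit = NULL, ...) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  ab <- .as_abnormal(labels)
  idx_norm <- which(!ab); idx_abn <- which(ab)
  if (length(idx_abn) < k || length(idx_norm) < 2 * k)
    stop("not enough samples of each class for ", k, " folds",
         call. = FALSE)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  if (is.null(fit)) {
    n_train <- floor(length(idx_norm) * train_fraction)
    tr <- sample(idx_norm, n_train)
    est_norm <- setdiff(idx_norm, tr)
    fit <- vae_occ(images[tr], seed = seed, ...)
  } else est_norm <- idx_norm
  fold_n <- sample(rep_len(seq_len(k), length(est_norm)))
  fold_a <- sample(rep_len(seq_len(k), length(idx_abn)))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    gi <- est_norm[fold_n != f]
    ni <- est_norm[fold_n == f]
    ai <- idx_abn[fold_a == f]
    zg <- predict(fit, images[gi], type = "latent")
    dens <- fit_gaussian(zg)
    sc_n <- abnormality_score(predict(fit, images[ni], type = "latent"),
                              dens)
    sc_a <- abnormality_score(predict(fit, images[ai], type = "latent"),
                              dens)
    reports[[f]] <- classwise_metrics(
      c(sc_n, sc_a), c(rep(FALSE, length(sc_n)), rep(TRUE, length(sc_a))))
  }
  mat <- do.call(rbind, lapply(reports, function(r) r$metrics))
  list(folds = reports, mean = colMeans(mat), sd = apply(mat, 2, stats::sd),
       fit = fit)
}
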