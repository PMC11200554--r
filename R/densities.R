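#' Diagonal Gaussian latent posterior
#'
#' Container for the approximate posterior \eqn{q(z \mid x)} of one image:
#' a diagonal multivariate normal with mean vector \eqn{\mu(x)} and
#' per-dimension standard deviation \eqn{\sigma(x)}.
#'
#' @param mean Numeric vector of length `d`; must be finite.
#' @param stddev Numeric vector of length `d`; all entries strictly positive.
#' @return An object of class `"latent_posterior"` with elements `mean` and
#'   `stddev`.
#' @examples
#' latent_posterior(c(0, 1), c(1, 0.5))
#' @export
latent_posterior <- function(mean, stddev) {
  mean <- as.numeric(mean)
  stddev <- as.numeric(stddev)
  if (length(mean) != length(stddev))
    stop("`mean` and `stddev` must have the same length", call. = FALSE)
  if (!all(is.finite(mean)))
    stop("`mean` must be finite", call. = FALSE)
  if (!all(is.finite(stddev)) || any(stddev <= 0))
    stop("`stddev` must be strictly positive", call. = FALSE)
  structure(list(mean = mean, stddev = stddev), class = "latent_posterior")
}

#' @export
print.latent_posterior <- function(x, ...) {
  cat("Diagonal Gaussian posterior, d =", length(x$mean), "\n")
  cat("  mean:  ", paste(signif(utils::head(x$mean, 6), 4), collapse = " "),
      if (length(x$mean) > 6) "...\n" else "\n")
  cat("  stddev:", paste(signif(utils::head(x$stddev, 6), 4), collapse = " "),
      if (length(x$stddev) > 6) "...\n" else "\n")
  invisible(x)
}

#' Full multivariate normal density
#'
#' Container for a multivariate normal \eqn{N(\mu, V)} with full covariance,
#' used both as the normal-class density estimated from latents of normal
#' cells and as an argument of the cross-entropy-based referenced
#' statistical distance.
#'
#' @param mean Numeric mean vector of length `d`.
#' @param covariance `d x d` symmetric positive-definite matrix.
#' @return An object of class `"gaussian_density"`.
#' @examples
#' gaussian_density(c(0, 0), diag(2))
#' @export
gaussian_density <- function(mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  d <- length(mean)
  if (!all(dim(covariance) == c(d, d)))
    stop("`covariance` must be a ", d, " x ", d, " matrix", call. = FALSE)
  if (max(abs(covariance - t(covariance))) > 1e-8 * (1 + max(abs(covariance))))
    stop("`covariance` must be symmetric", call. = FALSE)
  covariance <- (covariance + t(covariance)) / 2
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch))
    stop("`covariance` must be positive definite; ",
         "consider adding a ridge term", call. = FALSE)
  structure(list(mean = mean, covariance = covariance, chol = ch),
            class = "gaussian_density")
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat("Multivariate normal density, d =", length(x$mean), "\n")
  cat("  mean:     ", paste(signif(utils::head(x$mean, 6), 4), collapse = " "),
      if (length(x$mean) > 6) "...\n" else "\n")
  cat("  log|V|:   ", signif(2 * sum(log(diag(x$chol))), 6), "\n")
  invisible(x)
}

#' Coerce a density object to a full multivariate normal
#'
#' A `latent_posterior` (diagonal Gaussian) is promoted to a
#' `gaussian_density` with diagonal covariance; a `gaussian_density` is
#' returned unchanged.
#'
#' @param x A `latent_posterior` or `gaussian_density`.
#' @return A `gaussian_density`.
#' @export
as_gaussian_density <- function(x) {
  if (inherits(x, "gaussian_density")) return(x)
  if (inherits(x, "latent_posterior")) {
    d <- length(x$mean)
    return(gaussian_density(x$mean, diag(x$stddev^2, nrow = d)))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to a gaussian_density", call. = FALSE)
}

#' Set of diagonal Gaussian posteriors
#'
#' Compact matrix representation for a batch of per-image latent
#' posteriors: one row per image in both the mean and stddev matrices.
#' This is what [encode()] and [generate_latent_fixture()] return.
#'
#' @param mean `n x d` matrix of posterior means.
#' @param stddev `n x d` matrix of strictly positive posterior standard
#'   deviations.
#' @return An object of class `"latent_posteriors"`.
#' @export
latent_posteriors <- function(mean, stddev) {
  mean <- as.matrix(mean)
  stddev <- as.matrix(stddev)
  if (!all(dim(mean) == dim(stddev)))
    stop("`mean` and `stddev` must have identical dimensions", call. = FALSE)
  if (nrow(mean) > 0 && (!all(is.finite(stddev)) || any(stddev <= 0)))
    stop("`stddev` must be strictly positive", call. = FALSE)
  structure(list(mean = mean, stddev = stddev), class = "latent_posteriors")
}

#' @export
print.latent_posteriors <- function(x, ...) {
  cat("Set of", nrow(x$mean), "diagonal Gaussian posteriors, d =",
      ncol(x$mean), "\n")
  invisible(x)
}

#' @export
length.latent_posteriors <- function(x) nrow(x$mean)

#' Extract one posterior from a set
#'
#' @param x A `latent_posteriors` object.
#' @param i Row index.
#' @param ... Unused.
#' @return A `latent_posterior`.
#' @export
`[[.latent_posteriors` <- function(x, i, ...) {
  latent_posterior(x$mean[i, ], x$stddev[i, ])
}

## Internal: accept latent_posteriors, a list of posteriors/densities with
## diagonal covariance, and return list(mean = n x d, var = n x d).
.diag_gaussians <- function(x) {
  if (inherits(x, "latent_posteriors"))
    return(list(mean = x$mean, var = x$stddev^2))
  if (inherits(x, "latent_posterior"))
    return(list(mean = matrix(x$mean, 1), var = matrix(x$stddev^2, 1)))
  if (is.list(x)) {
    ms <- lapply(x, function(e) {
      if (inherits(e, "latent_posterior")) return(e$mean)
      if (inherits(e, "gaussian_density")) return(e$mean)
      stop("unsupported element in density list", call. = FALSE)
    })
    vs <- lapply(x, function(e) {
      if (inherits(e, "latent_posterior")) return(e$stddev^2)
      v <- e$covariance
      if (max(abs(v - diag(diag(v)))) > 1e-12)
        stop("list elements must have diagonal covariance for the ",
             "vectorised path", call. = FALSE)
      diag(v)
    })
    return(list(mean = do.call(rbind, ms), var = do.call(rbind, vs)))
  }
  stop("expected latent_posteriors or a list of densities", call. = FALSE)
}
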