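#' Latent traversal grid
#'
#' Decodes images along an even grid in one latent dimension, holding all
#' other coordinates at the centre of the (non-augmented) normal-class
#' latent distribution.  The grid runs from
#' `center[dim] - span * stddevs[dim]` to `center[dim] + span * stddevs[dim]`
#' in `steps` points inclusive of both endpoints, so with the defaults
#' (10 steps, span 4) the first value sits at -4 standard deviations and
#' the last at +4.
#'
#' @param state A fitted [vae_occ()] model (or internal state).
#' @param center Length-`d` centre vector (mean of normal-class latent
#'   means); defaults to the fitted model's Gaussian mean.
#' @param stddevs Length-`d` per-dimension standard deviations of the
#'   normal-class latent means; defaults derived from the fitted model.
#' @param dim Latent dimension to traverse (1-based).
#' @param steps Number of grid points.
#' @param span Half-width of the grid in standard deviations.
#' @return Object of class `"traversal_grid"`: list with `dim`, `values`
#'   (the step values) and `images` (decoded arrays).  Has a `plot`
#'   method.
#' @export
latent_traversal <- function(state, center = NULL, stddevs = NULL, dim,
                             steps = 10, span = 4) {
  st <- .as_state(state)
  d <- st$dims$d
  if (is.null(center) && inherits(state, "vae_occ"))
    center <- state$density$mean
  if (is.null(stddevs) && inherits(state, "vae_occ"))
    stddevs <- sqrt(diag(state$density$covariance))
  if (is.null(center) || is.null(stddevs))
    stop("`center` and `stddevs` are required unless a fitted vae_occ ",
         "model is supplied", call. = FALSE)
  if (dim < 1 || dim > d)
    stop("`dim` must lie in 1..", d, call. = FALSE)
  if (length(center) != d || length(stddevs) != d)
    stop("`center` and `stddevs` must have length ", d, call. = FALSE)
  values <- center[dim] + seq(-span, span, length.out = steps) *
    stddevs[dim]
  Z <- matrix(rep(center, each = steps), steps, d)
  Z[, dim] <- values
  structure(list(dim = dim, values = values, images = decode(Z, st)),
            class = "traversal_grid")
}

#' @export
print.traversal_grid <- function(x, ...) {
  cat("Latent traversal of dimension", x$dim, "in", length(x$values),
      "steps over [", signif(x$values[1], 4), ",",
      signif(x$values[length(x$values)], 4), "]\n")
  invisible(x)
}

#' Plot a latent traversal as an image strip
#'
#' @param x A `traversal_grid` from [latent_traversal()].
#' @param add_label Annotate the strip with the dimension index.
#' @param ... Unused.
#' @export
plot.traversal_grid <- function(x, add_label = FALSE, ...) {
  k <- length(x$images)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, k), ylim = c(0, 1), asp = 1)
  for (i in seq_len(k)) {
    img <- x$images[[i]]
    graphics::rasterImage(grDevices::as.raster(img), i - 1, 0, i, 1,
                          interpolate = FALSE)
  }
  if (add_label)
    graphics::mtext(paste0("z", x$dim), side = 2, line = 0.2, las = 1,
                    cex = 0.8)
  invisible(x)
}

#' Per-class pairwise latent density summaries
#'
#' For every pair of latent dimensions and every (merged) class, a 2-D
#' kernel density estimate of the latent means on a regular grid — the
#' numerical content behind pairwise latent contour plots.  Raw labels
#' can be merged for display (e.g. LSIL with ASC-US and HSIL with ASC-H,
#' the usual low/high-grade grouping).
#'
#' @param latent_means `n x d` matrix of latent means.
#' @param class_labels Character vector of raw labels, length `n`.
#' @param merge_map Named character vector mapping raw labels to display
#'   groups; unlisted labels keep their own name.
#' @param gridsize Number of grid points per axis.
#' @param span Grid half-width in standard deviations around the mean of
#'   each dimension (all classes pooled).
#' @return Nested list: `result[[group]][[paste(i, j)]]` is a list with
#'   `x`, `y`, `z` (as from [MASS::kde2d()]) and the dimension pair.
#'   Groups with fewer than 2 samples are skipped with a warning.
#' @export
pairwise_density_summary <- function(latent_means, class_labels,
                                     merge_map = NULL, gridsize = 100,
                                     span = 4) {
  X <- as.matrix(latent_means)
  d <- ncol(X)
  groups <- as.character(class_labels)
  if (!is.null(merge_map)) {
    mapped <- merge_map[groups]
    groups <- ifelse(is.na(mapped), groups, mapped)
  }
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  out <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    if (sum(sel) < 2) {
      warning("group '", g, "' has fewer than 2 samples; skipped")
      next
    }
    Xg <- X[sel, , drop = FALSE]
    pairs <- list()
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
      lims <- c(ctr[i] - span * sds[i], ctr[i] + span * sds[i],
                ctr[j] - span * sds[j], ctr[j] + span * sds[j])
      hx <- MASS::bandwidth.nrd(Xg[, i])
      hy <- MASS::bandwidth.nrd(Xg[, j])
      if (hx <= 0) hx <- max(stats::sd(Xg[, i]), 1e-3)
      if (hy <= 0) hy <- max(stats::sd(Xg[, j]), 1e-3)
      kd <- MASS::kde2d(Xg[, i], Xg[, j], h = c(hx, hy), n = gridsize,
                        lims = lims)
      pairs[[paste(i, j)]] <- list(dims = c(i, j), x = kd$x, y = kd$y,
                                   z = kd$z)
    }
    out[[g]] <- pairs
  }
  out
}

#' Query images in the same cluster as a given sample
#'
#' Returns the co-cluster members of a query sample ordered by increasing
#' dissimilarity to it, together with the class composition of the
#' cluster — the retrieval step used to inspect images similar to a cell
#' under review.
#'
#' @param sample_index Index of the query sample in the clustering.
#' @param cluster_result A [cluster_result()] that retains its
#'   dissimilarity matrix (e.g. from [agglomerative_crsd()]).
#' @param annotations Optional data frame aligned with the clustered
#'   samples; its rows are attached to the result.
#' @return List with `members` (data frame: index, dissimilarity, plus
#'   annotation columns; the query itself excluded) and `composition`
#'   (class counts within the cluster, when annotations carry a `class`
#'   column).
#' @export
query_cluster <- function(sample_index, cluster_result,
                          annotations = NULL) {
  stopifnot(inherits(cluster_result, "cluster_result"))
  n <- length(cluster_result$labels)
  if (sample_index < 1 || sample_index > n)
    stop("`sample_index` out of range 1..", n, call. = FALSE)
  if (is.null(cluster_result$dissimilarity))
    stop("the cluster result does not retain a dissimilarity matrix",
         call. = FALSE)
  lab <- cluster_result$labels[sample_index]
  members <- setdiff(which(cluster_result$labels == lab), sample_index)
  dis <- cluster_result$dissimilarity[sample_index, members]
  ord <- order(dis)
  res <- data.frame(index = members[ord], dissimilarity = dis[ord])
  composition <- NULL
  if (!is.null(annotations)) {
    res <- cbind(res, annotations[members[ord], , drop = FALSE])
    if ("class" %in% names(annotations)) {
      allmem <- which(cluster_result$labels == lab)
      composition <- table(annotations$class[allmem])
    }
  }
  list(members = res, composition = composition)
}
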