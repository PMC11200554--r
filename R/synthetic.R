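#' Cell phenotype for the synthetic crop generator
#'
#' Describes a single rendered cell: an elliptical nucleus on a cytoplasm
#' disc over a white background, mimicking the appearance of a stained
#' cervical cell crop.  Abnormal phenotypes default to enlarged, darker,
#' more eccentric nuclei — the hyperchromatic enlarged-nucleus signal a
#' cytologist looks for.
#'
#' @param nucleus_radius Nucleus size in pixels (geometric mean of the
#'   ellipse semi-axes).  Must be at least 1 and less than half the image
#'   side when rendered.
#' @param nucleus_eccentricity Eccentricity of the nucleus ellipse, in
#'   `[0, 1)`; 0 is a circle.
#' @param nucleus_intensity Nucleus gray level in `[0, 1]` (lower = darker,
#'   i.e. more hyperchromatic).
#' @param cytoplasm_hue Cytoplasm hue in degrees, `[0, 360)`.
#' @param brightness Multiplicative brightness factor, `> 0`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (gray levels), `>= 0`.
#' @param is_abnormal Logical class flag carried through to annotations.
#' @param nucleus_angle Orientation of the nucleus major axis in degrees.
#' @return An object of class `"cell_phenotype"`.
#' @examples
#' ph <- cell_phenotype(nucleus_radius = 12)
#' img <- generate_cell_image(ph, image_size = 128, seed = 1)
#' @export
cell_phenotype <- function(nucleus_radius = 10,
                           nucleus_eccentricity = 0.3,
                           nucleus_intensity = 0.45,
                           cytoplasm_hue = 260,
                           brightness = 1,
                           noise_sd = 0.02,
                           is_abnormal = FALSE,
                           nucleus_angle = 0) {
  if (!is.finite(nucleus_radius) || nucleus_radius < 1)
    stop("`nucleus_radius` must be >= 1 pixel", call. = FALSE)
  if (nucleus_eccentricity < 0 || nucleus_eccentricity >= 1)
    stop("`nucleus_eccentricity` must lie in [0, 1)", call. = FALSE)
  if (nucleus_intensity < 0 || nucleus_intensity > 1)
    stop("`nucleus_intensity` must lie in [0, 1]", call. = FALSE)
  if (cytoplasm_hue < 0 || cytoplasm_hue >= 360)
    stop("`cytoplasm_hue` must lie in [0, 360) degrees", call. = FALSE)
  if (brightness <= 0)
    stop("`brightness` must be positive", call. = FALSE)
  if (noise_sd < 0)
    stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(nucleus_radius = nucleus_radius,
                 nucleus_eccentricity = nucleus_eccentricity,
                 nucleus_intensity = nucleus_intensity,
                 cytoplasm_hue = cytoplasm_hue,
                 brightness = brightness,
                 noise_sd = noise_sd,
                 is_abnormal = isTRUE(is_abnormal),
                 nucleus_angle = nucleus_angle),
            class = "cell_phenotype")
}

#' Render one synthetic cell-crop image
#'
#' Draws an anti-aliased filled nucleus ellipse on a cytoplasm disc over a
#' white background, applies the multiplicative brightness factor, adds
#' Gaussian pixel noise and clips to `[0, 1]`.  Deterministic given `seed`.
#'
#' @param phenotype A [cell_phenotype()].
#' @param image_size Side of the square output image in pixels.
#' @param seed Integer seed for the noise; the render itself is
#'   deterministic.
#' @param center Length-2 numeric, 0-based `(x, y)` cell-centre position;
#'   defaults to the image centre.
#' @param cytoplasm_radius Radius of the cytoplasm disc in pixels; default
#'   40\% of the image side so a 64-pixel window centred on the nucleus
#'   stays inside the cytoplasm.
#' @return `image_size x image_size x 3` array with values in `[0, 1]`,
#'   indexed `[row, col, channel]`.
#' @export
generate_cell_image <- function(phenotype, image_size = 256, seed = 1,
                                center = NULL,
                                cytoplasm_radius = 0.4 * image_size) {
  stopifnot(inherits(phenotype, "cell_phenotype"))
  if (phenotype$nucleus_radius >= image_size / 2)
    stop("`nucleus_radius` must be less than half the image side",
         call. = FALSE)
  if (is.null(center)) center <- c(image_size, image_size) / 2
  cx <- center[1]; cy <- center[2]

  ## 0-based pixel-centre coordinates
  xs <- matrix(rep(seq_len(image_size) - 1, each = image_size),
               nrow = image_size)            # [row, col] -> col index (x)
  ys <- matrix(rep(seq_len(image_size) - 1, times = image_size),
               nrow = image_size)            # [row, col] -> row index (y)

  ## cytoplasm disc coverage, ~1 px soft edge for anti-aliasing
  rad <- sqrt((xs - cx)^2 + (ys - cy)^2)
  cyto_cov <- pmin(pmax(cytoplasm_radius + 0.5 - rad, 0), 1)

  ## nucleus ellipse: semi-axes with geometric mean = nucleus_radius and
  ## axis ratio implied by the eccentricity; rotated by nucleus_angle
  ecc <- phenotype$nucleus_eccentricity
  ratio <- sqrt(1 - ecc^2)                   # b / a
  a <- phenotype$nucleus_radius / sqrt(ratio)
  b <- phenotype$nucleus_radius * sqrt(ratio)
  th <- phenotype$nucleus_angle * pi / 180
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  ## signed distance approximation for a soft ellipse edge
  q <- sqrt((u / a)^2 + (v / b)^2)
  nuc_cov <- pmin(pmax((1 - q) * min(a, b) + 0.5, 0), 1)

  cyto_rgb <- grDevices::col2rgb(
    grDevices::hsv(phenotype$cytoplasm_hue / 360, 0.35, 0.92))[, 1] / 255
  ## hyperchromatic nucleus: dark violet tint scaled by intensity
  nuc_rgb <- phenotype$nucleus_intensity * c(0.85, 0.7, 1)

  img <- array(1, dim = c(image_size, image_size, 3))  # white background
  for (ch in 1:3) {
    plane <- 1 * (1 - cyto_cov) + cyto_rgb[ch] * cyto_cov
    plane <- plane * (1 - nuc_cov) + nuc_rgb[ch] * nuc_cov
    img[, , ch] <- plane
  }
  img <- img * phenotype$brightness
  if (phenotype$noise_sd > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    img <- img + array(stats::rnorm(length(img), 0, phenotype$noise_sd),
                       dim = dim(img))
  }
  pmin(pmax(img, 0), 1)
}

## Save/restore the global RNG state so seeded generators do not disturb
## the caller's RNG stream.
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a synthetic two-class cell population
#'
#' Defines how many normal and abnormal cells to draw and the sampling
#' distribution of each phenotype field per class.  The abnormal class
#' defaults shift the nucleus radius by a factor 1.5, darken the nucleus
#' by 0.2 gray levels and add 0.2 to the eccentricity relative to normal —
#' the enlarged, hyperchromatic, irregular nucleus that signals cytologic
#' abnormality.
#'
#' @param n_normal,n_abnormal Non-negative class counts.
#' @param image_size Side of the generated crops (pixels).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param normal,abnormal Named lists overriding the per-class phenotype
#'   sampling parameters.  Recognised entries: `radius_mean`, `radius_sd`,
#'   `intensity_mean`, `intensity_sd`, `ecc_mean`, `ecc_sd`, `hue_range`
#'   (length 2, degrees), `brightness_sd`, `noise_sd`.
#' @param center_jitter Maximum uniform jitter (pixels) of the cell centre
#'   around the image centre; the realised centre is recorded in the
#'   annotation table.
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(n_normal, n_abnormal, image_size = 256, seed = 1,
                            normal = list(), abnormal = list(),
                            center_jitter = 0) {
  if (n_normal < 0 || n_abnormal < 0)
    stop("class counts must be non-negative", call. = FALSE)
  norm_def <- list(radius_mean = 10, radius_sd = 1.5,
                   intensity_mean = 0.45, intensity_sd = 0.05,
                   ecc_mean = 0.3, ecc_sd = 0.1,
                   hue_range = c(180, 330),
                   brightness_sd = 0.05, noise_sd = 0.02)
  abn_def <- norm_def
  abn_def$radius_mean <- norm_def$radius_mean * 1.5
  abn_def$radius_sd <- norm_def$radius_sd * 1.5
  abn_def$intensity_mean <- norm_def$intensity_mean - 0.2
  abn_def$ecc_mean <- norm_def$ecc_mean + 0.2
  norm_def[names(normal)] <- normal
  abn_def[names(abnormal)] <- abnormal
  structure(list(n_normal = n_normal, n_abnormal = n_abnormal,
                 image_size = image_size, seed = seed,
                 normal = norm_def, abnormal = abn_def,
                 center_jitter = center_jitter),
            class = "population_spec")
}

.sample_phenotype <- function(par, abnormal, image_size) {
  r <- stats::rnorm(1, par$radius_mean, par$radius_sd)
  r <- min(max(r, 3), image_size / 2 - 2)
  e <- min(max(stats::rnorm(1, par$ecc_mean, par$ecc_sd), 0), 0.95)
  it <- min(max(stats::rnorm(1, par$intensity_mean, par$intensity_sd), 0), 1)
  hue <- stats::runif(1, par$hue_range[1], par$hue_range[2]) %% 360
  br <- max(stats::rnorm(1, 1, par$brightness_sd), 0.5)
  ang <- stats::runif(1, 0, 180)
  cell_phenotype(nucleus_radius = r, nucleus_eccentricity = e,
                 nucleus_intensity = it, cytoplasm_hue = hue,
                 brightness = br, noise_sd = par$noise_sd,
                 is_abnormal = abnormal, nucleus_angle = ang)
}

#' Generate a synthetic cell population with annotations
#'
#' Draws phenotypes per class from the distributions in a
#' [population_spec()], renders one crop per cell, and builds a CRIC-style
#' annotation table (`image_id`, `center_x`, `center_y`, `class`) with
#' labels `"NILM"` for normals and `"ABNORMAL"` otherwise.  Optionally
#' writes crops as PNG files plus the annotation CSV.
#'
#' @param spec A [population_spec()].
#' @param dir Optional directory; when given, crops are written as
#'   `<image_id>.png` and the table as `annotations.csv`.
#' @return List with `images` (list of arrays), `annotations` (data frame)
#'   and `phenotypes` (list of the sampled [cell_phenotype()] objects).
#' @export
generate_population <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(spec$seed)
  n <- spec$n_normal + spec$n_abnormal
  cls <- c(rep(FALSE, spec$n_normal), rep(TRUE, spec$n_abnormal))
  images <- vector("list", n)
  phenos <- vector("list", n)
  ann <- data.frame(image_id = character(n), center_x = numeric(n),
                    center_y = numeric(n), class = character(n),
                    stringsAsFactors = FALSE)
  half <- spec$image_size / 2
  for (i in seq_len(n)) {
    par <- if (cls[i]) spec$abnormal else spec$normal
    ph <- .sample_phenotype(par, cls[i], spec$image_size)
    jit <- if (spec$center_jitter > 0)
      stats::runif(2, -spec$center_jitter, spec$center_jitter) else c(0, 0)
    ctr <- c(half, half) + jit
    img_seed <- sample.int(.Machine$integer.max, 1)
    images[[i]] <- generate_cell_image(ph, spec$image_size, seed = img_seed,
                                       center = ctr)
    phenos[[i]] <- ph
    ann$image_id[i] <- sprintf("cell_%04d", i)
    ann$center_x[i] <- ctr[1]
    ann$center_y[i] <- ctr[2]
    ann$class[i] <- if (cls[i]) "ABNORMAL" else "NILM"
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      png::writePNG(images[[i]],
                    file.path(dir, paste0(ann$image_id[i], ".png")))
    utils::write.csv(ann, file.path(dir, "annotations.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(images = images, annotations = ann, phenotypes = phenos)
}

#' Generate a fixture of diagonal Gaussian latent posteriors
#'
#' Samples `n` posteriors from a mixture of labelled components: posterior
#' `i` assigned to component `k` has mean drawn from
#' `N(component_means[[k]], diag(component_stddevs[[k]]^2))` and posterior
#' standard deviation equal to `component_stddevs[[k]]`.  Used as ground
#' truth for clustering on latent posterior distributions.
#'
#' @param n Number of posteriors.
#' @param dim Latent dimension.
#' @param component_means List of length-`dim` mean vectors, one per
#'   component.
#' @param component_stddevs List of length-`dim` positive stddev vectors.
#' @param assignment Integer vector of length `n` with values in
#'   `1..K`, or `NULL` to assign components uniformly at random.
#' @param seed Integer seed.
#' @return List with `posteriors` (a [latent_posteriors()] set) and
#'   `labels` (integer component assignment).
#' @export
generate_latent_fixture <- function(n, dim, component_means,
                                    component_stddevs, assignment = NULL,
                                    seed = 1) {
  K <- length(component_means)
  if (length(component_stddevs) != K)
    stop("`component_means` and `component_stddevs` must have equal length",
         call. = FALSE)
  for (k in seq_len(K)) {
    if (length(component_means[[k]]) != dim ||
        length(component_stddevs[[k]]) != dim)
      stop("component ", k, " is not of dimension ", dim, call. = FALSE)
    if (any(component_stddevs[[k]] <= 0))
      stop("component stddevs must be strictly positive", call. = FALSE)
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  if (is.null(assignment)) assignment <- sample.int(K, n, replace = TRUE)
  if (length(assignment) != n || any(assignment < 1 | assignment > K))
    stop("`assignment` must have length n with values in 1..K",
         call. = FALSE)
  mu <- matrix(0, n, dim); sdv <- matrix(0, n, dim)
  for (i in seq_len(n)) {
    k <- assignment[i]
    mu[i, ] <- component_means[[k]] +
      component_stddevs[[k]] * stats::rnorm(dim)
    sdv[i, ] <- component_stddevs[[k]]
  }
  list(posteriors = latent_posteriors(mu, sdv),
       labels = as.integer(assignment))
}
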