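test_that("boundary filter keeps exactly the interior annotations", {
  rec <- data.frame(image_id = c("a", "b"),
                    center_x = c(64, 500), center_y = c(500, 500),
                    class = "NILM")
  out <- filter_boundary(rec, 1024, 1024, margin = 128)
  expect_identical(out$image_id, "b")     # 64 < 128: removed; 500 kept

  ## exhaustive agreement with the half-open rule on random records
  set.seed(1)
  rec <- data.frame(image_id = sprintf("r%03d", 1:100),
                    center_x = runif(100, 0, 1024),
                    center_y = runif(100, 0, 1024), class = "NILM")
  out <- filter_boundary(rec, 1024, 1024, 128)
  manual <- rec[rec$center_x >= 128 & rec$center_x < 896 &
                  rec$center_y >= 128 & rec$center_y < 896, ]
  expect_identical(out, manual)
  ## keep fraction near (768/1024)^2 = 0.5625, binomial 3-sigma band
  expect_lt(abs(nrow(out) / 100 - 0.5625),
            3 * sqrt(0.5625 * 0.4375 / 100))
})

test_that("boundary filter is idempotent and warns on excessive margins", {
  set.seed(2)
  rec <- data.frame(image_id = sprintf("r%02d", 1:50),
                    center_x = runif(50, 0, 512),
                    center_y = runif(50, 0, 512), class = "NILM")
  once <- filter_boundary(rec, 512, 512, 128)
  twice <- filter_boundary(once, 512, 512, 128)
  expect_identical(once, twice)
  expect_warning(out <- filter_boundary(rec, 512, 512, 256),
                 "no admissible region")
  expect_equal(nrow(out), 0)
})

test_that("crop extraction is centred, exact, and path-independent", {
  ## constant image -> constant crop
  img <- array(0.37, c(300, 300, 3))
  crop <- extract_crop(img, list(center_x = 150, center_y = 150))
  expect_equal(dim(crop), c(64, 64, 3))
  expect_true(all(crop == 0.37))

  ## two-path equivalence: 256-crop then centred 64 equals direct 64
  set.seed(3)
  big <- array(runif(600 * 600 * 3), c(600, 600, 3))
  rec <- list(center_x = 300, center_y = 280)
  direct <- extract_crop(big, rec, crop_size = 256, model_size = 64)
  mid <- extract_crop(big, rec, crop_size = 256, model_size = 256)
  two_step <- extract_crop(mid, list(center_x = 128, center_y = 128),
                           crop_size = 256, model_size = 64)
  expect_identical(direct, two_step)

  ## crop centred on a rendered nucleus: dark-pixel centroid near centre
  ph <- cell_phenotype(nucleus_radius = 20, noise_sd = 0)
  cell <- generate_cell_image(ph, image_size = 300, seed = 1,
                              center = c(163, 140))
  crop <- extract_crop(cell, list(center_x = 163, center_y = 140))
  lum <- (crop[, , 1] + crop[, , 2] + crop[, , 3]) / 3
  dark <- which(lum < 0.5, arr.ind = TRUE)
  centroid <- colMeans(dark)                      # (row, col), 1-based
  expect_lt(abs(centroid[1] - 1 - 32), 1)         # 0-based centre = 32
  expect_lt(abs(centroid[2] - 1 - 32), 1)

  expect_error(extract_crop(img, list(center_x = 10, center_y = 150)),
               "bounds")
})

test_that("augmentation modes honour their contracts", {
  set.seed(4)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(augment(img, augmentation_mode("none"), seed = 1), img)

  ## fab collapsed to the identity transform
  ident <- augmentation_mode("fab", rotation = c(0, 0), translation = 0,
                             brightness = c(1, 1), flip_prob = 0)
  expect_equal(augment(img, ident, seed = 1), img, tolerance = 1e-12)

  ## determinism
  fab <- augmentation_mode("fab")
  expect_identical(augment(img, fab, seed = 5), augment(img, fab, seed = 5))
  expect_false(identical(augment(img, fab, seed = 5),
                         augment(img, fab, seed = 6)))

  expect_error(augmentation_mode("warp"))
  expect_error(augment(img, list(mode = "fa")), "augmentation_mode")
})

test_that("geometry-only augmentation preserves the intensity histogram
           of a rotationally symmetric image", {
  ## radially symmetric smooth disc: any rotation/flip about the centre
  ## leaves the pixel histogram unchanged up to interpolation error
  n <- 96
  xs <- matrix(rep(0:(n - 1), each = n), n) - (n - 1) / 2
  ys <- matrix(rep(0:(n - 1), times = n), n) - (n - 1) / 2
  r <- sqrt(xs^2 + ys^2)
  ## support kept 24 px inside the frame so reflection padding only ever
  ## mirrors zeros into the region the rotation samples
  plane <- pmax(0, 1 - r / 24)
  img <- array(rep(plane, 3), c(n, n, 3))
  fa <- augmentation_mode("fa", translation = 0)
  br <- seq(0, 1, length.out = 101)
  for (s in 1:4) {
    out <- augment(img, fa, seed = s)
    h1 <- hist(img, breaks = br, plot = FALSE)$counts
    h2 <- hist(out, breaks = br, plot = FALSE)$counts
    expect_lt(sum(abs(h1 - h2)) / sum(h1), 0.02)
  }
})
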