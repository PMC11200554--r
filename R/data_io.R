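#' Read a CRIC-style annotation table
#'
#' Expects a CSV with header `image_id,center_x,center_y,class`.
#' Coordinates are 0-based with `center_x` the column and `center_y` the
#' row of the annotated cell centre on the source image.
#'
#' @param path CSV file path.
#' @return Data frame with the four annotation columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "center_x", "center_y", "class")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ann[, need]
}

#' Drop annotations too close to the image boundary
#'
#' Keeps exactly the records whose centre satisfies
#' `margin <= center_x < image_width - margin` and
#' `margin <= center_y < image_height - margin`, preserving order.  With
#' the default margin of 128 pixels this guarantees that a full 256-pixel
#' window around the centre exists.
#'
#' @param records Annotation data frame (see [read_annotations()]).
#' @param image_width,image_height Source image size in pixels.
#' @param margin Exclusion margin in pixels (non-negative).
#' @return The filtered data frame.
#' @export
filter_boundary <- function(records, image_width, image_height,
                            margin = 128) {
  if (margin < 0) stop("`margin` must be non-negative", call. = FALSE)
  if (margin >= image_width / 2 || margin >= image_height / 2) {
    warning("margin of ", margin, " px leaves no admissible region in a ",
            image_width, " x ", image_height, " image; returning no records")
    return(records[integer(0), , drop = FALSE])
  }
  keep <- records$center_x >= margin & records$center_x < image_width - margin &
    records$center_y >= margin & records$center_y < image_height - margin
  records[keep, , drop = FALSE]
}

#' Extract the model-input window around an annotated cell
#'
#' Returns the `model_size` window centred on `(center_x, center_y)`.
#' Taking a `crop_size` crop first and then the centred `model_size` crop
#' yields the same pixels by construction; the direct window is computed.
#' For even sizes the window covers columns
#' `center_x - model_size/2 .. center_x + model_size/2 - 1` (0-based), and
#' likewise for rows.
#'
#' @param image `[row, col, channel]` array in `[0, 1]`.
#' @param record One-row annotation data frame, or a list with `center_x`
#'   and `center_y`.
#' @param crop_size Size of the conceptual intermediate crop (pixels).
#' @param model_size Side of the returned window (pixels).
#' @return `model_size x model_size x 3` array.
#' @export
extract_crop <- function(image, record, crop_size = 256, model_size = 64) {
  if (model_size > crop_size)
    stop("`model_size` must not exceed `crop_size`", call. = FALSE)
  cx <- round(record$center_x[1]); cy <- round(record$center_y[1])
  h <- dim(image)[1]; w <- dim(image)[2]
  half <- model_size %/% 2
  cols <- (cx - half):(cx + half - 1) + 1   # 0-based -> 1-based
  rows <- (cy - half):(cy + half - 1) + 1
  if (min(rows) < 1 || max(rows) > h || min(cols) < 1 || max(cols) > w)
    stop("crop window [", min(cols) - 1, ", ", max(cols) - 1, "] x [",
         min(rows) - 1, ", ", max(rows) - 1,
         "] exceeds image bounds ", w, " x ", h, call. = FALSE)
  image[rows, cols, , drop = FALSE]
}

#' Image augmentation mode
#'
#' The three augmentation regimes used when training on annotated cells:
#' `"none"` (identity), `"fa"` (random horizontal/vertical flips, rotation
#' and translation — geometry only, pixel intensities untouched) and
#' `"fab"` (`"fa"` plus a multiplicative brightness factor).
#'
#' @param mode One of `"none"`, `"fa"`, `"fab"`.
#' @param rotation Length-2 range of rotation angles in degrees.
#' @param translation Maximum translation as a fraction of the image side.
#' @param brightness Length-2 range of the multiplicative brightness
#'   factor (only used by `"fab"`).
#' @param flip_prob Probability of a flip along each axis.
#' @return An object of class `"augmentation_mode"`.
#' @export
augmentation_mode <- function(mode = c("none", "fa", "fab"),
                              rotation = c(0, 360), translation = 0.1,
                              brightness = c(0.8, 1.2), flip_prob = 0.5) {
  mode <- match.arg(mode)
  structure(list(mode = mode, rotation = rotation,
                 translation = translation, brightness = brightness,
                 flip_prob = flip_prob),
            class = "augmentation_mode")
}

## reflect-pad an image by `pad` pixels on every side
.pad_reflect <- function(img, pad) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ridx <- c(rev(seq_len(pad) + 1), seq_len(h), h - seq_len(pad))
  cidx <- c(rev(seq_len(pad) + 1), seq_len(w), w - seq_len(pad))
  img[ridx, cidx, , drop = FALSE]
}

## geometric transform shared by augment() and the training loop: flips,
## rotation about the image centre and translation composed into a single
## affine map with bilinear interpolation (one resampling pass, so flips
## and axis-aligned rotations stay exact on the pixel grid).
.augment_geometry <- function(img, flip_h, flip_v, angle, tx, ty) {
  h <- dim(img)[1]; w <- dim(img)[2]
  e <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Fl <- diag(c(if (flip_h) -1 else 1, if (flip_v) -1 else 1))
  A <- R %*% Fl
  ctr <- c(w, h) / 2                      # continuous (x, y) centre
  off <- ctr + c(tx, ty) - A %*% ctr
  m <- rbind(t(A), as.numeric(off))
  out <- EBImage::affine(e, m, filter = "bilinear",
                         output.dim = c(w, h), bg.col = "white")
  aperm(as.array(out), c(2, 1, 3))
}

.draw_augment_params <- function(mode) {
  flip_h <- stats::runif(1) < mode$flip_prob
  flip_v <- stats::runif(1) < mode$flip_prob
  angle <- stats::runif(1, mode$rotation[1], mode$rotation[2])
  bfac <- if (mode$mode == "fab")
    stats::runif(1, mode$brightness[1], mode$brightness[2]) else 1
  list(flip_h = flip_h, flip_v = flip_v, angle = angle, bfac = bfac)
}

#' Apply a random augmentation to one image
#'
#' `"none"` returns the input unchanged.  `"fa"` applies random flips, a
#' rotation about the image centre and a translation, with bilinear
#' interpolation; the image is reflection-padded before the geometric
#' transform so no artificial background enters the frame.  `"fab"`
#' additionally multiplies by a random brightness factor.  Output is
#' clipped to `[0, 1]` and deterministic given `seed`.
#'
#' @param image `[row, col, channel]` array in `[0, 1]`.
#' @param mode An [augmentation_mode()].
#' @param seed Integer seed.
#' @return Augmented image of the same dimensions.
#' @export
augment <- function(image, mode, seed = 1) {
  if (!inherits(mode, "augmentation_mode"))
    stop("`mode` must be an augmentation_mode object", call. = FALSE)
  if (mode$mode == "none") return(image)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  p <- .draw_augment_params(mode)
  side <- dim(image)[1]
  shift <- round(stats::runif(2, -mode$translation, mode$translation) * side)
  pad <- ceiling(side / 2)
  padded <- .pad_reflect(image, pad)
  out <- .augment_geometry(padded, p$flip_h, p$flip_v, p$angle,
                           shift[1], shift[2])
  ctr <- pad + seq_len(side)
  out <- out[ctr, ctr, , drop = FALSE]
  pmin(pmax(out * p$bfac, 0), 1)
}
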