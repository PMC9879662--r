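# Seeded synthetic image/mask generator. Emulates single-foreground-structure
# medical images — one bright blob / tube-like region on a noisy background —
# so every downstream stage (training, fusion, the federated experiment) is
# testable without external datasets. Masks are drawn first; images derive
# from them (foreground 0.7, background 0.3, Gaussian blur, Gaussian noise),
# which keeps the task learnable by very small networks in CPU minutes.

#' Configuration for the synthetic dataset generator
#'
#' @param n_images number of samples to generate (>= 0).
#' @param image_size `(height, width)` in pixels, each >= 16.
#' @param shape_family `"ellipse"` (one random ellipse), `"tube"` (one thick
#'   random segment), or `"multi_blob"` (union of 2-4 ellipses).
#' @param fg_fraction_range `(low, high)` bounds in `(0, 1)` on every mask's
#'   foreground fraction.
#' @param noise_sigma standard deviation of additive Gaussian intensity noise
#'   on the `[0, 1]` scale.
#' @param blur_sigma Gaussian blur radius in pixels (0 disables).
#' @param seed integer seed; identical configs generate bit-identical data.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_images, image_size = c(32L, 32L),
                             shape_family = c("ellipse", "tube", "multi_blob"),
                             fg_fraction_range = c(0.1, 0.35),
                             noise_sigma = 0.05, blur_sigma = 0.7,
                             seed = 1L) {
  shape_family <- match.arg(shape_family)
  n_images <- as.integer(n_images)
  if (is.na(n_images) || n_images < 0L)
    stop_config("n_images must be a non-negative count")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 16L))
    stop_config("image_size must be (height, width) with both >= 16 px")
  f <- as.numeric(fg_fraction_range)
  if (length(f) != 2L || f[1L] <= 0 || f[2L] >= 1 || f[1L] > f[2L])
    stop_config("fg_fraction_range must satisfy 0 < low <= high < 1")
  if (noise_sigma < 0) stop_config("noise_sigma must be non-negative")
  if (blur_sigma < 0) stop_config("blur_sigma must be non-negative")
  structure(list(n_images = n_images, image_size = image_size,
                 shape_family = shape_family, fg_fraction_range = f,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = seed), class = "synthetic_config")
}

# ---- mask morphology (4-neighbour structuring element) ---------------------

shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate1 <- function(m) {
  (m + shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
     shift_mat(m, 0, 1) + shift_mat(m, 0, -1) > 0) * 1
}

erode1 <- function(m) {
  1 - dilate1(1 - m)
}

# ---- shape samplers (0-based row/col pixel centres) ------------------------

ellipse_mask <- function(H, W, frac, margin = 0.22) {
  cy <- runif(1, margin, 1 - margin) * (H - 1)
  cx <- runif(1, margin, 1 - margin) * (W - 1)
  rho <- runif(1, 0.6, 1.7)
  theta <- runif(1, 0, pi)
  a <- sqrt(frac * H * W * rho / pi)
  b <- a / rho
  yy <- matrix(0:(H - 1), H, W) - cy
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE) - cx
  u <- yy * cos(theta) + xx * sin(theta)
  v <- -yy * sin(theta) + xx * cos(theta)
  ((u / a)^2 + (v / b)^2 <= 1) * 1
}

tube_mask <- function(H, W, frac) {
  # thick segment between two random border-ish points
  p1 <- c(runif(1, 0, 0.25) * (H - 1), runif(1, 0, 1) * (W - 1))
  p2 <- c(runif(1, 0.75, 1) * (H - 1), runif(1, 0, 1) * (W - 1))
  len <- sqrt(sum((p2 - p1)^2))
  thick <- max(1.5, frac * H * W / len)
  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d <- p2 - p1
  t <- pmin(pmax(((yy - p1[1]) * d[1] + (xx - p1[2]) * d[2]) / sum(d^2), 0), 1)
  dist <- sqrt((yy - (p1[1] + t * d[1]))^2 + (xx - (p1[2] + t * d[2]))^2)
  (dist <= thick / 2) * 1
}

multi_blob_mask <- function(H, W, frac) {
  k <- sample(2:4, 1)
  m <- matrix(0, H, W)
  for (i in seq_len(k)) m <- pmax(m, ellipse_mask(H, W, frac / k, margin = 0.15))
  m
}

draw_mask <- function(cfg) {
  H <- cfg$image_size[1L]; W <- cfg$image_size[2L]
  lo <- cfg$fg_fraction_range[1L]; hi <- cfg$fg_fraction_range[2L]
  mask <- NULL
  for (attempt in seq_len(100L)) {
    f <- runif(1, lo, hi)
    mask <- switch(cfg$shape_family,
                   ellipse = ellipse_mask(H, W, f),
                   tube = tube_mask(H, W, f),
                   multi_blob = multi_blob_mask(H, W, f))
    fr <- mean(mask)
    if (fr >= lo && fr <= hi) return(mask)
  }
  # rejection cap reached: adjust the last draw morphologically
  for (step in seq_len(200L)) {
    fr <- mean(mask)
    if (fr >= lo && fr <= hi) return(mask)
    mask <- if (fr > hi) erode1(mask) else dilate1(mask)
    if (sum(mask) == 0) {  # re-seed a pixel if erosion emptied the mask
      mask[ceiling(nrow(mask) / 2), ceiling(ncol(mask) / 2)] <- 1
    }
  }
  stop_config("could not realise a mask with foreground fraction in [",
              lo, ", ", hi, "]")
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- outer(k, k)
  kern <- array(kern / sum(kern), dim = c(2L * r + 1L, 2L * r + 1L, 1L, 1L))
  blur <- function(m) {
    x <- array(m, dim = c(dim(m), 1L))
    cpp_conv2d_fw(x, kern, 0, 1L, r, 1L, 1L)[, , 1L]
  }
  # normalised convolution corrects zero-padding darkening at borders
  blur(img) / blur(matrix(1, nrow(img), ncol(img)))
}

render_image <- function(mask, cfg) {
  img <- 0.3 + 0.4 * mask
  img <- gaussian_blur(img, cfg$blur_sigma)
  if (cfg$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_sigma),
                        nrow(img), ncol(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a seeded synthetic dataset
#'
#' Draws `n_images` image/mask pairs per the config. Every mask's foreground
#' fraction lies inside `fg_fraction_range` (rejection sampling with a
#' morphological fallback), every mask has at least one foreground and one
#' background pixel, and identical configs produce bit-identical datasets
#' (each sample derives its own RNG stream from the config seed and index).
#'
#' @param config a [synthetic_config()].
#' @return list of samples, each `list(image, mask, sample_id)` with `image`
#'   an `H x W` matrix in `[0, 1]` and `mask` a binary `H x W` matrix.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_config("config must be a synthetic_config")
  lapply(seq_len(config$n_images), function(i) {
    with_seed(derive_seed(config$seed, 1000L + i), {
      mask <- draw_mask(config)
      list(image = render_image(mask, config), mask = mask,
           sample_id = sprintf("s%04d", i))
    })
  })
}

#' Split samples and form nested training buckets
#'
#' Shuffles sample ids with the given seed, holds out validation and test
#' fractions (sizes rounded down), and slices the remaining training ids into
#' five nested buckets at 20/40/60/80/100% of the training portion (sizes
#' rounded down, minimum 1; the last bucket is the full training set).
#'
#' @param samples list of samples (needs `sample_id`).
#' @param val_frac,test_frac held-out fractions with
#'   `val_frac + test_frac < 1`.
#' @param seed shuffle seed.
#' @return object of class `"dataset_buckets"`: `train_buckets` (list of five
#'   nested id vectors), `val_ids`, `test_ids`.
#' @export
make_buckets <- function(samples, val_frac = 0.1, test_frac = 0.1, seed = 1L) {
  if (val_frac < 0 || test_frac < 0 || val_frac + test_frac >= 1)
    stop_config("val_frac + test_frac must be < 1")
  ids <- vapply(samples, function(s) s$sample_id, "")
  n <- length(ids)
  ids <- with_seed(seed, sample(ids))
  n_val <- floor(val_frac * n); n_test <- floor(test_frac * n)
  n_train <- n - n_val - n_test
  if (n_train < 5L)
    stop_config("need at least 5 training samples to form 5 buckets, have ",
                n_train)
  val_ids <- if (n_val) ids[seq_len(n_val)] else character(0)
  test_ids <- if (n_test) ids[n_val + seq_len(n_test)] else character(0)
  train_ids <- ids[n_val + n_test + seq_len(n_train)]
  sizes <- pmax(1L, floor(seq(0.2, 1, by = 0.2) * n_train))
  structure(list(train_buckets = lapply(sizes, function(k) train_ids[seq_len(k)]),
                 bucket_percent = seq(20L, 100L, by = 20L),
                 val_ids = val_ids, test_ids = test_ids),
            class = "dataset_buckets")
}

#' @export
print.dataset_buckets <- function(x, ...) {
  cat(sprintf("<dataset_buckets> train buckets %s | val %d | test %d\n",
              paste(lengths(x$train_buckets), collapse = "/"),
              length(x$val_ids), length(x$test_ids)))
  invisible(x)
}

#' Write / read a dataset as PNG pairs
#'
#' Layout: `images/<id>.png` and `masks/<id>.png` (8-bit greyscale; masks use
#' 0/255 on disk and 0/1 in memory) plus a `manifest.json` listing ids.
#' Masks round-trip exactly; images round-trip to 8-bit quantisation.
#'
#' @param samples list of samples.
#' @param directory dataset directory.
#' @return `read_dataset()` returns the sample list (alphabetical by id);
#'   `write_dataset()` the directory, invisibly.
#' @export
write_dataset <- function(samples, directory) {
  dir.create(file.path(directory, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(round(s$image * 255) / 255,
                  file.path(directory, "images", paste0(s$sample_id, ".png")))
    png::writePNG(s$mask,
                  file.path(directory, "masks", paste0(s$sample_id, ".png")))
  }
  writeLines(jsonlite::toJSON(list(
    ids = vapply(samples, function(s) s$sample_id, "")), pretty = TRUE),
    file.path(directory, "manifest.json"))
  invisible(directory)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  img_dir <- file.path(directory, "images")
  msk_dir <- file.path(directory, "masks")
  imgs <- if (dir.exists(img_dir))
    sort(list.files(img_dir, pattern = "\\.png$")) else character(0)
  msks <- if (dir.exists(msk_dir))
    sort(list.files(msk_dir, pattern = "\\.png$")) else character(0)
  unmatched <- c(setdiff(imgs, msks), setdiff(msks, imgs))
  if (length(unmatched))
    stop_format("image/mask pairing broken for id(s): ",
                paste(sub("\\.png$", "", unmatched), collapse = ", "))
  lapply(imgs, function(f) {
    img <- png::readPNG(file.path(img_dir, f))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    msk <- png::readPNG(file.path(msk_dir, f))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    list(image = img, mask = (msk > 0.5) * 1,
         sample_id = sub("\\.png$", "", f))
  })
}
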