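#' Declare a segmentation network architecture
#'
#' Describes one of the four supported encoder-decoder families declaratively;
#' [build_model()] instantiates it and [count_parameters()] computes its exact
#' trainable-scalar count from the spec alone.
#'
#' All families share the same conventions: 3x3 convolutions in same-padding
#' blocks, ReLU after every convolution, 2x2 max-pool downsampling, and a
#' final 1x1 convolution whose sigmoid output gives per-pixel foreground
#' probabilities. Channel widths double per resolution level unless
#' `width_schedule` overrides them.
#'
#' * `"unet"` — plain encoder-decoder with long skip connections: each decoder
#'   level upsamples, concatenates the same-scale encoder features, and
#'   convolves.
#' * `"unetpp"` — nested dense skip pathway: intermediate nodes `X[i,j]`
#'   aggregate all previous same-scale nodes plus an upsampled deeper node.
#' * `"unet3p"` — full-scale skips: every decoder level fuses all encoder
#'   scales (max-pooled down) and all deeper decoder levels (upsampled),
#'   each reduced to `base_width` channels; decoder width is
#'   `depth * base_width` everywhere.
#' * `"nasunet"` — fixed downsampling (DownSC) and upsampling (UpSC) cells
#'   assembled from a small primitive set (`"sep_conv_3x3"`,
#'   `"dil_conv_3x3"`, `"max_pool_3x3"`, `"identity"`) with a residual
#'   connection around the primitive stack. No architecture search is
#'   performed; the cell is part of the spec.
#'
#' @param family one of `"unet"`, `"unetpp"`, `"unet3p"`, `"nasunet"`.
#' @param depth number of resolution levels (>= 2).
#' @param base_width channels at the top level (>= 1).
#' @param in_channels,out_channels input / output channel counts.
#' @param upsample_mode `"transposed_conv"` (2x2 stride-2 transposed
#'   convolution) or `"bilinear_conv"` (bilinear upsampling followed by a
#'   3x3 convolution).
#' @param width_schedule optional integer vector of length `depth` overriding
#'   the doubling widths.
#' @param nasunet_cell list with character vectors `down` and `up`: the
#'   ordered primitives of the DownSC and UpSC cells.
#' @return an object of class `"architecture_spec"`.
#' @export
#' @examples
#' spec <- architecture_spec("unet", depth = 2, base_width = 4)
#' count_parameters(spec)
architecture_spec <- function(family = c("unet", "unetpp", "unet3p", "nasunet"),
                              depth = 5L, base_width = 32L,
                              in_channels = 1L, out_channels = 1L,
                              upsample_mode = c("transposed_conv",
                                                "bilinear_conv"),
                              width_schedule = NULL,
                              nasunet_cell = list(
                                down = c("sep_conv_3x3", "dil_conv_3x3"),
                                up = c("sep_conv_3x3", "identity"))) {
  family <- match.arg(family)
  upsample_mode <- match.arg(upsample_mode)
  depth <- as.integer(depth); base_width <- as.integer(base_width)
  if (depth < 2L) stop_config("depth must be >= 2, got ", depth)
  if (base_width < 1L) stop_config("base_width must be >= 1, got ", base_width)
  if (in_channels < 1L || out_channels < 1L)
    stop_config("in_channels and out_channels must be >= 1")
  widths <- if (is.null(width_schedule)) {
    base_width * 2L^(seq_len(depth) - 1L)
  } else {
    ws <- as.integer(width_schedule)
    if (length(ws) != depth || any(ws < 1L))
      stop_config("width_schedule must give ", depth, " positive widths")
    ws
  }
  known <- c("sep_conv_3x3", "dil_conv_3x3", "max_pool_3x3", "identity")
  if (family == "nasunet") {
    bad <- setdiff(unlist(nasunet_cell), known)
    if (length(bad))
      stop_config("unknown nasunet cell primitive(s): ",
                  paste(bad, collapse = ", "))
    if (!all(c("down", "up") %in% names(nasunet_cell)))
      stop_config("nasunet_cell needs 'down' and 'up' primitive lists")
  }
  structure(list(family = family, depth = depth, base_width = base_width,
                 widths = widths, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 upsample_mode = upsample_mode, nasunet_cell = nasunet_cell),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s, depth %d, widths %s, %d -> %d ch, %s\n",
              x$family, x$depth, paste(x$widths, collapse = "/"),
              x$in_channels, x$out_channels, x$upsample_mode))
  invisible(x)
}

# ---- shared builder pieces -------------------------------------------------

conv_block <- function(g, input, cin, cout) {
  add_conv(g, add_conv(g, input, 3L, cin, cout), 3L, cout, cout)
}

# upsample w[from] channels to w[to] channels at double resolution
add_up <- function(g, input, cin, cout, mode) {
  if (mode == "transposed_conv") add_tconv2(g, input, cin, cout)
  else add_conv(g, add_upsample(g, input, 2L), 3L, cin, cout)
}

build_encoder <- function(g, x, spec) {
  w <- spec$widths
  enc <- integer(spec$depth)
  cur <- x
  cin <- spec$in_channels
  for (l in seq_len(spec$depth)) {
    enc[l] <- conv_block(g, cur, cin, w[l])
    if (l < spec$depth) cur <- add_maxpool(g, enc[l], 2L)
    cin <- w[l]
  }
  enc
}

build_unet_graph <- function(g, spec) {
  w <- spec$widths
  x <- g$add("input")
  enc <- build_encoder(g, x, spec)
  cur <- enc[spec$depth]
  for (l in rev(seq_len(spec$depth - 1L))) {
    up <- add_up(g, cur, w[l + 1L], w[l], spec$upsample_mode)
    cur <- conv_block(g, add_concat(g, c(up, enc[l])), 2L * w[l], w[l])
  }
  add_conv(g, cur, 1L, w[1L], spec$out_channels, relu = FALSE)
}

build_unetpp_graph <- function(g, spec) {
  d <- spec$depth; w <- spec$widths
  x <- g$add("input")
  enc <- build_encoder(g, x, spec)
  xs <- lapply(seq_len(d), function(i) {
    v <- vector("list", d - i + 1L); v[[1L]] <- enc[i]; v
  })
  for (j in seq_len(d - 1L)) {
    for (i in seq_len(d - j)) {
      up <- add_up(g, xs[[i + 1L]][[j]], w[i + 1L], w[i], spec$upsample_mode)
      cat_id <- add_concat(g, c(unlist(xs[[i]][seq_len(j)]), up))
      xs[[i]][[j + 1L]] <- conv_block(g, cat_id, (j + 1L) * w[i], w[i])
    }
  }
  add_conv(g, xs[[1L]][[d]], 1L, w[1L], spec$out_channels, relu = FALSE)
}

build_unet3p_graph <- function(g, spec) {
  d <- spec$depth; w <- spec$widths; bw <- spec$base_width
  D <- d * bw
  x <- g$add("input")
  enc <- build_encoder(g, x, spec)
  dec <- vector("list", d)
  dec[[d]] <- enc[d]
  for (l in rev(seq_len(d - 1L))) {
    srcs <- integer(0)
    for (e in seq_len(l)) {
      src <- if (e < l) add_maxpool(g, enc[e], 2L^(l - e)) else enc[e]
      srcs <- c(srcs, add_conv(g, src, 3L, w[e], bw))
    }
    for (m in seq(l + 1L, d)) {
      sw <- if (m == d) w[d] else D
      up <- add_upsample(g, dec[[m]], 2L^(m - l))
      srcs <- c(srcs, add_conv(g, up, 3L, sw, bw))
    }
    dec[[l]] <- add_conv(g, add_concat(g, srcs), 3L, D, D)
  }
  add_conv(g, dec[[1L]], 1L, D, spec$out_channels, relu = FALSE)
}

add_cell_primitive <- function(g, input, C, name) {
  switch(name,
    sep_conv_3x3 = add_conv(g, add_conv(g, input, 3L, C, C, groups = C),
                            1L, C, C),
    dil_conv_3x3 = add_conv(g, input, 3L, C, C, pad = 2L, dil = 2L),
    max_pool_3x3 = add_maxpool(g, input, 3L, stride = 1L, pad = 1L),
    identity = input,
    stop_config("unknown nasunet cell primitive: ", name))
}

add_cell_body <- function(g, entry, C, prims) {
  h <- entry
  for (p in prims) h <- add_cell_primitive(g, h, C, p)
  if (h == entry) entry else add_sum(g, h, entry)
}

build_nasunet_graph <- function(g, spec) {
  d <- spec$depth; w <- spec$widths
  x <- g$add("input")
  enc <- integer(d)
  enc[1L] <- add_conv(g, x, 3L, spec$in_channels, w[1L])
  for (l in seq(2L, d)) {  # DownSC: stride-2 entry then primitive stack
    entry <- add_conv(g, enc[l - 1L], 3L, w[l - 1L], w[l],
                      stride = 2L, pad = 1L)
    enc[l] <- add_cell_body(g, entry, w[l], spec$nasunet_cell$down)
  }
  cur <- enc[d]
  for (l in rev(seq_len(d - 1L))) {  # UpSC: upsample entry, fuse skip, stack
    up <- add_up(g, cur, w[l + 1L], w[l], spec$upsample_mode)
    red <- add_conv(g, add_concat(g, c(up, enc[l])), 1L, 2L * w[l], w[l])
    cur <- add_cell_body(g, red, w[l], spec$nasunet_cell$up)
  }
  add_conv(g, cur, 1L, w[1L], spec$out_channels, relu = FALSE)
}

#' Instantiate a segmentation network from a spec
#'
#' Allocates and deterministically initialises all trainable parameters
#' (uniform He-style fan-in scaling, seeded) and returns a model handle that
#' [forward()], [train_segnet()] and [predict_mask()] operate on.
#'
#' @param spec an [architecture_spec()].
#' @param seed integer seed controlling weight initialisation; identical
#'   `spec` + `seed` give bit-identical weights.
#' @return an object of class `"segnet"`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "architecture_spec"))
    stop_config("spec must be an architecture_spec")
  with_seed(seed, {
    g <- graph_builder()
    out_id <- switch(spec$family,
      unet = build_unet_graph(g, spec),
      unetpp = build_unetpp_graph(g, spec),
      unet3p = build_unet3p_graph(g, spec),
      nasunet = build_nasunet_graph(g, spec))
    structure(list(spec = spec, nodes = g$nodes, out_id = out_id,
                   divisor = 2L^(spec$depth - 1L), init_seed = seed),
              class = "segnet")
  })
}

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf("<segnet> %s: depth %d, widths %s, %s trainable parameters\n",
              x$spec$family, x$spec$depth,
              paste(x$spec$widths, collapse = "/"),
              format(graph_param_count(x), big.mark = ",")))
  invisible(x)
}

# ---- parameter accounting (closed form, no allocation) ---------------------

n_conv <- function(k, cin, cout, groups = 1L) k * k * (cin / groups) * cout + cout
n_up <- function(cin, cout, mode) {
  if (mode == "transposed_conv") 4 * cin * cout + cout
  else 9 * cin * cout + cout
}
n_block <- function(cin, cout) n_conv(3, cin, cout) + n_conv(3, cout, cout)
n_encoder <- function(spec) {
  w <- spec$widths
  sum(n_block(c(spec$in_channels, w[-spec$depth]), w))
}
n_prims <- function(C, prims) {
  sum(vapply(prims, function(p) switch(p,
    sep_conv_3x3 = n_conv(3, C, C, groups = C) + n_conv(1, C, C),
    dil_conv_3x3 = n_conv(3, C, C),
    max_pool_3x3 = 0,
    identity = 0,
    stop_config("unknown nasunet cell primitive: ", p)), 0))
}

#' Exact trainable-parameter count of an architecture
#'
#' Computes the number of trainable scalars (convolution weights plus biases)
#' from the spec by closed-form accounting, without allocating any weights.
#' The count matches a walk over [build_model()]'s instantiated parameter
#' arrays exactly. Under the default conventions (depth 5, widths 32-512,
#' one input and one output channel, transposed-convolution upsampling, two
#' 3x3 convolutions per block) the plain U-Net counts 7,759,521 scalars
#' (7.8 M) and the nested-skip variant 9,041,601 (9.0 M).
#'
#' @param spec an [architecture_spec()].
#' @return integer-valued numeric scalar.
#' @export
count_parameters <- function(spec) {
  if (!inherits(spec, "architecture_spec"))
    stop_config("spec must be an architecture_spec")
  d <- spec$depth; w <- spec$widths; mode <- spec$upsample_mode
  total <- switch(spec$family,
    unet = {
      dec <- sum(vapply(seq_len(d - 1L), function(l)
        n_up(w[l + 1L], w[l], mode) + n_block(2L * w[l], w[l]), 0))
      n_encoder(spec) + dec + n_conv(1, w[1L], spec$out_channels)
    },
    unetpp = {
      nested <- 0
      for (j in seq_len(d - 1L))
        for (i in seq_len(d - j))
          nested <- nested + n_up(w[i + 1L], w[i], mode) +
            n_block((j + 1L) * w[i], w[i])
      n_encoder(spec) + nested + n_conv(1, w[1L], spec$out_channels)
    },
    unet3p = {
      bw <- spec$base_width; D <- d * bw
      dec <- 0
      for (l in seq_len(d - 1L)) {
        dec <- dec + sum(n_conv(3, w[seq_len(l)], bw))
        sw <- ifelse(seq(l + 1L, d) == d, w[d], D)
        dec <- dec + sum(n_conv(3, sw, bw)) + n_conv(3, D, D)
      }
      n_encoder(spec) + dec + n_conv(1, D, spec$out_channels)
    },
    nasunet = {
      down <- sum(vapply(seq(2L, d), function(l)
        n_conv(3, w[l - 1L], w[l]) + n_prims(w[l], spec$nasunet_cell$down), 0))
      up <- sum(vapply(seq_len(d - 1L), function(l)
        n_up(w[l + 1L], w[l], mode) + n_conv(1, 2L * w[l], w[l]) +
          n_prims(w[l], spec$nasunet_cell$up), 0))
      n_conv(3, spec$in_channels, w[1L]) + down + up +
        n_conv(1, w[1L], spec$out_channels)
    })
  total
}

# ---- forward / digests / checkpoints ---------------------------------------

as_image_array <- function(image, in_channels) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3L || dim(image)[3L] != in_channels)
    stop_config("image must be H x W (x in_channels)")
  storage.mode(image) <- "double"
  image
}

check_divisible <- function(model, h, w) {
  dv <- model$divisor
  if (h %% dv != 0L || w %% dv != 0L)
    stop_config("input size ", h, "x", w, " must be divisible by 2^(depth-1) = ",
                dv)
}

forward_one <- function(model, image, keep = FALSE) {
  x <- as_image_array(image, model$spec$in_channels)
  check_divisible(model, dim(x)[1L], dim(x)[2L])
  forward_graph(model, x, keep = keep)
}

#' Run a network forward, returning per-pixel probabilities
#'
#' Applies the network and the sigmoid output activation. Accepts a single
#' `H x W` matrix, an `H x W x N` array (a batch; order preserved), or a list
#' of matrices. Spatial dimensions must be divisible by `2^(depth - 1)`.
#'
#' @param model a `"segnet"` from [build_model()].
#' @param images input image(s) with intensities on the `[0, 1]` scale.
#' @return probabilities in `[0, 1]`, shaped like the input (single matrix,
#'   `H x W x N` array, or list).
#' @export
forward <- function(model, images) {
  if (!inherits(model, "segnet")) stop_config("model must be a segnet")
  squeeze <- function(logits) {
    if (model$spec$out_channels == 1L) {
      p <- stats::plogis(logits[, , 1L])
      dim(p) <- dim(logits)[1:2]
      p
    } else stats::plogis(logits)
  }
  if (is.list(images)) return(lapply(images, function(im)
    squeeze(forward_one(model, im)$out)))
  if (is.matrix(images) ||
      (length(dim(images)) == 3L &&
       dim(images)[3L] == model$spec$in_channels && model$spec$in_channels > 1L))
    return(squeeze(forward_one(model, images)$out))
  if (length(dim(images)) == 3L) {
    out <- vapply(seq_len(dim(images)[3L]), function(i)
      squeeze(forward_one(model, images[, , i])$out),
      matrix(0, dim(images)[1L], dim(images)[2L]))
    return(out)
  }
  stop_config("images must be a matrix, a 3-d array, or a list of matrices")
}

#' @export
predict.segnet <- function(object, images, type = c("prob", "mask"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- forward(object, images)
  if (type == "prob") return(p)
  if (is.list(p)) lapply(p, function(m) (m > threshold) * 1L)
  else (p > threshold) * 1L
}

#' SHA-512 digest of a model's trainable parameters
#'
#' Hashes the canonical little-endian serialization of every weight and bias
#' in node order; identical spec + seed (+ training trajectory) give
#' identical digests.
#'
#' @param model a `"segnet"`.
#' @return 128-character lowercase hex string.
#' @export
weights_digest <- function(model) {
  if (!inherits(model, "segnet")) stop_config("model must be a segnet")
  raw_to_hex(cpp_sha512(serialize_weights(model)))
}

#' Save / load a model checkpoint
#'
#' `save_segnet()` writes the raw weight bytes to `path` and a JSON sidecar
#' (`<path>.json`) holding the spec and the weights digest; `load_segnet()`
#' rebuilds the model and verifies the digest.
#'
#' @param model a `"segnet"`.
#' @param path checkpoint file path.
#' @return `load_segnet()` returns the restored `"segnet"`;
#'   `save_segnet()` returns `path` invisibly.
#' @export
save_segnet <- function(model, path) {
  if (!inherits(model, "segnet")) stop_config("model must be a segnet")
  writeBin(serialize_weights(model), path)
  sidecar <- list(spec = unclass(model$spec)[c(
    "family", "depth", "base_width", "in_channels", "out_channels",
    "upsample_mode", "widths")],
    nasunet_cell = model$spec$nasunet_cell,
    init_seed = model$init_seed,
    weights_digest = weights_digest(model))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  spec <- architecture_spec(side$spec$family, depth = side$spec$depth,
                            base_width = side$spec$base_width,
                            in_channels = side$spec$in_channels,
                            out_channels = side$spec$out_channels,
                            upsample_mode = side$spec$upsample_mode,
                            width_schedule = side$spec$widths,
                            nasunet_cell = lapply(side$nasunet_cell, unlist))
  model <- build_model(spec, seed = side$init_seed)
  bytes <- readBin(path, "raw", n = file.size(path))
  vals <- readBin(bytes, "double", n = length(bytes) / 8L, size = 8L,
                  endian = "little")
  off <- 0L
  for (i in seq_along(model$nodes)) {
    p <- model$nodes[[i]]$param
    if (is.null(p)) next
    nw <- length(p$W); nb <- length(p$b)
    model$nodes[[i]]$param$W <- array(vals[off + seq_len(nw)], dim = dim(p$W))
    off <- off + nw
    model$nodes[[i]]$param$b <- vals[off + seq_len(nb)]
    off <- off + nb
  }
  if (off != length(vals))
    stop_format("checkpoint size does not match architecture")
  if (weights_digest(model) != side$weights_digest)
    stop_format("checkpoint digest mismatch for ", path)
  model
}
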