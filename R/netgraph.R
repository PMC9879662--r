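# Minimal static computation graph for the encoder-decoder networks.
# Nodes are evaluated in insertion order (builders emit topologically sorted
# graphs); activations are (H, W, C) arrays. Backward walks the node list in
# reverse and accumulates parameter gradients plus input gradients.

graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$add <- function(op, inputs = integer(), cfg = list(), param = NULL) {
    # force all arguments before reserving the id: nested builder calls in
    # an argument position must append their nodes first
    inputs <- as.integer(inputs); force(cfg); force(param)
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- list(op = op, inputs = inputs, cfg = cfg, param = param)
    id
  }
  env
}

# He-style uniform fan-in initialisation; biases start at zero.
init_conv_param <- function(k, cin_g, cout, fan_in) {
  limit <- sqrt(6 / fan_in)
  list(W = array(runif(k * k * cin_g * cout, -limit, limit),
                 dim = c(k, k, cin_g, cout)),
       b = numeric(cout))
}

add_conv <- function(g, input, k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                     dil = 1L, groups = 1L, relu = TRUE) {
  input <- as.integer(input)  # evaluate nested builders before drawing weights
  cin_g <- cin %/% groups
  p <- init_conv_param(k, cin_g, cout, fan_in = k * k * cin_g)
  id <- g$add("conv", input,
              cfg = list(stride = as.integer(stride), pad = as.integer(pad),
                         dil = as.integer(dil), groups = as.integer(groups)),
              param = p)
  if (relu) g$add("relu", id) else id
}

add_tconv2 <- function(g, input, cin, cout, relu = TRUE) {
  input <- as.integer(input)
  p <- init_conv_param(2L, cin, cout, fan_in = cin)
  id <- g$add("tconv2", input, param = p)
  if (relu) g$add("relu", id) else id
}

add_maxpool <- function(g, input, k, stride = k, pad = 0L) {
  g$add("maxpool", input, cfg = list(k = as.integer(k),
                                     stride = as.integer(stride),
                                     pad = as.integer(pad)))
}

add_upsample <- function(g, input, factor) {
  g$add("bilinear", input, cfg = list(f = as.integer(factor)))
}

add_concat <- function(g, inputs) g$add("concat", inputs)

add_sum <- function(g, a, b) g$add("add", c(a, b))

forward_graph <- function(net, x, keep = FALSE) {
  nodes <- net$nodes
  n <- length(nodes)
  acts <- vector("list", n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    acts[[i]] <- switch(nd$op,
      input = x,
      conv = cpp_conv2d_fw(acts[[nd$inputs]], nd$param$W, nd$param$b,
                           nd$cfg$stride, nd$cfg$pad, nd$cfg$dil,
                           nd$cfg$groups),
      relu = { a <- acts[[nd$inputs]]; a[a < 0] <- 0; a },
      maxpool = {
        r <- cpp_maxpool_fw(acts[[nd$inputs]], nd$cfg$k, nd$cfg$stride,
                            nd$cfg$pad)
        if (keep) caches[[i]] <- list(idx = r$idx,
                                      dim = dim(acts[[nd$inputs]]))
        r$y
      },
      tconv2 = cpp_tconv2_fw(acts[[nd$inputs]], nd$param$W, nd$param$b),
      bilinear = cpp_bilinear_up_fw(acts[[nd$inputs]], nd$cfg$f),
      concat = {
        parts <- acts[nd$inputs]
        d <- dim(parts[[1L]])
        array(unlist(parts, use.names = FALSE),
              dim = c(d[1L], d[2L], sum(vapply(parts, function(p)
                dim(p)[3L], 0))))
      },
      add = acts[[nd$inputs[1L]]] + acts[[nd$inputs[2L]]],
      stop("unknown graph op: ", nd$op)
    )
  }
  list(acts = acts, caches = caches, out = acts[[net$out_id]])
}

backward_graph <- function(net, fwd, gout) {
  nodes <- net$nodes
  n <- length(nodes)
  gacts <- vector("list", n)
  pgrads <- vector("list", n)
  gacts[[net$out_id]] <- gout
  acc <- function(id, g) {
    gacts[[id]] <<- if (is.null(gacts[[id]])) g else gacts[[id]] + g
  }
  for (i in rev(seq_len(n))) {
    g <- gacts[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    switch(nd$op,
      input = NULL,
      conv = {
        r <- cpp_conv2d_bw(fwd$acts[[nd$inputs]], nd$param$W, g,
                           nd$cfg$stride, nd$cfg$pad, nd$cfg$dil,
                           nd$cfg$groups)
        pgrads[[i]] <- list(W = r$gw, b = r$gb)
        acc(nd$inputs, r$gx)
      },
      relu = acc(nd$inputs, g * (fwd$acts[[i]] > 0)),
      maxpool = {
        ca <- fwd$caches[[i]]
        acc(nd$inputs, cpp_maxpool_bw(ca$idx, g, ca$dim[1L], ca$dim[2L],
                                      ca$dim[3L]))
      },
      tconv2 = {
        r <- cpp_tconv2_bw(fwd$acts[[nd$inputs]], nd$param$W, g)
        pgrads[[i]] <- list(W = r$gw, b = r$gb)
        acc(nd$inputs, r$gx)
      },
      bilinear = {
        d <- dim(fwd$acts[[nd$inputs]])
        acc(nd$inputs, cpp_bilinear_up_bw(g, d[1L], d[2L], nd$cfg$f))
      },
      concat = {
        off <- 0L
        for (id in nd$inputs) {
          cc <- dim(fwd$acts[[id]])[3L]
          acc(id, g[, , off + seq_len(cc), drop = FALSE])
          off <- off + cc
        }
      },
      add = { acc(nd$inputs[1L], g); acc(nd$inputs[2L], g) }
    )
    gacts[[i]] <- NULL  # free as we go
  }
  pgrads
}

# Elementwise accumulate two pgrad lists (NULL-safe)
accumulate_pgrads <- function(total, pg) {
  if (is.null(total)) return(pg)
  for (i in seq_along(pg)) {
    if (!is.null(pg[[i]])) {
      total[[i]]$W <- total[[i]]$W + pg[[i]]$W
      total[[i]]$b <- total[[i]]$b + pg[[i]]$b
    }
  }
  total
}

sgd_update <- function(net, pgrads, lr, scale = 1) {
  for (i in seq_along(net$nodes)) {
    pg <- pgrads[[i]]
    if (is.null(pg)) next
    net$nodes[[i]]$param$W <- net$nodes[[i]]$param$W - lr * scale * pg$W
    net$nodes[[i]]$param$b <- net$nodes[[i]]$param$b - lr * scale * pg$b
  }
  net
}

graph_param_count <- function(net) {
  sum(vapply(net$nodes, function(nd) {
    if (is.null(nd$param)) 0 else length(nd$param$W) + length(nd$param$b)
  }, 0))
}

# Canonical little-endian serialization of all trainable scalars, node order
serialize_weights <- function(net) {
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  for (nd in net$nodes) {
    if (!is.null(nd$param)) {
      writeBin(as.numeric(nd$param$W), con, size = 8L, endian = "little")
      writeBin(as.numeric(nd$param$b), con, size = 8L, endian = "little")
    }
  }
  rawConnectionValue(con)
}
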