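# Shared fixtures, generated in code at test time.

tiny_dataset <- function(n = 24, seed = 1234, size = c(32L, 32L)) {
  generate_dataset(synthetic_config(n, image_size = size, seed = seed))
}

random_mask <- function(h = 8, w = 8, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# A 4-block toy chain over one authorized site, plus its registry and key.
toy_chain <- function(seed = 99, n_blocks = 4) {
  key <- sprintf("key-%d", seed)
  reg <- set_authorized(register_site(site_registry(), "site_1", key),
                        "site_1")
  chain <- new_chain()
  set.seed(seed)
  for (i in seq_len(n_blocks)) {
    pl <- block_payload("site_1", i,
                        sha512_hex(sprintf("data-%d-%d", seed, i)),
                        hyperparameters(runif(1, 0.01, 0.5),
                                        sample.int(20, 1), sample.int(8, 1)),
                        sha512_hex(sprintf("weights-%d-%d", seed, i)),
                        timestamp = i)
    chain <- append_block(chain, pl, reg, key)
  }
  list(chain = chain, registry = reg, key = key)
}

# Exhaustive per-pixel tally: the independent fusion oracle.
vote_oracle <- function(probabilities, threshold = 0.5) {
  d <- dim(probabilities)
  out <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      v <- probabilities[r, c, ] > threshold
      n1 <- sum(v); n0 <- length(v) - n1
      out[r, c] <- if (n1 > n0) 1 else if (n1 < n0) 0
      else as.numeric(mean(probabilities[r, c, ]) > 0.5)
    }
  }
  out
}

# Set-enumeration IoU oracle over explicit pixel-index sets.
iou_oracle <- function(u, v) {
  su <- which(u == 1); sv <- which(v == 1)
  un <- union(su, sv)
  if (!length(un)) return(1)
  length(intersect(su, sv)) / length(un)
}
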