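# Hash-chain audit ledger. Every model update becomes a block carrying the
# digests of its training-data manifest and delivered weights plus the
# hyperparameters used; blocks link by the SHA-512 of their predecessor's
# canonical serialization, and an auxiliary running checksum
#   H_i = ( H_{i-1} + ( C(H_{i-1} || payload_digest) mod 64 ) ) mod 2^512
# (C = SHA-512, digests read as big-endian unsigned integers) is carried
# alongside. A site registry acts as the smart-contract layer: only
# registered, authorized, non-blacklisted sites may append, and appends are
# authenticated with an HMAC-SHA-512 over the payload digest under the
# site's registered key.

#' Hex encoding helpers
#'
#' Convert between raw byte vectors and lowercase hex strings (the on-disk
#' and in-memory representation of all 512-bit digests in the ledger).
#'
#' @param r raw vector.
#' @param h hex string of even length.
#' @return `raw_to_hex()` a string; `hex_to_raw()` a raw vector.
#' @export
raw_to_hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

#' @rdname raw_to_hex
#' @export
hex_to_raw <- function(h) {
  if (!is.character(h) || length(h) != 1L || nchar(h) %% 2L != 0L ||
      grepl("[^0-9a-fA-F]", h))
    stop_format("not a valid hex string")
  as.raw(strtoi(substring(h, seq(1L, nchar(h), 2L), seq(2L, nchar(h), 2L)),
                16L))
}

as_bytes <- function(x) {
  if (is.raw(x)) x else if (is.character(x)) charToRaw(paste(x, collapse = ""))
  else stop_config("expected raw bytes or a character string")
}

#' SHA-512 digest
#'
#' Full SHA-512 of a raw vector or UTF-8 string, returned as a
#' 128-character hex string. `compression_digest()` is the ledger-facing
#' alias used when deriving chain checksums.
#'
#' @param data raw vector or single string.
#' @return 128-character lowercase hex digest.
#' @export
sha512_hex <- function(data) raw_to_hex(cpp_sha512(as_bytes(data)))

#' @rdname sha512_hex
#' @export
compression_digest <- function(data) sha512_hex(data)

#' Padded message length under SHA-512 preprocessing
#'
#' SHA-512 extends a message with a single 1 bit, zero padding, and a 128-bit
#' length field so the total is a multiple of 1,024 bits (the block size of
#' the 64-bit-word compression function). Returns that padded length.
#'
#' @param message_length_bits non-negative integer bit length.
#' @return padded length in bits (a positive multiple of 1,024).
#' @export
#' @examples
#' sha512_padded_length(0)    # 1024
#' sha512_padded_length(1000) # 2048
sha512_padded_length <- function(message_length_bits) {
  n <- as.numeric(message_length_bits)
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop_config("message_length_bits must be a single non-negative integer")
  1024 * ceiling((n + 1 + 128) / 1024)
}

#' Chain checksum recurrence
#'
#' Advances the auxiliary ledger checksum: interprets `h_prev` (the previous
#' checksum, `H0` for the first block) and the block's payload digest as
#' 512-bit big-endian integers and computes
#' `H_i = (H_{i-1} + (SHA512(H_{i-1} || payload_digest) mod 64)) mod 2^512`.
#' Successive checksums therefore differ by at most 63.
#'
#' @param h_prev 128-character hex value of the previous checksum.
#' @param payload_digest 128-character hex payload digest.
#' @return 128-character hex value of the new checksum.
#' @export
chain_checksum <- function(h_prev, payload_digest) {
  a <- hex_to_raw(h_prev); b <- hex_to_raw(payload_digest)
  if (length(a) != 64L || length(b) != 64L)
    stop_config("chain_checksum expects 512-bit (64-byte) hex values")
  inc <- as.integer(cpp_sha512(c(a, b))[64L]) %% 64L
  # big-endian 512-bit addition of a value in [0, 63], mod 2^512
  v <- as.integer(a)
  i <- 64L
  carry <- inc
  while (carry > 0L && i >= 1L) {
    s <- v[i] + carry
    v[i] <- s %% 256L
    carry <- s %/% 256L
    i <- i - 1L
  }
  raw_to_hex(as.raw(v))
}

hmac_sha512 <- function(key, data) {
  key <- as_bytes(key); data <- as_bytes(data)
  if (length(key) > 128L) key <- cpp_sha512(key)
  key <- c(key, raw(128L - length(key)))
  ipad <- as.raw(bitwXor(as.integer(key), 0x36L))
  opad <- as.raw(bitwXor(as.integer(key), 0x5cL))
  raw_to_hex(cpp_sha512(c(opad, cpp_sha512(c(ipad, data)))))
}

# ---- canonical serialization ----------------------------------------------

json_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub("\"", "\\\\\"", s)
  gsub("[\x01-\x1f]", "", s)
}

fmt_num <- function(x) {
  if (x == floor(x) && abs(x) < 2^53) sprintf("%.0f", x)
  else sprintf("%.17g", x)
}

# Canonical JSON: keys in fixed sorted order, numbers in pinned formats,
# UTF-8; guarantees bit-identical digests across platforms and sessions.
canonical_payload_json <- function(payload) {
  hp <- payload$hyperparameters
  sprintf(paste0(
    '{"data_digest":"%s",',
    '"hyperparameters":{"batch_size":%d,"epochs":%d,"learning_rate":%s},',
    '"round":%d,"site_id":"%s","timestamp":%.0f,"weights_digest":"%s"}'),
    payload$data_digest, as.integer(hp$batch_size), as.integer(hp$epochs),
    fmt_num(hp$learning_rate), as.integer(payload$round),
    json_escape(payload$site_id), payload$timestamp, payload$weights_digest)
}

canonical_block_json <- function(block) {
  sprintf(paste0(
    '{"chain_checksum":"%s","index":%d,"payload":%s,',
    '"payload_digest":"%s","prev_hash":"%s","signature":"%s"}'),
    block$chain_checksum, block$index,
    canonical_payload_json(block$payload),
    block$payload_digest, block$prev_hash, block$signature)
}

#' Construct a block payload
#'
#' The content a site commits to the ledger for one training round: its
#' identity, the digest of the training-data manifest it used, the
#' hyperparameters, and the digest of the weights it delivers.
#'
#' @param site_id site identifier string.
#' @param round integer training round.
#' @param data_digest 128-char hex digest of the training-data manifest.
#' @param hyperparameters a [hyperparameters()] object (or equivalent list).
#' @param weights_digest 128-char hex digest of the delivered weights.
#' @param timestamp integer epoch seconds.
#' @return an object of class `"block_payload"`.
#' @export
block_payload <- function(site_id, round, data_digest, hyperparameters,
                          weights_digest, timestamp = 0L) {
  if (!is.character(site_id) || length(site_id) != 1L || !nzchar(site_id))
    stop_config("site_id must be a non-empty string")
  for (d in list(data_digest, weights_digest))
    if (nchar(d) != 128L) stop_config("digests must be 512-bit hex values")
  structure(list(site_id = site_id, round = as.integer(round),
                 data_digest = tolower(data_digest),
                 hyperparameters = hyperparameters,
                 weights_digest = tolower(weights_digest),
                 timestamp = as.numeric(timestamp)),
            class = "block_payload")
}

# ---- site registry ("smart contract" layer) --------------------------------

#' Site authorization registry
#'
#' A minimal contract layer deciding which sites may append blocks. Sites
#' register once with a signing key, must be explicitly authorized, and can
#' be blacklisted; blacklisting atomically revokes authorization.
#'
#' @param registry a `"site_registry"`.
#' @param site_id site identifier.
#' @param key raw vector or string: the site's signing key (shared-secret
#'   MAC key; the registry copy is used to verify appended signatures).
#' @param authorized logical.
#' @return an updated `"site_registry"` (functional updates);
#'   `is_authorized()` returns a logical.
#' @export
site_registry <- function() {
  structure(list(sites = list()), class = "site_registry")
}

#' @rdname site_registry
#' @export
register_site <- function(registry, site_id, key) {
  stopifnot(inherits(registry, "site_registry"))
  if (site_id %in% names(registry$sites))
    stop_config("site already registered: ", site_id)
  registry$sites[[site_id]] <- list(key = as_bytes(key), authorized = FALSE,
                                    blacklisted = FALSE)
  registry
}

#' @rdname site_registry
#' @export
set_authorized <- function(registry, site_id, authorized = TRUE) {
  s <- registry$sites[[site_id]]
  if (is.null(s)) stop_config("unknown site: ", site_id)
  if (s$blacklisted && authorized)
    stop_config("cannot authorize a blacklisted site: ", site_id)
  registry$sites[[site_id]]$authorized <- isTRUE(authorized)
  registry
}

#' @rdname site_registry
#' @export
blacklist_site <- function(registry, site_id) {
  if (is.null(registry$sites[[site_id]]))
    stop_config("unknown site: ", site_id)
  registry$sites[[site_id]]$blacklisted <- TRUE
  registry$sites[[site_id]]$authorized <- FALSE
  registry
}

#' @rdname site_registry
#' @export
is_authorized <- function(registry, site_id) {
  s <- registry$sites[[site_id]]
  !is.null(s) && s$authorized && !s$blacklisted
}

# ---- chain -----------------------------------------------------------------

ZERO512 <- strrep("0", 128L)

genesis_marker <- function(h0) sprintf('{"genesis":"%s"}', h0)

#' Create an empty ledger chain
#'
#' @param h0 128-character hex initial checksum value (defaults to zero).
#' @return an object of class `"ledger_chain"`.
#' @export
new_chain <- function(h0 = ZERO512) {
  if (nchar(h0) != 128L) stop_config("h0 must be a 512-bit hex value")
  structure(list(h0 = tolower(h0), blocks = list()), class = "ledger_chain")
}

#' @export
print.ledger_chain <- function(x, ...) {
  cat(sprintf("<ledger_chain> %d block(s), H0 = %s...\n",
              length(x$blocks), substr(x$h0, 1L, 12L)))
  invisible(x)
}

#' @export
length.ledger_chain <- function(x) length(x$blocks)

#' Append a signed block to the chain
#'
#' Authorization is checked against the registry, the payload is canonically
#' serialized and digested, the predecessor hash and checksum recurrence are
#' advanced, and the block is signed with the provided key (which must match
#' the site's registered key).
#'
#' @param chain a [new_chain()].
#' @param payload a [block_payload()].
#' @param registry a [site_registry()].
#' @param signing_key the appending site's key.
#' @return the extended `"ledger_chain"`.
#' @export
append_block <- function(chain, payload, registry, signing_key) {
  stopifnot(inherits(chain, "ledger_chain"),
            inherits(registry, "site_registry"))
  sid <- payload$site_id
  s <- registry$sites[[sid]]
  if (is.null(s) || !s$authorized || s$blacklisted)
    stop(structure(class = c("segfed_auth_error", "error", "condition"),
                   list(message = paste0("site not authorized to append: ",
                                         sid), call = sys.call())))
  payload_digest <- sha512_hex(canonical_payload_json(payload))
  signature <- hmac_sha512(signing_key, hex_to_raw(payload_digest))
  if (signature != hmac_sha512(s$key, hex_to_raw(payload_digest)))
    stop(structure(class = c("segfed_signature_error", "error", "condition"),
                   list(message = paste0("signature does not verify for ",
                                         sid), call = sys.call())))
  nb <- length(chain$blocks)
  prev_hash <- if (nb == 0L) sha512_hex(genesis_marker(chain$h0))
  else sha512_hex(canonical_block_json(chain$blocks[[nb]]))
  h_prev <- if (nb == 0L) chain$h0 else chain$blocks[[nb]]$chain_checksum
  block <- list(index = nb, prev_hash = prev_hash, payload = payload,
                payload_digest = payload_digest,
                chain_checksum = chain_checksum(h_prev, payload_digest),
                signature = signature)
  chain$blocks[[nb + 1L]] <- block
  chain
}

#' Verify the integrity of a chain
#'
#' Recomputes every block's payload digest, predecessor-hash linkage,
#' checksum recurrence and signature. Never throws on tampered data: it
#' returns the indices (as stored in the blocks, 0-based) of all blocks
#' failing any check; an empty vector means the chain is intact.
#'
#' @param chain a `"ledger_chain"`.
#' @param registry the [site_registry()] holding verification keys.
#' @return integer vector of offending block indices (possibly empty).
#' @export
verify_chain <- function(chain, registry) {
  bad <- integer(0)
  prev_hash <- sha512_hex(genesis_marker(chain$h0))
  h_prev <- chain$h0
  for (i in seq_along(chain$blocks)) {
    blk <- chain$blocks[[i]]
    ok <- TRUE
    pd <- tryCatch(sha512_hex(canonical_payload_json(blk$payload)),
                   error = function(e) NA_character_)
    if (is.na(pd) || !identical(pd, blk$payload_digest)) ok <- FALSE
    if (!identical(blk$prev_hash, prev_hash)) ok <- FALSE
    if (!identical(blk$index, i - 1L) && !identical(blk$index, as.numeric(i - 1L)))
      ok <- FALSE
    if (ok && !identical(blk$chain_checksum,
                         chain_checksum(h_prev, blk$payload_digest)))
      ok <- FALSE
    s <- registry$sites[[blk$payload$site_id]]
    if (is.null(s) ||
        !is.na(pd) && !identical(blk$signature,
                                 hmac_sha512(s$key, hex_to_raw(pd))))
      ok <- FALSE
    if (!ok) bad <- c(bad, as.integer(i - 1L))
    prev_hash <- sha512_hex(canonical_block_json(blk))
    h_prev <- blk$chain_checksum
  }
  bad
}

#' Persist / load a chain as JSON lines
#'
#' One block per line; digests are hex strings, so files are plain text and
#' platform independent.
#'
#' @param chain a `"ledger_chain"`.
#' @param path file path.
#' @return `read_chain()` returns a `"ledger_chain"`; `write_chain()` the
#'   path, invisibly.
#' @export
write_chain <- function(chain, path) {
  header <- sprintf('{"h0":"%s"}', chain$h0)
  lines <- vapply(chain$blocks, canonical_block_json, "")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_format("empty chain file: ", path)
  h0 <- jsonlite::fromJSON(lines[1L])$h0
  chain <- new_chain(h0)
  for (ln in lines[-1L]) {
    b <- jsonlite::fromJSON(ln)
    payload <- block_payload(b$payload$site_id, b$payload$round,
                             b$payload$data_digest,
                             hyperparameters(b$payload$hyperparameters$learning_rate,
                                             b$payload$hyperparameters$epochs,
                                             b$payload$hyperparameters$batch_size),
                             b$payload$weights_digest,
                             b$payload$timestamp)
    chain$blocks[[length(chain$blocks) + 1L]] <-
      list(index = as.integer(b$index), prev_hash = b$prev_hash,
           payload = payload, payload_digest = b$payload_digest,
           chain_checksum = b$chain_checksum, signature = b$signature)
  }
  chain
}
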