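# Orchestration of the full simulated workflow: per-architecture GA tuning,
# per-site local training, ledger logging of every model update, plurality
# fusion of the local models, and the attack-detection experiment contrasting
# audited (hash-chain verified) and unaudited runs.

#' Attack model configuration
#'
#' Defines which synthetic attacks are injected into the update stream and at
#' what rate. Types: `"payload_tamper"` (flip a random bit in a stored block
#' field after append), `"stale_link"` (corrupt a block's predecessor hash),
#' `"unauthorized_site"` (append attempt from an unregistered site),
#' `"weight_poison"` (perturb the delivered weight bytes after their digest
#' was committed).
#'
#' @param attack_rate probability in `[0, 1]` that an update is attacked.
#' @param attack_types subset of the four type names (non-empty when
#'   `attack_rate > 0`).
#' @param seed RNG seed for attack placement.
#' @return an object of class `"attack_config"`.
#' @export
attack_config <- function(attack_rate = 0.3,
                          attack_types = c("payload_tamper", "stale_link",
                                           "unauthorized_site",
                                           "weight_poison"),
                          seed = 1L) {
  known <- c("payload_tamper", "stale_link", "unauthorized_site",
             "weight_poison")
  bad <- setdiff(attack_types, known)
  if (length(bad)) stop_config("unknown attack type(s): ",
                               paste(bad, collapse = ", "))
  if (attack_rate < 0 || attack_rate > 1)
    stop_config("attack_rate must lie in [0, 1]")
  if (attack_rate > 0 && !length(attack_types))
    stop_config("attack_types must be non-empty when attack_rate > 0")
  structure(list(attack_rate = attack_rate, attack_types = attack_types,
                 seed = as.integer(seed)), class = "attack_config")
}

#' Federated run configuration
#'
#' @param n_sites number of data-holding sites (>= 1); training data is
#'   split into contiguous equal shards after a seeded shuffle and the four
#'   architectures are assigned to sites round-robin.
#' @param data_fraction_percent training bucket to use: one of
#'   20, 40, 60, 80, 100.
#' @param architectures model families to train and fuse.
#' @param depth,base_width architecture size shared by all families.
#' @param ga a [ga_config()] controlling the per-architecture tuning budget.
#' @param ga_space a [search_space()]; keep the epoch range modest, it bounds
#'   the final training budget too.
#' @param ga_subset_size training samples per GA fitness evaluation.
#' @param attack an [attack_config()] (used by [detection_experiment()]).
#' @param val_frac,test_frac held-out fractions.
#' @param threshold vote/mask binarisation threshold.
#' @param seed master seed for the run.
#' @return an object of class `"federated_config"`.
#' @export
federated_config <- function(n_sites = 1L, data_fraction_percent = 100L,
                             architectures = c("unet", "unetpp", "unet3p",
                                               "nasunet"),
                             depth = 3L, base_width = 8L,
                             ga = ga_config(population_size = 5L,
                                            generations = 3L,
                                            tournament_size = 3L),
                             ga_space = search_space(
                               lr_range = c(5e-3, 0.3),
                               epochs_range = c(2L, 8L),
                               batch_range = c(2L, 16L)),
                             ga_subset_size = 24L,
                             attack = attack_config(),
                             val_frac = 0.15, test_frac = 0.15,
                             threshold = 0.5, seed = 1L) {
  if (n_sites < 1L) stop_config("n_sites must be >= 1")
  if (!data_fraction_percent %in% c(20, 40, 60, 80, 100))
    stop_config("data_fraction_percent must be one of 20/40/60/80/100")
  structure(list(n_sites = as.integer(n_sites),
                 data_fraction_percent = as.integer(data_fraction_percent),
                 architectures = architectures, depth = as.integer(depth),
                 base_width = as.integer(base_width), ga = ga,
                 ga_space = ga_space,
                 ga_subset_size = as.integer(ga_subset_size),
                 attack = attack, val_frac = val_frac, test_frac = test_frac,
                 threshold = threshold, seed = as.integer(seed)),
            class = "federated_config")
}

site_key <- function(seed, site_id) {
  cpp_sha512(charToRaw(paste0("site-key:", seed, ":", site_id)))
}

manifest_digest <- function(ids) {
  sha512_hex(paste(sort(ids), collapse = "\n"))
}

#' Run the full simulated federated pipeline
#'
#' For each architecture: tune learning rate, epochs and batch size with the
#' genetic algorithm on the assigned site's shard, train the final local
#' model with the winning genes, and append a signed ledger block recording
#' the site, the data-manifest digest, the hyperparameters and the trained
#' weights digest. The local models are then fused by per-pixel plurality
#' voting on the held-out test set, and the chain is verified.
#'
#' @param config a [federated_config()].
#' @param samples dataset, e.g. from [generate_dataset()].
#' @return object of class `"fed_summary"`: `per_arch` data frame (best
#'   genes, validation and test IoU per architecture), `ensemble_iou`,
#'   `model_fits`, `chain`, `registry`, `buckets`, `chain_ok`.
#' @export
run_pipeline <- function(config, samples) {
  stopifnot(inherits(config, "federated_config"))
  buckets <- make_buckets(samples, config$val_frac, config$test_frac,
                          seed = derive_seed(config$seed, 7L))
  by_id <- setNames(samples, vapply(samples, function(s) s$sample_id, ""))
  bucket_idx <- match(config$data_fraction_percent, buckets$bucket_percent)
  train_ids <- buckets$train_buckets[[bucket_idx]]
  val_samples <- by_id[buckets$val_ids]
  test_samples <- by_id[buckets$test_ids]

  # contiguous equal shards after a seeded shuffle
  shuffled <- with_seed(derive_seed(config$seed, 11L), sample(train_ids))
  shard_of <- rep(seq_len(config$n_sites), length.out = length(shuffled))
  shard_of <- sort(shard_of)
  shards <- split(shuffled, shard_of)

  registry <- site_registry()
  sites <- paste0("site_", seq_len(config$n_sites))
  for (s in sites) {
    registry <- register_site(registry, s, site_key(config$seed, s))
    registry <- set_authorized(registry, s)
  }
  chain <- new_chain()

  fits <- list()
  rows <- NULL
  for (i in seq_along(config$architectures)) {
    fam <- config$architectures[[i]]
    site_i <- (i - 1L) %% config$n_sites + 1L
    shard <- by_id[shards[[site_i]]]
    if (!length(shard)) stop_config("site ", site_i, " received no data")
    spec <- architecture_spec(fam, depth = config$depth,
                              base_width = config$base_width)
    ga_train <- shard[seq_len(min(config$ga_subset_size, length(shard)))]
    ga_val <- val_samples[seq_len(min(12L, length(val_samples)))]
    eval_fn <- function(genes, seed) {
      hp <- hyperparameters(genes$learning_rate, genes$epochs,
                            min(genes$batch_size, length(ga_train)))
      m <- build_model(spec, seed = derive_seed(seed, 1L))
      fit <- train_segnet(m, ga_train, ga_val, hp, seed = seed)
      fit$final_val_loss
    }
    cfg_i <- config$ga
    cfg_i$seed <- derive_seed(config$seed, 100L + i)
    tuned <- run_ga(config$ga_space, cfg_i, eval_fn)
    best <- tuned$best$genes
    hp <- hyperparameters(best$learning_rate, best$epochs,
                          min(best$batch_size, length(shard)))
    model <- build_model(spec, seed = derive_seed(config$seed, 200L + i))
    fit <- train_segnet(model, shard, val_samples, hp,
                        seed = derive_seed(config$seed, 300L + i),
                        threshold = config$threshold)
    payload <- block_payload(sites[site_i], round = i,
                             data_digest = manifest_digest(names(shard)),
                             hyperparameters = hp,
                             weights_digest = fit$weights_digest,
                             timestamp = i)
    chain <- append_block(chain, payload, registry,
                          site_key(config$seed, sites[site_i]))
    fits[[fam]] <- fit
    rows <- rbind(rows, data.frame(
      family = fam, site = sites[site_i], learning_rate = hp$learning_rate,
      epochs = hp$epochs, batch_size = hp$batch_size,
      val_iou = fit$val_iou,
      test_iou = evaluate_model(fit, test_samples, config$threshold)))
  }

  fused_iou <- mean(vapply(test_samples, function(s)
    iou(s$mask, ensemble_predict(fits, s$image, config$threshold)), 0))

  structure(list(per_arch = rows, ensemble_iou = fused_iou,
                 model_fits = fits, chain = chain, registry = registry,
                 buckets = buckets,
                 chain_ok = length(verify_chain(chain, registry)) == 0L,
                 config = config),
            class = "fed_summary")
}

#' @export
print.fed_summary <- function(x, ...) {
  cat(sprintf("<fed_summary> %d architecture(s), %d site(s), chain %s\n",
              nrow(x$per_arch), x$config$n_sites,
              if (x$chain_ok) "verified" else "NOT verified"))
  print(x$per_arch, row.names = FALSE, digits = 3)
  cat(sprintf("  ensemble IoU on test set: %.3f\n", x$ensemble_iou))
  invisible(x)
}

# ---- attack injection and detection ----------------------------------------

random_digest_hex <- function() {
  raw_to_hex(as.raw(sample.int(256L, 64L, replace = TRUE) - 1L))
}

flip_bit_in_raw <- function(r) {
  pos <- sample.int(length(r), 1L)
  bit <- sample.int(8L, 1L) - 1L
  r[pos] <- as.raw(bitwXor(as.integer(r[pos]), bitwShiftL(1L, bit)))
  r
}

# Flip one low bit (0-6) of one character: the mutated string stays valid
# ASCII so it flows through serialization like any attacker-written value.
flip_char_bit <- function(s) {
  b <- charToRaw(s)
  repeat {
    pos <- sample.int(length(b), 1L)
    bit <- sample.int(7L, 1L) - 1L
    nb <- bitwXor(as.integer(b[pos]), bitwShiftL(1L, bit))
    if (nb != 0L) break
  }
  b[pos] <- as.raw(nb)
  rawToChar(b)
}

tamper_payload <- function(payload) {
  field <- sample(c("data_digest", "weights_digest", "learning_rate",
                    "epochs", "batch_size", "round", "site_id"), 1L)
  if (field %in% c("data_digest", "weights_digest")) {
    payload[[field]] <- flip_char_bit(payload[[field]])
  } else if (field == "learning_rate") {
    b <- writeBin(payload$hyperparameters$learning_rate, raw(),
                  size = 8L, endian = "little")
    payload$hyperparameters$learning_rate <-
      readBin(flip_bit_in_raw(b), "double", 1L, size = 8L, endian = "little")
  } else if (field %in% c("epochs", "batch_size")) {
    v <- payload$hyperparameters[[field]]
    payload$hyperparameters[[field]] <-
      bitwXor(v, bitwShiftL(1L, sample.int(12L, 1L) - 1L))
  } else if (field == "round") {
    payload$round <- bitwXor(payload$round, bitwShiftL(1L, sample.int(12L, 1L) - 1L))
  } else {
    payload$site_id <- flip_char_bit(payload$site_id)
  }
  payload
}

# A simulated update: everything a site delivers for one round — the payload
# plus the actual weight bytes whose digest the payload commits to.
simulate_updates <- function(n_updates, n_sites, seed) {
  with_seed(seed, {
    sites <- paste0("site_", rep_len(seq_len(n_sites), n_updates))
    lapply(seq_len(n_updates), function(i) {
      wbytes <- as.raw(sample.int(256L, 128L, replace = TRUE) - 1L)
      hp <- hyperparameters(stats::runif(1L, 1e-3, 0.9),
                            sample.int(30L, 1L), sample.int(16L, 1L))
      list(site_id = sites[i], round = i,
           payload = block_payload(sites[i], i, random_digest_hex(), hp,
                                   sha512_hex(wbytes), timestamp = i),
           weights = wbytes)
    })
  })
}

#' Inject attacks into an update stream
#'
#' Each update is independently attacked with probability
#' `attack_cfg$attack_rate`; the attack type is drawn uniformly from
#' `attack_types`. Returns the attacked stream plus the ground-truth log of
#' which update was hit by what (empty at rate 0). Seeded: identical inputs
#' give identical logs.
#'
#' @param updates update stream from the pipeline (or simulated internally
#'   by [detection_experiment()]).
#' @param attack_cfg an [attack_config()].
#' @return list with `updates` (possibly modified; unauthorized-site attacks
#'   add an intruder update) and `log` (data frame of index + type).
#' @export
inject_attacks <- function(updates, attack_cfg) {
  stopifnot(inherits(attack_cfg, "attack_config"))
  with_seed(attack_cfg$seed, {
    log <- NULL
    for (i in seq_along(updates)) {
      if (stats::runif(1L) < attack_cfg$attack_rate) {
        type <- if (length(attack_cfg$attack_types) == 1L)
          attack_cfg$attack_types else sample(attack_cfg$attack_types, 1L)
        updates[[i]]$attack <- type
        if (type == "payload_tamper") {
          updates[[i]]$tampered_payload <- tamper_payload(updates[[i]]$payload)
        } else if (type == "stale_link") {
          updates[[i]]$stale_hash <- random_digest_hex()
        } else if (type == "unauthorized_site") {
          updates[[i]]$intruder_id <- paste0("intruder_", i)
        } else if (type == "weight_poison") {
          updates[[i]]$weights <- flip_bit_in_raw(updates[[i]]$weights)
        }
        log <- rbind(log, data.frame(index = i, type = type))
      }
    }
    list(updates = updates,
         log = if (is.null(log)) data.frame(index = integer(0),
                                            type = character(0)) else log)
  })
}

payload_schema_ok <- function(payload) {
  hp <- payload$hyperparameters
  is.character(payload$site_id) && nzchar(payload$site_id) &&
    is.numeric(payload$round) && payload$round >= 1 &&
    grepl("^[0-9a-f]{128}$", payload$data_digest) &&
    grepl("^[0-9a-f]{128}$", payload$weights_digest) &&
    is.finite(hp$learning_rate) && hp$learning_rate > 0 &&
    hp$learning_rate <= 1 && hp$epochs >= 1 && hp$batch_size >= 1
}

attack_report <- function(log, detected_idx, blockchain_enabled) {
  injected <- nrow(log)
  detected <- sum(log$index %in% detected_idx)
  per_type <- if (injected) {
    agg <- stats::aggregate(list(injected = log$index),
                            by = list(type = log$type), FUN = length)
    agg$detected <- vapply(agg$type, function(tp)
      sum(log$index[log$type == tp] %in% detected_idx), 0L)
    agg
  } else data.frame(type = character(0), injected = integer(0),
                    detected = integer(0))
  structure(list(injected = injected, detected = detected,
                 detection_rate = if (injected) 100 * detected / injected
                 else NULL,
                 per_type = per_type,
                 blockchain_enabled = blockchain_enabled),
            class = "attack_report")
}

#' @export
print.attack_report <- function(x, ...) {
  cat(sprintf("<attack_report> ledger %s: %d/%d attacks detected (%s)\n",
              if (x$blockchain_enabled) "ON" else "OFF",
              x$detected, x$injected,
              if (is.null(x$detection_rate)) "rate undefined"
              else sprintf("%.1f%%", x$detection_rate)))
  invisible(x)
}

run_detection_once <- function(n_updates, n_sites, attack_cfg, seed) {
  updates <- simulate_updates(n_updates, n_sites, seed)
  attacked <- inject_attacks(updates, attack_cfg)
  updates <- attacked$updates
  log <- attacked$log

  registry <- site_registry()
  for (s in paste0("site_", seq_len(n_sites))) {
    registry <- register_site(registry, s, site_key(seed, s))
    registry <- set_authorized(registry, s)
  }

  chain <- new_chain()
  rejected_at_append <- integer(0)   # ledger-side registry rejections
  block_of_update <- rep(NA_integer_, length(updates))
  for (i in seq_along(updates)) {
    u <- updates[[i]]
    if (!is.null(u$intruder_id)) {
      # intruder replays the payload under its own unregistered identity
      bad_payload <- u$payload
      bad_payload$site_id <- u$intruder_id
      ok <- tryCatch({
        append_block(chain, bad_payload, registry,
                     cpp_sha512(charToRaw(u$intruder_id)))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) rejected_at_append <- c(rejected_at_append, i)
      next
    }
    chain <- append_block(chain, u$payload, registry, site_key(seed, u$site_id))
    block_of_update[i] <- length(chain$blocks)
    # post-append storage tampering
    if (!is.null(u$tampered_payload))
      chain$blocks[[length(chain$blocks)]]$payload <- u$tampered_payload
    if (!is.null(u$stale_hash))
      chain$blocks[[length(chain$blocks)]]$prev_hash <- u$stale_hash
  }

  # audited condition: full chain verification, registry rejections, and
  # recomputation of each delivered weight blob's digest
  flagged <- verify_chain(chain, registry)
  detected_on <- rejected_at_append
  for (i in seq_along(updates)) {
    bi <- block_of_update[i]
    if (is.na(bi)) next
    blk <- chain$blocks[[bi]]
    if ((blk$index %in% flagged) ||
        sha512_hex(updates[[i]]$weights) != blk$payload$weights_digest)
      detected_on <- c(detected_on, i)
  }

  # unaudited condition: schema validation of delivered payloads only
  detected_off <- integer(0)
  for (i in seq_along(updates)) {
    u <- updates[[i]]
    pl <- if (!is.null(u$tampered_payload)) u$tampered_payload else u$payload
    if (!is.null(u$intruder_id)) pl$site_id <- u$intruder_id
    if (!payload_schema_ok(pl)) detected_off <- c(detected_off, i)
  }

  list(on = attack_report(log, detected_on, TRUE),
       off = attack_report(log, detected_off, FALSE))
}

#' Attack-detection experiment with and without ledger verification
#'
#' Simulates an update stream per training-data bucket, injects attacks per
#' the config, and reports the percentage detected under two conditions:
#' ledger verification ON (chain verification + registry rejections + weight
#' digest recomputation) and OFF (schema validation of payloads only). The
#' ON checks subsume the OFF checks, so the ON rate dominates for every
#' bucket; payload tampering and stale links are always caught when ON.
#'
#' @param config a [federated_config()] (supplies `attack`, `n_sites`,
#'   `seed`).
#' @param bucket_percents data buckets to report, as percentages.
#' @param updates_per_100 update-stream length at the 100% bucket; buckets
#'   scale it proportionally.
#' @return object of class `"detection_experiment"`: `table` (percent,
#'   with_blockchain, without_blockchain rates) and per-bucket
#'   `"attack_report"` pairs.
#' @export
detection_experiment <- function(config,
                                 bucket_percents = c(20, 40, 60, 80, 100),
                                 updates_per_100 = 40L) {
  stopifnot(inherits(config, "federated_config"))
  reports <- list()
  tab <- NULL
  for (p in bucket_percents) {
    n_up <- max(4L, as.integer(round(updates_per_100 * p / 100)))
    acfg <- config$attack
    acfg$seed <- derive_seed(config$seed, 500L + p)
    res <- run_detection_once(n_up, config$n_sites, acfg,
                              seed = derive_seed(config$seed, 600L + p))
    reports[[as.character(p)]] <- res
    tab <- rbind(tab, data.frame(
      percent_of_data = p,
      injected = res$on$injected,
      with_blockchain = if (is.null(res$on$detection_rate)) NA
      else res$on$detection_rate,
      without_blockchain = if (is.null(res$off$detection_rate)) NA
      else res$off$detection_rate))
  }
  structure(list(table = tab, reports = reports, config = config),
            class = "detection_experiment")
}

#' @export
print.detection_experiment <- function(x, ...) {
  cat("Percentage of detected attacks, ledger verification on vs off\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a side-by-side input / truth / prediction panel
#'
#' Composes a 3-panel greyscale PNG (input image, ground-truth mask,
#' predicted mask) separated by thin white gutters.
#'
#' @param image `H x W` intensity matrix.
#' @param gt_mask,pred_mask binary `H x W` masks.
#' @param path output PNG path.
#' @param gutter separator width in pixels.
#' @return `path`, invisibly.
#' @export
render_panel <- function(image, gt_mask, pred_mask, path, gutter = 2L) {
  if (!identical(dim(image), dim(gt_mask)) ||
      !identical(dim(image), dim(pred_mask)))
    stop_config("image and masks must share the same dimensions")
  sep <- matrix(1, nrow(image), gutter)
  panel <- cbind(image, sep, gt_mask, sep, pred_mask)
  png::writePNG(pmin(pmax(panel, 0), 1), path)
  invisible(path)
}
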