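test_that("attack injection is seeded, rate-faithful at the extremes, and typed", {
  cfg0 <- attack_config(attack_rate = 0, seed = 1)
  ups <- segfed:::simulate_updates(10, 2, seed = 5)
  expect_identical(nrow(inject_attacks(ups, cfg0)$log), 0L)

  cfg1 <- attack_config(attack_rate = 1, seed = 2)
  res <- inject_attacks(ups, cfg1)
  expect_identical(nrow(res$log), 10L)
  expect_true(all(res$log$type %in% cfg1$attack_types))
  expect_identical(inject_attacks(ups, cfg1)$log, res$log)

  expect_error(attack_config(attack_rate = 1.2), "attack_rate")
  expect_error(attack_config(attack_types = "meteor"), "unknown attack type")
  expect_error(attack_config(attack_rate = 0.5, attack_types = character(0)),
               "non-empty")
})

test_that("audited detection catches all payload tampering and stale links", {
  cfg <- federated_config(
    n_sites = 2, seed = 3,
    attack = attack_config(attack_rate = 0.5,
                           attack_types = c("payload_tamper", "stale_link")))
  res <- segfed:::run_detection_once(30, 2, cfg$attack, seed = 9)
  expect_gt(res$on$injected, 0)
  expect_identical(res$on$detected, res$on$injected)
  expect_equal(res$on$detection_rate, 100)
})

test_that("detection with the ledger dominates the schema-only baseline per bucket", {
  cfg <- federated_config(n_sites = 2, seed = 6,
                          attack = attack_config(attack_rate = 0.4, seed = 6))
  exp <- detection_experiment(cfg, bucket_percents = c(20, 60, 100),
                              updates_per_100 = 30)
  tab <- exp$table
  expect_identical(tab$percent_of_data, c(20, 60, 100))
  ok <- !is.na(tab$with_blockchain)
  expect_true(all(tab$with_blockchain[ok] >= tab$without_blockchain[ok]))
  # weight poisoning and unauthorized appends are ledger-detectable
  r100 <- exp$reports[["100"]]$on$per_type
  full <- r100$type %in% c("payload_tamper", "stale_link", "weight_poison",
                           "unauthorized_site")
  expect_identical(r100$detected[full], r100$injected[full])
})

test_that("zero injected attacks reports an undefined (null) rate, not 0", {
  cfg <- attack_config(attack_rate = 0, seed = 1)
  res <- segfed:::run_detection_once(8, 1, cfg, seed = 2)
  expect_identical(res$on$injected, 0L)
  expect_null(res$on$detection_rate)
  expect_null(res$off$detection_rate)
})

test_that("render_panel lays out input | truth | prediction and round-trips", {
  ds <- tiny_dataset(1, seed = 55, size = c(32L, 32L))
  s <- ds[[1]]
  path <- withr::local_tempfile(fileext = ".png")
  render_panel(s$image, s$mask, s$mask, path)
  img <- png::readPNG(path)
  expect_identical(nrow(img), 32L)
  expect_identical(ncol(img), 3L * 32L + 2L * 2L)
  # gt == pred: middle and right panels identical
  expect_identical(img[, 35:66], img[, 69:100])
  expect_error(render_panel(s$image, s$mask, matrix(0, 16, 16), path),
               "dimensions")
})

test_that("a scaled-down clean pipeline trains, fuses, logs and verifies", {
  ds <- tiny_dataset(60, seed = 77)
  cfg <- federated_config(
    n_sites = 2, architectures = c("unet", "nasunet"), depth = 2,
    base_width = 6,
    ga = ga_config(population_size = 3L, generations = 1L,
                   tournament_size = 2L),
    ga_space = search_space(c(0.01, 0.2), c(2L, 4L), c(2L, 8L)),
    ga_subset_size = 10L, seed = 8)
  res <- run_pipeline(cfg, ds)
  expect_identical(length(res$chain), 2L)       # one block per architecture
  expect_true(res$chain_ok)
  expect_true(all(res$per_arch$test_iou >= 0 & res$per_arch$test_iou <= 1))
  expect_true(res$ensemble_iou >= 0 && res$ensemble_iou <= 1)
  expect_identical(sort(unique(res$per_arch$site)), c("site_1", "site_2"))
  # the chain records the hyperparameters the GA selected
  expect_identical(res$chain$blocks[[1]]$payload$hyperparameters$epochs,
                   res$per_arch$epochs[1])
})
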