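test_that("generation honours the config contract", {
  expect_length(generate_dataset(synthetic_config(0)), 0)

  cfg <- synthetic_config(50, fg_fraction_range = c(0.05, 0.25), seed = 5)
  ds <- generate_dataset(cfg)
  expect_length(ds, 50)
  fr <- vapply(ds, function(s) mean(s$mask), 0)
  expect_true(all(fr >= 0.05 & fr <= 0.25))
  for (s in ds) {
    expect_identical(dim(s$image), dim(s$mask))
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(sum(s$mask) >= 1 && sum(s$mask) < length(s$mask))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("identical configs generate bit-identical datasets", {
  for (fam in c("ellipse", "tube", "multi_blob")) {
    cfg <- synthetic_config(6, shape_family = fam, seed = 77)
    expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  }
})

test_that("invalid configs name the offending field", {
  expect_error(synthetic_config(-1), "n_images")
  expect_error(synthetic_config(3, image_size = c(8, 32)), "image_size")
  expect_error(synthetic_config(3, fg_fraction_range = c(0, 0.2)),
               "fg_fraction_range")
  expect_error(synthetic_config(3, fg_fraction_range = c(0.3, 0.2)),
               "fg_fraction_range")
  expect_error(synthetic_config(3, noise_sigma = -1), "noise_sigma")
})

test_that("buckets are nested, disjoint from holdouts, and deterministic", {
  ds <- tiny_dataset(100, seed = 3, size = c(16L, 16L))
  bk <- make_buckets(ds, val_frac = 0.1, test_frac = 0.1, seed = 4)
  expect_identical(lengths(bk$train_buckets), c(16L, 32L, 48L, 64L, 80L))
  for (k in 1:4)
    expect_true(all(bk$train_buckets[[k]] %in% bk$train_buckets[[k + 1]]))
  all_train <- bk$train_buckets[[5]]
  expect_length(intersect(all_train, bk$val_ids), 0)
  expect_length(intersect(all_train, bk$test_ids), 0)
  expect_length(intersect(bk$val_ids, bk$test_ids), 0)
  expect_setequal(c(all_train, bk$val_ids, bk$test_ids),
                  vapply(ds, function(s) s$sample_id, ""))
  expect_identical(bk, make_buckets(ds, 0.1, 0.1, seed = 4))
  expect_error(make_buckets(ds[1:6], 0.3, 0.3, seed = 1), "5 buckets")
})

test_that("PNG round-trip is lossless for masks and 8-bit for images", {
  ds <- tiny_dataset(10, seed = 21, size = c(16L, 16L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_length(back, 10)
  for (i in seq_along(ds)) {
    expect_identical(back[[i]]$mask, ds[[i]]$mask)
    expect_lt(max(abs(back[[i]]$image - ds[[i]]$image)), 1 / 255)
  }
  expect_length(read_dataset(withr::local_tempdir()), 0)

  file.remove(file.path(dir, "masks", paste0(ds[[3]]$sample_id, ".png")))
  expect_error(read_dataset(dir), ds[[3]]$sample_id)
})
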