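test_that("iou handles identity, disjoint, overlap and the empty convention", {
  set.seed(2)
  m <- random_mask()
  expect_equal(iou(m, m), 1)
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(iou(a, b), 0)
  d <- matrix(0, 4, 4); d[1:2, 2:3] <- 1
  expect_equal(iou(a, d), 2 / 6)
  expect_equal(iou(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(iou(matrix(0, 3, 3), matrix(0, 4, 4)), "dimensions")
  expect_error(iou(matrix(2, 3, 3), matrix(0, 3, 3)), "binary")
})

test_that("iou matches the set-enumeration oracle and is symmetric/bounded", {
  set.seed(31)
  for (i in 1:200) {
    u <- random_mask(8, 8, runif(1, 0.1, 0.9))
    v <- random_mask(8, 8, runif(1, 0.1, 0.9))
    x <- iou(u, v)
    expect_equal(x, iou_oracle(u, v))
    expect_equal(x, iou(v, u))
    expect_true(x >= 0 && x <= 1)
    expect_identical(x == 1, identical(u, v) ||
                       (sum(u) == 0 && sum(v) == 0))
  }
})

test_that("predict_mask uses a strict threshold and evaluate averages IoU", {
  m <- build_model(architecture_spec("unet", depth = 2, base_width = 4),
                   seed = 3)
  set.seed(4)
  img <- matrix(runif(256), 16, 16)
  p <- forward(m, img)
  t0 <- p[5, 5]
  msk <- predict_mask(m, img, threshold = t0)
  expect_identical(msk[5, 5], 0)           # p > t is strict: equality -> 0
  msk2 <- predict_mask(m, img, threshold = t0 - 1e-9)
  expect_identical(msk2[5, 5], 1)
  expect_identical(predict_mask(m, img, 0.5), (p > 0.5) * 1)

  ds <- tiny_dataset(6, seed = 9, size = c(16L, 16L))
  ev <- evaluate_model(m, ds)
  expect_equal(ev, mean(vapply(ds, function(s)
    iou(s$mask, predict_mask(m, s$image)), 0)))
  expect_equal(evaluate_model(m, rev(ds)), ev)   # permutation invariance
  expect_error(evaluate_model(m, list()), "empty")
})

test_that("training contracts: epoch bookkeeping, zero-step limit, batch guard", {
  ds <- tiny_dataset(12, seed = 15, size = c(16L, 16L))
  tr <- ds[1:8]; va <- ds[9:12]
  m <- build_model(architecture_spec("unet", depth = 2, base_width = 4),
                   seed = 2)
  init_loss <- mean(vapply(va, function(s) {
    z <- segfed:::forward_one(m, s$image)$out
    segfed:::bce_logits(z, array(s$mask, dim = dim(z)))$loss
  }, 0))
  fit0 <- train_segnet(m, tr, va, hyperparameters(1e-12, 1, 4), seed = 1)
  expect_lt(abs(fit0$final_val_loss - init_loss), 1e-6)

  fit <- train_segnet(m, tr, va, hyperparameters(0.05, 3, 4), seed = 1)
  expect_length(fit$per_epoch_loss, 3)
  expect_identical(fit$weights_digest, weights_digest(fit$model))
  refit <- train_segnet(m, tr, va, hyperparameters(0.05, 3, 4), seed = 1)
  expect_identical(refit$weights_digest, fit$weights_digest)

  expect_error(train_segnet(m, tr, va, hyperparameters(0.05, 1, 100)),
               "batch_size")
  expect_error(hyperparameters(1.5, 1, 1), "learning_rate")
  expect_error(hyperparameters(0.1, 0, 1), "epochs")
})

test_that("SGD on the synthetic task reaches high IoU and beats the untrained net", {
  ds <- generate_dataset(synthetic_config(200, seed = 7))
  tr <- ds[1:160]; va <- ds[161:200]
  hp <- hyperparameters(1e-2, 30, 8)
  wins <- 0; improved <- 0
  for (sd in 1:5) {
    m <- build_model(architecture_spec("unet", depth = 3, base_width = 8),
                     seed = sd)
    before <- evaluate_model(m, va)
    fit <- train_segnet(m, tr, va, hp, seed = sd)
    if (fit$val_iou >= 0.8) wins <- wins + 1
    if (fit$val_iou > before) improved <- improved + 1
  }
  expect_gte(wins, 3)       # majority of 5 seeds
  expect_gte(improved, 4)
})
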