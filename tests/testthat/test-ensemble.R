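test_that("plurality fusion matches the counting oracle, with tie rule by mean probability", {
  # forced tie cases at a single pixel
  mk_panel <- function(probs) vote_panel(array(probs, dim = c(1, 1, 4)))
  expect_identical(majority_vote(mk_panel(c(0.9, 0.8, 0.7, 0.1)))[1, 1], 1)
  expect_identical(majority_vote(mk_panel(c(0.9, 0.79, 0.4, 0.39)))[1, 1], 1)  # mean 0.62
  expect_identical(majority_vote(mk_panel(c(0.61, 0.51, 0.2, 0.2)))[1, 1], 0)  # mean 0.38
  expect_identical(majority_vote(mk_panel(c(0.75, 0.75, 0.25, 0.25)))[1, 1], 0) # mean exactly 0.5

  set.seed(20)
  for (i in 1:150) {
    M <- sample(c(1, 3, 4, 5), 1)
    pr <- array(runif(6 * 6 * M), dim = c(6, 6, M))
    pan <- vote_panel(pr)
    expect_identical(majority_vote(pan), vote_oracle(pr))
    # permutation symmetry
    perm <- sample(M)
    expect_identical(majority_vote(vote_panel(pr[, , perm, drop = FALSE])),
                     majority_vote(pan))
    # unanimity preservation
    agree <- apply(pan$binary_votes, c(1, 2), function(v) length(unique(v)) == 1)
    fused <- majority_vote(pan)
    expect_identical(fused[agree], pan$binary_votes[, , 1][agree])
  }
})

test_that("flipping one vote 0 -> 1 never flips a fused pixel 1 -> 0", {
  set.seed(21)
  for (i in 1:50) {
    pr <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
    base <- majority_vote(vote_panel(pr))
    m <- sample(4, 1); r <- sample(4, 1); c <- sample(4, 1)
    pr2 <- pr
    pr2[r, c, m] <- 1  # vote and probability both go up
    after <- majority_vote(vote_panel(pr2))
    expect_false(base[r, c] == 1 && after[r, c] == 0)
  }
})

test_that("ensemble_predict wraps forward + fusion and is order-invariant", {
  ds <- tiny_dataset(3, seed = 30, size = c(16L, 16L))
  models <- lapply(1:4, function(sd)
    build_model(architecture_spec(c("unet", "unetpp", "unet3p",
                                    "nasunet")[sd],
                                  depth = 2, base_width = 3), seed = sd))
  img <- ds[[1]]$image
  expect_identical(ensemble_predict(models[1], img),
                   predict_mask(models[[1]], img))
  fused <- ensemble_predict(models, img)
  expect_identical(ensemble_predict(rev(models), img), fused)
  # equals the brute-force per-pixel tally over the models' probability maps
  pr <- array(unlist(lapply(models, forward, images = img)),
              dim = c(16, 16, 4))
  expect_identical(fused, vote_oracle(pr))
  # incompatible model named by position (divisor 32 does not divide 16)
  bad <- build_model(architecture_spec("unet", depth = 6, base_width = 1),
                     seed = 9)
  expect_error(ensemble_predict(c(models[1:2], list(bad)), img), "model 3")
})
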