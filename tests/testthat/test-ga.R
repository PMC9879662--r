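space <- search_space(c(1e-4, 1), c(1L, 50L), c(1L, 32L))

genes_in_space <- function(ind, sp = space) {
  g <- ind$genes
  g$learning_rate >= sp$lr[1] && g$learning_rate <= sp$lr[2] &&
    g$epochs >= sp$epochs[1] && g$epochs <= sp$epochs[2] &&
    g$batch_size >= sp$batch[1] && g$batch_size <= sp$batch[2]
}

test_that("population initialisation is in-range, deterministic, honours degenerate ranges", {
  set.seed(10); pop <- init_population(space, 20)
  expect_length(pop, 20)
  expect_true(all(vapply(pop, genes_in_space, TRUE)))
  expect_true(all(is.na(vapply(pop, function(i) i$fitness, 0))))
  set.seed(10); expect_identical(init_population(space, 20), pop)
  expect_error(init_population(space, 1), ">= 2")

  sp1 <- search_space(c(0.1, 0.2), c(5L, 6L), c(2L, 3L))
  set.seed(3)
  pop1 <- init_population(sp1, 30)
  expect_true(all(vapply(pop1, function(i) i$genes$epochs, 0L) %in% 5:6))
})

test_that("fitness map is the stated strictly decreasing transform", {
  expect_equal(fitness_from_loss(0), 1)
  expect_equal(fitness_from_loss(1), 0.5)
  ls <- sort(runif(50, 0, 10))
  expect_true(all(diff(fitness_from_loss(ls)) < 0))
  expect_error(fitness_from_loss(NaN), "loss")
  expect_error(fitness_from_loss(-1), "loss")
})

test_that("tournament selection excludes exactly the k-1 worst and favours rank", {
  set.seed(5)
  pop <- init_population(space, 15)
  fits <- seq(0.1, 0.9, length.out = 15)
  for (i in seq_along(pop)) pop[[i]]$fitness <- fits[i]
  # the known best contestant always wins its tournament
  for (rep in 1:50) {
    w <- tournament_select(pop, 5)
    expect_true(w$fitness >= sort(fits, decreasing = TRUE)[11])
  }
  # analytic feasibility: population 100, k = 5 -> exactly 4 unselectable
  p <- tournament_win_probability(runif(100), 5)
  expect_identical(sum(p == 0), 4L)
  expect_equal(sum(p), 1)
  # selection probability non-decreasing in fitness rank (Monte-Carlo)
  set.seed(6)
  wins <- integer(15)
  for (rep in 1:4000) {
    w <- tournament_select(pop, 5)
    wins[which(fits == w$fitness)] <- wins[which(fits == w$fitness)] + 1L
  }
  expect_identical(sum(wins[1:4]), 0L)
  lo <- mean(wins[5:9]); hi <- mean(wins[10:15])
  expect_gt(hi, lo)
  # k = 1 degenerates to uniform selection over everyone
  set.seed(7)
  ws <- replicate(2000, tournament_select(pop, 1)$fitness)
  expect_gt(min(table(ws)), 0)
  expect_error(tournament_select(init_population(space, 3), 2), "fitness")
})

test_that("crossover respects one-point semantics and space closure", {
  set.seed(11)
  a <- segfed:::new_individual(0.01, 10L, 4L)
  b <- segfed:::new_individual(0.2, 30L, 16L)
  cfg_v <- ga_config(encoding = "value")
  found_cut1 <- FALSE
  for (i in 1:50) {
    kids <- crossover(a, b, cfg_v, space)
    g1 <- kids[[1]]$genes
    expect_true(g1$learning_rate %in% c(a$genes$learning_rate) ||
                  identical(g1, a$genes))
    if (identical(g1, list(learning_rate = 0.01, epochs = 30L,
                           batch_size = 16L)))
      found_cut1 <- TRUE
  }
  expect_true(found_cut1)  # cut after the first gene occurs and swaps the tail

  for (cfg in list(ga_config(encoding = "value"),
                   ga_config(encoding = "binary"))) {
    kids <- crossover(a, a, cfg, space)
    expect_identical(kids[[1]]$genes, a$genes)
    expect_identical(kids[[2]]$genes, a$genes)
  }

  set.seed(12)
  cfg_b <- ga_config(encoding = "binary")
  pop <- init_population(space, 40)
  for (i in 1:1000) {
    pr <- sample(40, 2)
    kids <- crossover(pop[[pr[1]]], pop[[pr[2]]], cfg_b, space)
    expect_true(all(vapply(kids, genes_in_space, TRUE)))
  }
})

test_that("mutation is rate-faithful, range-closed, and resets fitness", {
  set.seed(13)
  ind <- segfed:::new_individual(0.05, 25L, 8L, fitness = 0.7)
  expect_identical(mutate(ind, space, 0), ind)
  m1 <- mutate(ind, space, 1)
  expect_true(genes_in_space(m1))
  expect_true(is.na(m1$fitness))
  # per-gene mutation frequency at rate 0.5 over 10,000 gene trials; the
  # continuous lr gene is the clean indicator (a re-randomised integer gene
  # can land on its old value by chance)
  set.seed(15)
  lr_changed <- mean(replicate(10000, {
    mutate(ind, space, 0.5)$genes$learning_rate != ind$genes$learning_rate
  }))
  expect_lt(abs(lr_changed - 0.5), 0.02)
})

test_that("run_ga recovers a known optimum and elitism keeps best fitness monotone", {
  topt <- c(0.3, 0.6, 0.45)
  tn <- function(g) c(
    (log(g$learning_rate) - log(space$lr[1])) / (log(space$lr[2]) - log(space$lr[1])),
    (g$epochs - space$epochs[1]) / diff(space$epochs),
    (g$batch_size - space$batch[1]) / diff(space$batch))
  bowl <- function(genes, seed) sum((tn(genes) - topt)^2)
  # grid oracle: confirm where the optimum actually lies inside the space
  grid <- expand.grid(a = seq(0, 1, 0.05), b = seq(0, 1, 0.05),
                      c = seq(0, 1, 0.05))
  vals <- (grid$a - topt[1])^2 + (grid$b - topt[2])^2 + (grid$c - topt[3])^2
  expect_equal(unlist(grid[which.min(vals), ], use.names = FALSE),
               c(0.3, 0.6, 0.45))

  hits <- 0
  for (sd in 1:10) {
    r <- run_ga(space, ga_config(20, 10, 5, seed = sd), bowl)
    expect_true(!is.unsorted(r$history$best_fitness))
    if (all(abs(tn(r$best$genes) - topt) <= 0.1)) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # generations = 0 evaluates the initial population only
  r0 <- run_ga(space, ga_config(10, 0, 3, seed = 1), bowl)
  expect_identical(nrow(r0$history), 1L)
  expect_equal(r0$best$fitness,
               max(vapply(r0$population, function(i) i$fitness, 0)))
  # evaluation failures carry generation/individual context
  expect_error(run_ga(space, ga_config(4, 0, 2, seed = 1),
                      function(genes, seed) stop("boom")),
               "generation 0, individual")
})
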