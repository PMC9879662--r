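# Genetic search over {learning rate, epochs, batch size}. The learning rate
# lives on a log scale (it spans orders of magnitude); integer genes round to
# nearest with ties up. Every operator is closed over the search space:
# children and mutants are clipped/decoded back into range.

#' Hyperparameter search space
#'
#' @param lr_range length-2 numeric in `(0, 1]`, low < high; sampled and
#'   binary-encoded on a log scale.
#' @param epochs_range,batch_range length-2 integer ranges, low < high.
#' @return an object of class `"search_space"`.
#' @export
search_space <- function(lr_range = c(1e-4, 1), epochs_range = c(1L, 50L),
                         batch_range = c(1L, 32L)) {
  chk <- function(r, name) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] >= r[2L])
      stop_config(name, " must be (low, high) with low < high")
  }
  chk(lr_range, "lr_range"); chk(epochs_range, "epochs_range")
  chk(batch_range, "batch_range")
  if (lr_range[1L] <= 0 || lr_range[2L] > 1)
    stop_config("lr_range must lie inside (0, 1]")
  structure(list(lr = as.numeric(lr_range),
                 epochs = as.integer(epochs_range),
                 batch = as.integer(batch_range)), class = "search_space")
}

#' Genetic-algorithm configuration
#'
#' Defaults mirror the study setting: population 20 evolved for 10
#' generations, tournaments of 5, with one elite carried over unchanged so
#' best-so-far fitness is non-decreasing.
#'
#' @param population_size number of individuals (>= 2).
#' @param generations number of evolution steps (0 = evaluate the initial
#'   population only).
#' @param tournament_size k individuals drawn without replacement per
#'   selection.
#' @param crossover_rate probability a parent pair recombines.
#' @param mutation_rate per-gene probability of re-randomisation.
#' @param encoding `"value"` (one-point crossover on the 3-gene vector) or
#'   `"binary"` (one-point crossover on the concatenated 48-bit fixed-point
#'   encoding).
#' @param elitism_count individuals copied unchanged into each generation.
#' @param seed integer RNG seed for the whole run.
#' @return an object of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 20L, generations = 10L,
                      tournament_size = 5L, crossover_rate = 0.9,
                      mutation_rate = 0.15,
                      encoding = c("value", "binary"),
                      elitism_count = 1L, seed = 1L) {
  encoding <- match.arg(encoding)
  population_size <- as.integer(population_size)
  if (population_size < 2L) stop_config("population_size must be >= 2")
  tournament_size <- as.integer(tournament_size)
  if (tournament_size < 1L || tournament_size > population_size)
    stop_config("tournament_size must lie in [1, population_size]")
  elitism_count <- as.integer(elitism_count)
  if (elitism_count < 0L || elitism_count >= population_size)
    stop_config("elitism_count must be < population_size")
  structure(list(population_size = population_size,
                 generations = as.integer(generations),
                 tournament_size = tournament_size,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, encoding = encoding,
                 elitism_count = elitism_count, seed = as.integer(seed)),
            class = "ga_config")
}

new_individual <- function(lr, epochs, batch, fitness = NA_real_) {
  structure(list(genes = list(learning_rate = lr,
                              epochs = as.integer(epochs),
                              batch_size = as.integer(batch)),
                 fitness = fitness), class = "ga_individual")
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

clip_genes <- function(ind, space) {
  g <- ind$genes
  g$learning_rate <- min(max(g$learning_rate, space$lr[1L]), space$lr[2L])
  g$epochs <- min(max(g$epochs, space$epochs[1L]), space$epochs[2L])
  g$batch_size <- min(max(g$batch_size, space$batch[1L]), space$batch[2L])
  ind$genes <- g
  ind
}

sample_gene <- function(space, which) {
  switch(which,
    lr = exp(runif(1L, log(space$lr[1L]), log(space$lr[2L]))),
    epochs = sample.int(space$epochs[2L] - space$epochs[1L] + 1L, 1L) +
      space$epochs[1L] - 1L,
    batch = sample.int(space$batch[2L] - space$batch[1L] + 1L, 1L) +
      space$batch[1L] - 1L)
}

#' Draw an initial random population
#'
#' Genes are uniform over the space (log-uniform for the learning rate);
#' fitness starts unset. Uses the current RNG state: seed the session (or use
#' [run_ga()], which seeds from its config) for reproducibility.
#'
#' @param space a [search_space()].
#' @param n population size (>= 2).
#' @return list of `"ga_individual"`.
#' @export
init_population <- function(space, n) {
  n <- as.integer(n)
  if (n < 2L) stop_config("population size must be >= 2")
  lapply(seq_len(n), function(i)
    new_individual(sample_gene(space, "lr"), sample_gene(space, "epochs"),
                   sample_gene(space, "batch")))
}

#' Map a training loss to a fitness value
#'
#' Strictly decreasing bounded map `1 / (1 + loss)`: loss 0 gives the maximal
#' fitness 1, and larger losses always score lower.
#'
#' @param loss finite non-negative number.
#' @return fitness in `(0, 1]`.
#' @export
fitness_from_loss <- function(loss) {
  if (!is.numeric(loss) || any(is.na(loss)) || any(!is.finite(loss)) ||
      any(loss < 0))
    stop_config("loss must be finite and non-negative")
  1 / (1 + loss)
}

#' Tournament selection
#'
#' Draws `k` distinct individuals uniformly without replacement and returns
#' the one with the highest (already evaluated) fitness; contestants are not
#' re-evaluated. With distinct fitnesses the `k - 1` worst individuals of the
#' population can never win any tournament.
#'
#' @param population list of evaluated `"ga_individual"`.
#' @param k tournament size.
#' @return the winning `"ga_individual"`.
#' @export
tournament_select <- function(population, k) {
  if (k < 1L || k > length(population))
    stop_config("k must lie in [1, population size]")
  fit <- vapply(population, function(ind) ind$fitness, 0)
  if (any(is.na(fit))) stop_config("all individuals must have fitness set")
  contestants <- sample.int(length(population), k)
  population[[contestants[which.max(fit[contestants])]]]
}

#' Analytic tournament win probability
#'
#' For distinct fitnesses, individual with rank `r` (1 = worst) wins a
#' size-`k` tournament iff the other `k - 1` contestants are all worse, so
#' `P(win) = choose(r - 1, k - 1) / choose(n, k)`; the `k - 1` worst
#' individuals have probability exactly zero.
#'
#' @param fitness numeric vector of distinct fitness values.
#' @param k tournament size.
#' @return vector of win probabilities, one per individual (sums to 1).
#' @export
tournament_win_probability <- function(fitness, k) {
  n <- length(fitness)
  r <- rank(fitness)
  choose(r - 1, k - 1) / choose(n, k)
}

# 16-bit fixed-point codes on normalized (log for lr) coordinates
encode_bits <- function(ind, space) {
  tnorm <- c(
    (log(ind$genes$learning_rate) - log(space$lr[1L])) /
      (log(space$lr[2L]) - log(space$lr[1L])),
    (ind$genes$epochs - space$epochs[1L]) /
      (space$epochs[2L] - space$epochs[1L]),
    (ind$genes$batch_size - space$batch[1L]) /
      (space$batch[2L] - space$batch[1L]))
  codes <- round_half_up(pmin(pmax(tnorm, 0), 1) * 65535)
  unlist(lapply(codes, function(cd)
    as.integer(bitwAnd(bitwShiftR(cd, 15:0), 1L))))
}

decode_bits <- function(bits, space) {
  codes <- vapply(0:2, function(j)
    sum(bits[j * 16L + 1:16] * 2L^(15:0)), 0)
  tnorm <- codes / 65535
  lr <- exp(log(space$lr[1L]) +
              tnorm[1L] * (log(space$lr[2L]) - log(space$lr[1L])))
  ep <- round_half_up(space$epochs[1L] +
                        tnorm[2L] * (space$epochs[2L] - space$epochs[1L]))
  bt <- round_half_up(space$batch[1L] +
                        tnorm[3L] * (space$batch[2L] - space$batch[1L]))
  clip_genes(new_individual(lr, ep, bt), space)
}

#' Recombine two parents
#'
#' Value mode performs one-point crossover on the 3-gene vector; binary mode
#' quantises each gene to a 16-bit fixed-point code within its range
#' (learning rate on the log scale), concatenates the codes into a 48-bit
#' string, crosses over at a random bit, and decodes (with clipping) back
#' into the space. Children of identical parents equal the parents in both
#' modes. Child fitness is unset.
#'
#' @param a,b parent `"ga_individual"`s.
#' @param cfg a [ga_config()] (supplies the encoding).
#' @param space a [search_space()] (for binary decode / clipping).
#' @return list of two children.
#' @export
crossover <- function(a, b, cfg, space) {
  if (cfg$encoding == "value") {
    cut <- sample.int(2L, 1L)  # after gene 1 or gene 2
    ga <- a$genes; gb <- b$genes
    c1 <- ga; c2 <- gb
    idx <- seq(cut + 1L, 3L)
    c1[idx] <- gb[idx]; c2[idx] <- ga[idx]
    list(new_individual(c1$learning_rate, c1$epochs, c1$batch_size),
         new_individual(c2$learning_rate, c2$epochs, c2$batch_size))
  } else {
    ba <- encode_bits(a, space); bb <- encode_bits(b, space)
    cut <- sample.int(47L, 1L)
    # a child whose bitstring equals a parent's inherits that parent's genes
    # exactly (quantisation must not drift identical parents)
    hatch <- function(bits) {
      if (identical(bits, ba))
        new_individual(a$genes$learning_rate, a$genes$epochs,
                       a$genes$batch_size)
      else if (identical(bits, bb))
        new_individual(b$genes$learning_rate, b$genes$epochs,
                       b$genes$batch_size)
      else decode_bits(bits, space)
    }
    list(hatch(c(ba[1:cut], bb[(cut + 1L):48L])),
         hatch(c(bb[1:cut], ba[(cut + 1L):48L])))
  }
}

#' Mutate an individual
#'
#' Each gene is independently re-randomised uniformly within its range
#' (log-uniform for the learning rate) with probability `rate`; fitness is
#' reset whenever any gene changes.
#'
#' @param ind a `"ga_individual"`.
#' @param space a [search_space()].
#' @param rate per-gene mutation probability in `[0, 1]`.
#' @return the (possibly) mutated individual.
#' @export
mutate <- function(ind, space, rate) {
  if (rate < 0 || rate > 1) stop_config("rate must lie in [0, 1]")
  hit <- runif(3L) < rate
  if (hit[1L]) ind$genes$learning_rate <- sample_gene(space, "lr")
  if (hit[2L]) ind$genes$epochs <- sample_gene(space, "epochs")
  if (hit[3L]) ind$genes$batch_size <- sample_gene(space, "batch")
  if (any(hit)) ind$fitness <- NA_real_
  ind
}

#' Run the genetic search
#'
#' Evaluate, carry elites, select parents by tournament, recombine, mutate,
#' repeat. `eval_fn(genes, seed)` must return a finite non-negative loss and
#' be deterministic given its seed (seeds are derived from `cfg$seed`, the
#' generation and the slot, so runs are reproducible end to end). Fitness is
#' `1 / (1 + loss)`; with `elitism_count >= 1` the best-so-far fitness is
#' non-decreasing across generations.
#'
#' @param space a [search_space()].
#' @param cfg a [ga_config()].
#' @param eval_fn function of `(genes, seed)` returning a loss, where
#'   `genes` is `list(learning_rate=, epochs=, batch_size=)`.
#' @return object of class `"ga_result"`: `best` individual, `history`
#'   data frame (per-generation best/mean fitness and best genes), and the
#'   final `population`.
#' @export
run_ga <- function(space, cfg, eval_fn) {
  stopifnot(inherits(space, "search_space"), inherits(cfg, "ga_config"))
  eval_pop <- function(pop, gen) {
    for (i in seq_along(pop)) {
      if (is.na(pop[[i]]$fitness)) {
        loss <- tryCatch(eval_fn(pop[[i]]$genes,
                                 derive_seed(cfg$seed, gen, i)),
                         error = function(e)
                           stop("evaluation failed at generation ", gen,
                                ", individual ", i, ": ",
                                conditionMessage(e), call. = FALSE))
        pop[[i]]$fitness <- fitness_from_loss(loss)
      }
    }
    pop
  }
  with_seed(cfg$seed, {
    pop <- eval_pop(init_population(space, cfg$population_size), 0L)
    hist <- data.frame()
    record <- function(gen, pop) {
      fit <- vapply(pop, function(ind) ind$fitness, 0)
      b <- pop[[which.max(fit)]]
      rbind(hist, data.frame(generation = gen, best_fitness = max(fit),
                             mean_fitness = mean(fit),
                             best_lr = b$genes$learning_rate,
                             best_epochs = b$genes$epochs,
                             best_batch = b$genes$batch_size))
    }
    hist <- record(0L, pop)
    if (cfg$generations > 0L) for (gen in seq_len(cfg$generations)) {
      fit <- vapply(pop, function(ind) ind$fitness, 0)
      nxt <- pop[order(-fit)[seq_len(cfg$elitism_count)]]
      while (length(nxt) < cfg$population_size) {
        p1 <- tournament_select(pop, cfg$tournament_size)
        p2 <- tournament_select(pop, cfg$tournament_size)
        kids <- if (runif(1L) < cfg$crossover_rate)
          crossover(p1, p2, cfg, space) else list(p1, p2)
        for (kid in kids) {
          if (length(nxt) < cfg$population_size)
            nxt <- c(nxt, list(mutate(kid, space, cfg$mutation_rate)))
        }
      }
      pop <- eval_pop(nxt, gen)
      hist <- record(gen, pop)
    }
    fit <- vapply(pop, function(ind) ind$fitness, 0)
    structure(list(best = pop[[which.max(fit)]], history = hist,
                   population = pop, config = cfg, space = space),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<ga_result> %d generation(s), population %d\n  best: lr %.4g, epochs %d, batch %d (fitness %.4f)\n",
    max(x$history$generation), x$config$population_size,
    b$genes$learning_rate, b$genes$epochs, b$genes$batch_size, b$fitness))
  invisible(x)
}

#' @export
plot.ga_result <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, h$best_fitness, type = "b", ylim = range(
    c(h$best_fitness, h$mean_fitness)), xlab = "generation",
    ylab = "fitness", main = "GA fitness trajectory", ...)
  graphics::lines(h$generation, h$mean_fitness, type = "b", lty = 2)
  graphics::legend("bottomright", legend = c("best", "mean"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
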