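test_that("random instantiation yields distinct, reproducible individuals", {
  cfg <- tiny_config(mu = 5)
  set.seed(cfg$seed); p1 <- instantiate_population(cfg)
  set.seed(cfg$seed); p2 <- instantiate_population(cfg)
  expect_identical(p1, p2)
  expect_identical(nrow(p1), 5L)
  expect_identical(length(unique(p1$toxin)), 5L)
  expect_error(ea_config(mu = 0), "mu")
})

test_that("consensus instantiation starts with near-perfect toxin domains", {
  cfg <- tiny_config(mu = 12, instantiation = "consensus",
                     toxin_length = 900, antidote_length = 300)
  set.seed(1); pop <- instantiate_population(cfg)
  expect_true(all(pop$nuclease == 1))
  expect_true(all(pop$dub == 1))
  # no motif is seeded: NLS/T4SS stay at background alignment credit
  expect_true(mean(pop$nls == 1) < 0.5)
  expect_identical(length(unique(pop$toxin)), 12L)
})

test_that("founder instantiation without burn-in is clonal", {
  cfg <- tiny_config(mu = 8, instantiation = "founder", founder_burnin = 0)
  set.seed(2); pop <- instantiate_population(cfg)
  expect_identical(length(unique(pop$toxin)), 1L)
  expect_equal(diversity_index(pop), 0)
})

test_that("starting diversity orders random > consensus > founder", {
  div <- vapply(c("random", "consensus", "founder"), function(method) {
    cfg <- ea_config(mu = 100, lambda = 10, instantiation = method,
                     toxin_length = 1200, antidote_length = 600, seed = 4)
    set.seed(cfg$seed)
    pop <- instantiate_population(cfg)
    diversity_index(pop)
  }, numeric(1))
  expect_gt(div[["random"]], div[["consensus"]])
  expect_gt(div[["consensus"]], div[["founder"]])
})

test_that("K-tournament selection degenerates correctly at K extremes", {
  cfg <- tiny_config(mu = 20, lambda = 10)
  set.seed(cfg$seed)
  pop <- instantiate_population(cfg)
  # K = mu: every tournament sees everyone -> pool is all-best
  cfg_max <- cfg; cfg_max$k_tournament <- 20L
  pool <- select_parents(pop, cfg_max)
  expect_identical(unique(pool), which.max(pop$fitness))
  expect_length(pool, 10L)
  # K = 1: uniform random draw covers more than just the best
  cfg_one <- cfg; cfg_one$k_tournament <- 1L
  set.seed(8)
  picks <- unique(unlist(replicate(50, select_parents(pop, cfg_one))))
  expect_gt(length(picks), 10)
})

test_that("K = 5 tournaments exert positive selection pressure", {
  cfg <- tiny_config(mu = 50, lambda = 20)
  set.seed(cfg$seed)
  pop <- instantiate_population(cfg)
  set.seed(21)
  gain <- replicate(200, {
    mean(pop$fitness[select_parents(pop, cfg)]) - mean(pop$fitness)
  })
  expect_gt(mean(gain > 0), 0.95)
})

test_that("fps and elitism parent selection respect fitness", {
  cfg <- tiny_config(mu = 20, lambda = 10)
  set.seed(cfg$seed)
  pop <- instantiate_population(cfg)
  cfg$parent_selection <- "elitism"
  pool <- select_parents(pop, cfg)
  expect_setequal(pool, order(-pop$fitness)[1:10])
  cfg$parent_selection <- "fps"
  set.seed(5)
  pool <- select_parents(pop, cfg)
  expect_length(pool, 10L)
  expect_true(all(pool %in% seq_len(20)))
})

test_that("reproduction returns exactly lambda evaluated offspring", {
  cfg <- tiny_config(mu = 20, lambda = 9)
  set.seed(cfg$seed)
  pop <- instantiate_population(cfg)
  off <- reproduce(pop, select_parents(pop, cfg), cfg, generation = 3L,
                   next_id = 1000L)
  expect_identical(nrow(off), 9L)
  expect_true(all(off$born == 3L))
  expect_identical(off$id, 1000L + 0:8)
  expect_false(anyNA(off$fitness))
})

test_that("clonal parents with mutation off breed clones", {
  ta <- make_perfect_ta(9)
  pop <- ta_fitness(tibble::tibble(
    id = 1:6, born = 0L, toxin = ta$toxin, antidote = ta$antidote,
    mut_rolls = 0L))
  cfg <- tiny_config(mu = 6, lambda = 4, mut_step_prob = 0)
  set.seed(31)
  off <- reproduce(pop, select_parents(pop, cfg), cfg)
  expect_true(all(off$toxin == ta$toxin))
  expect_true(all(off$antidote == ta$antidote))
  expect_true(all(off$fitness == ta$fitness))
})

test_that("truncation keeps the top mu with age-then-id tie-breaks", {
  cfg <- tiny_config(mu = 10, lambda = 5)
  big <- tiny_config(mu = 15)
  set.seed(cfg$seed)
  pop <- instantiate_population(big, evaluate = FALSE)
  pop$born <- rep(c(0L, 1L, 2L), each = 5)
  pop <- ta_fitness(pop, cfg)
  pop$fitness <- rep(1, 15)  # all equal: survivors must be the oldest
  surv <- select_survivors(pop, cfg)
  expect_identical(nrow(surv), 10L)
  expect_true(all(surv$born <= 1L))
  # best individual always survives
  pop$fitness <- seq(0.1, 1.5, length.out = 15)
  surv <- select_survivors(pop, cfg)
  expect_true(max(pop$fitness) %in% surv$fitness)
})

test_that("k-tournament survivor selection also holds carrying capacity", {
  cfg <- tiny_config(mu = 10, lambda = 5, survivor_selection = "k_tournament")
  set.seed(cfg$seed)
  pop <- instantiate_population(tiny_config(mu = 15), evaluate = FALSE)
  pop <- ta_fitness(pop, cfg)
  set.seed(41)
  surv <- select_survivors(pop, cfg)
  expect_identical(nrow(surv), 10L)
  expect_identical(anyDuplicated(surv$id), 0L)
})

test_that("re-instantiation replaces the configured number of worst members", {
  cfg <- tiny_config(mu = 20, lambda = 5)
  set.seed(cfg$seed)
  pop <- instantiate_population(cfg)
  expect_identical(reinstantiate(pop, cfg), pop)  # off -> identity
  cfg$reinstantiation <- "count"; cfg$reinstantiation_value <- 4
  set.seed(51)
  out <- reinstantiate(pop, cfg, generation = 7L, next_id = 900L)
  expect_identical(nrow(out), 20L)
  expect_identical(sum(out$born == 7L), 4L)
  # the replaced members were the worst
  expect_true(all(setdiff(pop$id, out$id) %in%
                    pop$id[order(pop$fitness)][1:4]))
  cfg$reinstantiation <- "fraction"; cfg$reinstantiation_value <- 0.1
  set.seed(52)
  out <- reinstantiate(pop, cfg, generation = 8L, next_id = 950L)
  expect_identical(sum(out$born == 8L), 2L)  # 10% of mu = 20
})

test_that("a run logs generation 0 plus one row per generation", {
  cfg <- tiny_config(generations = 0)
  run <- ea_run(cfg)
  expect_identical(nrow(run$log), 1L)
  expect_identical(run$log$generation, 0L)
  cfg <- tiny_config(generations = 4)
  run <- ea_run(cfg)
  expect_identical(run$log$generation, 0:4)
  expect_identical(nrow(run$final), cfg$mu)
})

test_that("best fitness is monotone under truncation and runs are deterministic", {
  cfg <- tiny_config(mu = 40, lambda = 10, generations = 25)
  run1 <- ea_run(cfg)
  run2 <- ea_run(cfg)
  expect_identical(run1$log, run2$log)
  expect_true(all(diff(run1$log$highestTAFitness_HTF) >= -1e-12))
  expect_true(all(vapply(run1$log$generation, function(g)
    nrow(run1$final), integer(1)) == cfg$mu))
})

test_that("mean fitness trends upward on short runs", {
  set.seed(61)
  slopes <- vapply(1:5, function(i) {
    cfg <- tiny_config(mu = 40, lambda = 10, generations = 30,
                       seed = 600 + i)
    run <- ea_run(cfg)
    unname(coef(lm(avgTAfitness_ATF ~ generation, data = run$log))[2])
  }, numeric(1))
  expect_gt(mean(slopes > 0), 0.8)
})

test_that("replicate runner derives distinct seeds and stacks logs", {
  cfg <- tiny_config(generations = 3)
  reps <- ea_replicates(cfg, n = 3)
  expect_length(reps$runs, 3L)
  expect_identical(length(unique(reps$logs$seed)), 3L)
  expect_identical(nrow(reps$logs), 3L * 4L)
  # explicit identical seeds give identical runs
  reps2 <- ea_replicates(cfg, n = 2, seeds = c(77L, 77L))
  expect_identical(reps2$runs[[1]]$log, reps2$runs[[2]]$log)
})

test_that("self-adaptive mutation-rate genes stay within bounds", {
  cfg <- tiny_config(mu = 30, lambda = 10, generations = 15,
                     init_mut_rolls = 2, max_mut_rolls = 4)
  run <- ea_run(cfg)
  expect_true(all(run$final$mut_rolls >= 0 & run$final$mut_rolls <= 4))
  expect_true(all(run$log$avgTAMutationRate_ATMR <= 4))
})
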