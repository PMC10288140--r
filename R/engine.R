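#' Select a mating pool of parents
#'
#' Default K-tournament: lambda independent tournaments, each drawing K
#' members uniformly without replacement and sending the fittest to the
#' pool. `"fps"` samples lambda parents with probability proportional to
#' fitness (shifted to be non-negative); `"elitism"` sends the lambda
#' fittest.
#'
#' @param population An evaluated population tibble.
#' @param config An [ea_config()].
#' @return Integer vector of length `config$lambda`: row indices of the
#'   selected parents.
#' @export
select_parents <- function(population, config = ea_config()) {
  n <- nrow(population)
  fit <- population$fitness
  switch(config$parent_selection,
    k_tournament = {
      k <- min(config$k_tournament, n)
      vapply(seq_len(config$lambda), function(i) {
        cand <- sample.int(n, k)
        cand[which.max(fit[cand])]
      }, integer(1))
    },
    fps = {
      w <- fit - min(fit)
      if (sum(w) <= 0) w <- rep(1, n)
      sample.int(n, config$lambda, replace = TRUE, prob = w)
    },
    elitism = {
      order(-fit)[rep_len(seq_len(min(config$lambda, n)), config$lambda)]
    }
  )
}

mutate_genome <- function(toxin, antidote, rolls, config) {
  # each dice roll targets toxin or antidote with probability proportional
  # to current gene length (a uniform position over the whole genome)
  for (r in seq_len(rolls)) {
    nt <- nchar(toxin)
    na <- nchar(antidote)
    if (nt + na == 0L) break
    if (stats::runif(1) < nt / (nt + na)) {
      toxin <- mutate_dna(toxin, 1L, config$indel_mean, config$indel_cap)
    } else {
      antidote <- mutate_dna(antidote, 1L, config$indel_mean, config$indel_cap)
    }
  }
  list(toxin = toxin, antidote = antidote)
}

#' Produce and evaluate lambda offspring from a mating pool
#'
#' Pairs are formed according to `config$mating_choice`; each pair yields
#' two children by gene-wise crossover (toxin with toxin, antidote with
#' antidote). A child inherits its mutation-rate gene from one parent at
#' random, steps it by one with probability `mut_step_prob` (clamped to
#' `[0, max_mut_rolls]`), and is then mutated with its own roll count.
#'
#' @param population An evaluated population tibble.
#' @param pool Integer row indices from [select_parents()].
#' @param config An [ea_config()].
#' @param generation Generation stamp for the children.
#' @param next_id First identifier to assign.
#' @return An evaluated tibble of exactly `config$lambda` offspring.
#' @export
reproduce <- function(population, pool, config = ea_config(),
                      generation = 1L, next_id = 1L) {
  lambda <- config$lambda
  mode <- config$mating_choice
  if (mode == "mixed") {
    mode <- sample(c("mating_pool", "sorted", "random"), 1L)
  }
  if (mode == "sorted") {
    pool <- pool[order(-population$fitness[pool])]
  }
  n_pairs <- ceiling(lambda / 2)
  pa <- pool[rep_len(seq(1L, length(pool), by = 2L), n_pairs)]
  pb <- switch(mode,
    sorted = pool[pmin(rep_len(seq(2L, length(pool) + 1L, by = 2L), n_pairs),
                       length(pool))],
    mating_pool = pool[sample.int(length(pool), n_pairs, replace = TRUE)],
    random = sample.int(nrow(population), n_pairs, replace = TRUE)
  )
  toxin <- character(2L * n_pairs)
  antidote <- character(2L * n_pairs)
  rolls <- integer(2L * n_pairs)
  for (p in seq_len(n_pairs)) {
    i <- pa[p]; j <- pb[p]
    tox_children <- crossover_dna(population$toxin[i], population$toxin[j],
                                  config$crossover_points)
    ant_children <- crossover_dna(population$antidote[i],
                                  population$antidote[j],
                                  config$crossover_points)
    for (c in 1:2) {
      k <- 2L * (p - 1L) + c
      r <- population$mut_rolls[[sample(c(i, j), 1L)]]
      if (stats::runif(1) < config$mut_step_prob) {
        r <- r + sample(c(-1L, 1L), 1L)
      }
      rolls[k] <- max(0L, min(config$max_mut_rolls, r))
      genome <- mutate_genome(tox_children[c], ant_children[c], rolls[k],
                              config)
      toxin[k] <- genome$toxin
      antidote[k] <- genome$antidote
    }
  }
  keep <- seq_len(lambda)
  offspring <- new_individuals(toxin[keep], antidote[keep], rolls[keep],
                               born = generation,
                               id = next_id + keep - 1L)
  ta_fitness(offspring, config)
}

#' Select survivors from the merged mu + lambda pool
#'
#' Default truncation: sort by total fitness (ties broken oldest-first, then
#' by identifier, for reproducibility) and keep the top mu, so carrying
#' capacity is constant and the best individual always survives. The
#' K-tournament variant fills the mu slots by repeated tournaments without
#' replacement of winners.
#'
#' @param candidates Evaluated tibble of mu + lambda individuals.
#' @param config An [ea_config()].
#' @return A population tibble of `config$mu` rows.
#' @export
select_survivors <- function(candidates, config = ea_config()) {
  mu <- config$mu
  if (nrow(candidates) <= mu) return(candidates)
  if (config$survivor_selection == "truncation") {
    ord <- order(-candidates$fitness, candidates$born, candidates$id)
    candidates[sort(ord[seq_len(mu)]), ]
  } else {
    remaining <- seq_len(nrow(candidates))
    chosen <- integer(mu)
    fit <- candidates$fitness
    for (s in seq_len(mu)) {
      k <- min(config$survivor_k, length(remaining))
      cand <- remaining[sample.int(length(remaining), k)]
      win <- cand[which.max(fit[cand])]
      chosen[s] <- win
      remaining <- remaining[remaining != win]
    }
    candidates[sort(chosen), ]
  }
}

#' Re-instantiation: immigration of fresh individuals
#'
#' Replaces the configured number of worst-fitness members with de-novo
#' individuals built by the run's instantiation regime, a diversity-
#' maintenance mechanism. Off by default in the main experiments.
#'
#' @param population An evaluated population tibble.
#' @param config An [ea_config()].
#' @param generation Generation stamp for the immigrants.
#' @param next_id First identifier to assign.
#' @param founder Founder gene pair (list with `toxin`, `antidote`) when the
#'   run uses the founder regime.
#' @return The population with immigrants swapped in.
#' @export
reinstantiate <- function(population, config = ea_config(),
                          generation = 0L, next_id = 1L, founder = NULL) {
  n_new <- switch(config$reinstantiation,
    off = 0L,
    count = as.integer(config$reinstantiation_value),
    fraction = as.integer(round(config$reinstantiation_value * config$mu))
  )
  if (n_new == 0L) return(population)
  sub <- config
  sub$mu <- n_new
  sub$k_tournament <- min(sub$k_tournament, n_new)
  fresh <- if (config$instantiation == "founder" && !is.null(founder)) {
    new_individuals(
      toxin = vapply(seq_len(n_new), function(i) {
        mutate_dna(founder$toxin, config$founder_burnin,
                   config$indel_mean, config$indel_cap)
      }, character(1)),
      antidote = vapply(seq_len(n_new), function(i) {
        mutate_dna(founder$antidote, config$founder_burnin,
                   config$indel_mean, config$indel_cap)
      }, character(1)),
      mut_rolls = rep(config$init_mut_rolls, n_new),
      born = generation, id = next_id + seq_len(n_new) - 1L
    ) |> ta_fitness(config)
  } else {
    fresh <- instantiate_population(sub, evaluate = TRUE)
    fresh$born <- generation
    fresh$id <- next_id + seq_len(n_new) - 1L
    fresh
  }
  worst <- order(population$fitness)[seq_len(n_new)]
  population[worst, ] <- fresh
  population
}

#' Run one (mu + lambda) evolutionary simulation
#'
#' Instantiates the population, then iterates parent selection,
#' reproduction with gene-wise crossover and self-adaptive mutation,
#' offspring evaluation, merging, survivor selection and (optionally)
#' re-instantiation for `config$generations` generations, logging the
#' fifteen tracked observables after instantiation and after every
#' generation. Fully deterministic under `config$seed`.
#'
#' @param config An [ea_config()].
#' @param quiet Suppress the per-run progress message.
#' @return A `cif_ea_run` object: list with `log` (tibble of
#'   `generations + 1` rows), `final` (the terminal population tibble),
#'   `config`, `seed` and `elapsed` (seconds). Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' run <- ea_run(ea_config(mu = 30, lambda = 6, generations = 5,
#'                         toxin_length = 300, antidote_length = 150,
#'                         seed = 7))
#' generics::glance(run)
#' @export
ea_run <- function(config = ea_config(), quiet = TRUE) {
  validate_ea_config(config)
  t0 <- Sys.time()
  set.seed(config$seed)
  founder <- if (config$instantiation == "founder") founder_pair(config)
  pop <- if (config$instantiation == "founder") {
    mu <- config$mu
    ta_fitness(new_individuals(
      toxin = vapply(seq_len(mu), function(i) {
        mutate_dna(founder$toxin, config$founder_burnin,
                   config$indel_mean, config$indel_cap)
      }, character(1)),
      antidote = vapply(seq_len(mu), function(i) {
        mutate_dna(founder$antidote, config$founder_burnin,
                   config$indel_mean, config$indel_cap)
      }, character(1)),
      mut_rolls = rep(config$init_mut_rolls, mu),
      born = 0L, id = seq_len(mu)
    ), config)
  } else {
    instantiate_population(config, evaluate = TRUE)
  }
  next_id <- config$mu + 1L
  logs <- vector("list", config$generations + 1L)
  logs[[1L]] <- generation_summary(pop, generation = 0L, config = config)
  gens_run <- 0L
  for (g in seq_len(config$generations)) {
    pool <- select_parents(pop, config)
    offspring <- reproduce(pop, pool, config, generation = g,
                           next_id = next_id)
    next_id <- next_id + config$lambda
    pop <- select_survivors(bind_rows(pop, offspring), config)
    if (config$reinstantiation != "off") {
      pop <- reinstantiate(pop, config, generation = g, next_id = next_id,
                           founder = founder)
      next_id <- next_id + config$mu  # ids never reused
    }
    logs[[g + 1L]] <- generation_summary(pop, generation = g, config = config)
    gens_run <- g
    if (max(pop$fitness) >= config$max_fitness_stop) break
  }
  structure(
    list(log = bind_rows(logs[seq_len(gens_run + 1L)]),
         final = pop, config = config, seed = config$seed,
         founder = founder,
         elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "cif_ea_run"
  )
}

#' @export
print.cif_ea_run <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "<cif_ea_run> seed %d: %d generations, mu = %d, lambda = %d\n",
    x$seed, last$generation, x$config$mu, x$config$lambda))
  cat(sprintf(
    "  terminal best fitness %.3f, mean fitness %.3f, diversity %.3f\n",
    last$highestTAFitness_HTF, last$avgTAfitness_ATF, last$diversityIndex_DI))
  cat(sprintf(
    "  signal location bias (0 = antidote/cifA, 1 = toxin/cifB): NLS %s, T4SS %s\n",
    format(round(last$avgNLSSITELocation_NLSL, 3)),
    format(round(last$avgTypeIVSITELocation_TYPL, 3))))
  invisible(x)
}

derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) + 104729 * seq_len(n)) %% 2147483646L + 1L)
}

#' Run independent replicate simulations
#'
#' Executes `n` independent [ea_run()]s whose seeds are derived
#' deterministically from `config$seed` (or supplied explicitly), as in the
#' 30-run replicate sets of the main experiments.
#'
#' @param config An [ea_config()].
#' @param n Number of replicate runs.
#' @param seeds Optional integer vector of per-run seeds (length `n`).
#' @param quiet Suppress progress messages.
#' @return A `cif_ea_replicates` object: list with `runs` (list of
#'   `cif_ea_run`), `logs` (combined log tibble with `run` and `seed`
#'   columns) and `config`.
#' @export
ea_replicates <- function(config = ea_config(), n = 30L, seeds = NULL,
                          quiet = TRUE) {
  if (is.null(seeds)) seeds <- derive_seeds(config$seed, n)
  if (length(seeds) != n) abort("`seeds` must have length `n`")
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    if (!quiet) message(sprintf("replicate %d/%d (seed %d)", i, n, cfg$seed))
    runs[[i]] <- ea_run(cfg)
  }
  logs <- bind_rows(lapply(seq_len(n), function(i) {
    mutate(runs[[i]]$log, run = i, seed = seeds[i], .before = 1L)
  }))
  structure(list(runs = runs, logs = logs, config = config),
            class = "cif_ea_replicates")
}

#' @export
print.cif_ea_replicates <- function(x, ...) {
  cat(sprintf("<cif_ea_replicates> %d runs of %d generations (mu = %d)\n",
              length(x$runs), x$config$generations, x$config$mu))
  term <- terminal_rows(x$logs)
  cat(sprintf("  terminal mean fitness %.3f (sd %.3f)\n",
              mean(term$avgTAfitness_ATF), sd(term$avgTAfitness_ATF)))
  invisible(x)
}
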