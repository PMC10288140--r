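#' Configure an evolutionary-algorithm run
#'
#' Builds the full configuration of a (mu + lambda) simulation with the
#' defaults of the main experiments: mu = 5,000 parents, lambda = 100
#' offspring, 1,000 generations, K-tournament parent selection with K = 5,
#' mating restricted to the mating pool, 4-point crossover applied gene-wise,
#' self-adaptive mutation-rate genes, truncation survivor selection, and no
#' re-instantiation. Every operator variant studied in the parameter sweep
#' is reachable through the corresponding argument.
#'
#' @param mu Population (carrying-capacity) size.
#' @param lambda Offspring per generation.
#' @param generations Number of generations to run.
#' @param parent_selection `"k_tournament"`, `"fps"` (fitness-proportional)
#'   or `"elitism"`.
#' @param k_tournament Tournament size K.
#' @param mating_choice `"mating_pool"` (random mates within the pool),
#'   `"sorted"` (mates of adjacent fitness rank), `"random"` (mates drawn
#'   from the whole population) or `"mixed"` (one of the three drawn
#'   per generation).
#' @param crossover_points 1, 2, 3, 4, 6 or `"mixed"`.
#' @param survivor_selection `"truncation"` or `"k_tournament"`.
#' @param survivor_k Tournament size for survivor selection.
#' @param reinstantiation `"off"`, `"count"` or `"fraction"`: immigration of
#'   fresh de-novo individuals each generation, replacing the worst members.
#' @param reinstantiation_value Number (for `"count"`) or fraction of mu
#'   (for `"fraction"`) of immigrants.
#' @param instantiation `"random"`, `"consensus"` or `"founder"` -- the three
#'   instantiation regimes, in decreasing order of starting diversity.
#' @param toxin_length,antidote_length Initial gene lengths in bp; toxins are
#'   longer than antidotes, as in real cif pairs.
#' @param founder_fasta Optional FASTA path supplying the founder TA pair for
#'   the founder regime (records named `...|toxin` and `...|antidote`).
#' @param founder_burnin Mutation dice rolls applied to each founder copy.
#' @param init_mut_rolls,max_mut_rolls Initial value and cap of the
#'   self-adaptive mutation-rate gene (dice rolls per child).
#' @param mut_step_prob Probability that a child's inherited mutation-rate
#'   gene steps by one.
#' @param indel_mean,indel_cap Indel length model in bases.
#' @param stop_handling `"symbol"` or `"truncate"`; see [translate_dna()].
#' @param match,mismatch,gap_open,gap_extend Alignment scoring model.
#' @param positive_residues,negative_residues,h_positive,binding_cap Binding
#'   model; `h_positive = TRUE` adds histidine to the positive set.
#' @param parsimony_threshold,parsimony_coefficient Parsimony pressure.
#' @param consensus_complement Length of the acidic (D/E) tract seeded into
#'   consensus-regime antidotes as a partial binding complement.
#' @param diversity_sample Toxins sampled per generation for the diversity
#'   index.
#' @param diversity_band Half-width of the alignment band used by the
#'   diversity index (`Inf` for full dynamic programming).
#' @param max_fitness_stop Early-termination fitness threshold; retained as a
#'   configuration stub and disabled (`Inf`) in all standard experiments.
#' @param seed Integer random seed; every source of randomness in a run flows
#'   from it.
#' @return An object of class `cif_ea_config` (a validated named list).
#' @examples
#' ea_config(mu = 100, lambda = 10, generations = 50)
#' @export
ea_config <- function(mu = 5000L, lambda = 100L, generations = 1000L,
                      parent_selection = c("k_tournament", "fps", "elitism"),
                      k_tournament = 5L,
                      mating_choice = c("mating_pool", "sorted", "random",
                                        "mixed"),
                      crossover_points = 4,
                      survivor_selection = c("truncation", "k_tournament"),
                      survivor_k = 5L,
                      reinstantiation = c("off", "count", "fraction"),
                      reinstantiation_value = 10,
                      instantiation = c("random", "consensus", "founder"),
                      toxin_length = 3000L, antidote_length = 1400L,
                      founder_fasta = NULL, founder_burnin = 25L,
                      init_mut_rolls = 5L, max_mut_rolls = 50L,
                      mut_step_prob = 0.1,
                      indel_mean = 3, indel_cap = 30L,
                      stop_handling = c("symbol", "truncate"),
                      match = 1, mismatch = -0.5,
                      gap_open = -1, gap_extend = -0.1,
                      positive_residues = "KR", negative_residues = "DE",
                      h_positive = FALSE, binding_cap = 11L,
                      parsimony_threshold = 4500L,
                      parsimony_coefficient = 5e-4,
                      consensus_complement = 6L,
                      diversity_sample = 10L, diversity_band = 64L,
                      max_fitness_stop = Inf,
                      seed = 1L) {
  config <- list(
    mu = as.integer(mu), lambda = as.integer(lambda),
    generations = as.integer(generations),
    parent_selection = match.arg(parent_selection),
    k_tournament = as.integer(k_tournament),
    mating_choice = match.arg(mating_choice),
    crossover_points = if (identical(crossover_points, "mixed")) "mixed"
                       else as.integer(crossover_points),
    survivor_selection = match.arg(survivor_selection),
    survivor_k = as.integer(survivor_k),
    reinstantiation = match.arg(reinstantiation),
    reinstantiation_value = reinstantiation_value,
    instantiation = match.arg(instantiation),
    toxin_length = as.integer(toxin_length),
    antidote_length = as.integer(antidote_length),
    founder_fasta = founder_fasta,
    founder_burnin = as.integer(founder_burnin),
    init_mut_rolls = as.integer(init_mut_rolls),
    max_mut_rolls = as.integer(max_mut_rolls),
    mut_step_prob = mut_step_prob,
    indel_mean = indel_mean, indel_cap = as.integer(indel_cap),
    stop_handling = match.arg(stop_handling),
    match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend,
    positive_residues = positive_residues,
    negative_residues = negative_residues,
    h_positive = isTRUE(h_positive),
    binding_cap = as.integer(binding_cap),
    parsimony_threshold = as.integer(parsimony_threshold),
    parsimony_coefficient = parsimony_coefficient,
    consensus_complement = as.integer(consensus_complement),
    diversity_sample = as.integer(diversity_sample),
    diversity_band = diversity_band,
    max_fitness_stop = max_fitness_stop,
    seed = as.integer(seed)
  )
  validate_ea_config(structure(config, class = "cif_ea_config"))
}

validate_ea_config <- function(config) {
  check <- function(ok, msg) if (!ok) abort(paste0("invalid config: ", msg))
  check(config$mu > 0L, "`mu` must be positive")
  check(config$lambda > 0L, "`lambda` must be positive")
  check(config$generations >= 0L, "`generations` must be non-negative")
  check(config$k_tournament >= 1L && config$k_tournament <= config$mu,
        "`k_tournament` must lie in [1, mu]")
  check(identical(config$crossover_points, "mixed") ||
          config$crossover_points %in% c(1L, 2L, 3L, 4L, 6L),
        "`crossover_points` must be 1, 2, 3, 4, 6 or \"mixed\"")
  check(config$toxin_length >= 0L && config$antidote_length >= 0L,
        "gene lengths must be non-negative")
  check(config$init_mut_rolls >= 0L &&
          config$init_mut_rolls <= config$max_mut_rolls,
        "`init_mut_rolls` must lie in [0, max_mut_rolls]")
  check(config$mut_step_prob >= 0 && config$mut_step_prob <= 1,
        "`mut_step_prob` must lie in [0, 1]")
  check(config$gap_open <= 0 && config$gap_extend <= 0,
        "gap penalties must be non-positive")
  check(config$binding_cap >= 1L, "`binding_cap` must be positive")
  check(config$parsimony_coefficient >= 0,
        "`parsimony_coefficient` must be non-negative")
  if (config$reinstantiation == "count") {
    check(config$reinstantiation_value >= 0 &&
            config$reinstantiation_value <= config$mu,
          "re-instantiation count must lie in [0, mu]")
  }
  if (config$reinstantiation == "fraction") {
    check(config$reinstantiation_value >= 0 &&
            config$reinstantiation_value <= 1,
          "re-instantiation fraction must lie in [0, 1]")
  }
  check(config$diversity_sample >= 2L, "`diversity_sample` must be >= 2")
  config
}

#' @export
print.cif_ea_config <- function(x, ...) {
  cat("<cif_ea_config>\n")
  cat(sprintf("  mu = %d, lambda = %d, generations = %d, seed = %d\n",
              x$mu, x$lambda, x$generations, x$seed))
  cat(sprintf("  instantiation = %s (toxin %d bp, antidote %d bp)\n",
              x$instantiation, x$toxin_length, x$antidote_length))
  cat(sprintf("  parents = %s (K = %d), mating = %s, crossover = %s-point\n",
              x$parent_selection, x$k_tournament, x$mating_choice,
              as.character(x$crossover_points)))
  cat(sprintf("  survivors = %s, reinstantiation = %s\n",
              x$survivor_selection, x$reinstantiation))
  invisible(x)
}

#' Read or write a run configuration as JSON
#'
#' The JSON file holds any subset of [ea_config()] fields; missing fields
#' take their defaults and unknown keys are rejected by name. A saved
#' configuration round-trips exactly.
#'
#' @param path File path.
#' @return `read_ea_config()` returns a `cif_ea_config`;
#'   `write_ea_config()` invisibly returns `path`.
#' @export
read_ea_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ea_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(ea_config, raw)
}

#' @rdname read_ea_config
#' @param config A `cif_ea_config`.
#' @export
write_ea_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (is.infinite(x$max_fitness_stop)) x$max_fitness_stop <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Preset experiment configurations
#'
#' Named configurations for the main experiments: the three instantiation
#' regimes (`"random-start"`, `"consensus-start"`, `"founder-start"`), the
#' population-size contrasts under the founder regime (`"mu-small"` with
#' mu = 1,000 and `"mu-large"` with mu = 20,000), and `"long-toxin"`
#' (founder regime with the initial toxin length doubled to 6,000 bp).
#' `scale` uniformly scales mu, lambda and generations for desk-scale
#' replication; it is a deliberate deviation knob, never applied silently.
#'
#' @param name Preset name.
#' @param scale Scale factor applied to mu, lambda and generations.
#' @param seed Random seed.
#' @return A `cif_ea_config`.
#' @examples
#' ea_preset("founder-start", scale = 0.05)
#' @export
ea_preset <- function(name = c("random-start", "consensus-start",
                               "founder-start", "mu-small", "mu-large",
                               "long-toxin"),
                      scale = 1, seed = 1L) {
  name <- match.arg(name)
  base <- switch(name,
    "random-start" = list(instantiation = "random"),
    "consensus-start" = list(instantiation = "consensus"),
    "founder-start" = list(instantiation = "founder"),
    "mu-small" = list(instantiation = "founder", mu = 1000L),
    "mu-large" = list(instantiation = "founder", mu = 20000L),
    "long-toxin" = list(instantiation = "founder", toxin_length = 6000L)
  )
  args <- modifyList(list(seed = seed), base)
  config <- do.call(ea_config, args)
  if (!identical(scale, 1)) {
    config$mu <- max(2L, as.integer(round(config$mu * scale)))
    config$lambda <- max(2L, as.integer(round(config$lambda * scale)))
    config$generations <- max(1L, as.integer(round(config$generations * scale)))
    config <- validate_ea_config(config)
  }
  config
}
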