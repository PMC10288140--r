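new_individuals <- function(toxin, antidote, mut_rolls, born, id) {
  n <- length(toxin)
  tibble::new_tibble(list(
    id = rep_len(as.integer(id), n),
    born = rep_len(as.integer(born), n),
    toxin = toxin, antidote = antidote,
    mut_rolls = rep_len(as.integer(mut_rolls), n)
  ), nrow = n)
}

fill_wildcards <- function(pattern, residues = aa_letters) {
  chars <- strsplit(pattern, "")[[1]]
  holes <- chars == "-"
  chars[holes] <- sample(residues, sum(holes), replace = TRUE)
  paste(chars, collapse = "")
}

random_protein <- function(n, residues = aa_letters) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

consensus_toxin_dna <- function(config) {
  # filled nuclease + DUB schemas embedded at a random position among random
  # flanks; per-individual length jitter keeps members distinct
  core <- paste0(fill_wildcards(schema_nuclease), fill_wildcards(schema_dub))
  target_aa <- max(nchar(core),
                   round(config$toxin_length / 3 * stats::runif(1, 0.9, 1.1)))
  pad <- target_aa - nchar(core)
  left <- if (pad > 0) sample.int(pad + 1L, 1L) - 1L else 0L
  protein <- paste0(random_protein(left), core, random_protein(pad - left))
  reverse_translate(protein)
}

consensus_antidote_dna <- function(config) {
  # random DNA seeded with a partial acidic complement of binding residues
  n_codons <- max(config$consensus_complement,
                  config$antidote_length %/% 3L)
  protein <- random_protein(n_codons)
  tract <- random_protein(config$consensus_complement, c("D", "E"))
  at <- sample.int(n_codons - config$consensus_complement + 1L, 1L)
  substr(protein, at, at + config$consensus_complement - 1L) <- tract
  reverse_translate(protein)
}

#' Instantiate a starting population
#'
#' The three instantiation regimes, in decreasing order of starting
#' diversity: `"random"` draws every gene as i.i.d. uniform DNA;
#' `"consensus"` builds each toxin around the filled nuclease and
#' deubiquitylase consensus schemas (wildcards filled with random residues,
#' random flanks, per-individual length jitter) and each antidote as random
#' sequence seeded with a short acidic tract as a partial binding
#' complement; `"founder"` derives all mu members by mutagenesis
#' (`founder_burnin` dice rolls per gene pair) of a single founder, read
#' from `founder_fasta` if given and otherwise built by the consensus
#' recipe.
#'
#' @param config An [ea_config()]; `config$instantiation` selects the
#'   regime. Called inside [ea_run()] under the run's seed; call
#'   `set.seed()` yourself for standalone reproducibility.
#' @param evaluate Attach fitness columns via [ta_fitness()] (default).
#' @return A population tibble of `config$mu` rows.
#' @export
instantiate_population <- function(config = ea_config(), evaluate = TRUE) {
  validate_ea_config(config)
  mu <- config$mu
  pop <- switch(config$instantiation,
    random = new_individuals(
      toxin = random_dna(rep(config$toxin_length, mu)),
      antidote = random_dna(rep(config$antidote_length, mu)),
      mut_rolls = rep(config$init_mut_rolls, mu),
      born = 0L, id = seq_len(mu)
    ),
    consensus = new_individuals(
      toxin = vapply(seq_len(mu), function(i) consensus_toxin_dna(config),
                     character(1)),
      antidote = vapply(seq_len(mu), function(i) consensus_antidote_dna(config),
                        character(1)),
      mut_rolls = rep(config$init_mut_rolls, mu),
      born = 0L, id = seq_len(mu)
    ),
    founder = {
      founder <- founder_pair(config)
      new_individuals(
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
      )
    }
  )
  if (evaluate) ta_fitness(pop, config) else pop
}

founder_pair <- function(config) {
  if (!is.null(config$founder_fasta)) {
    read_founder_fasta(config$founder_fasta)
  } else {
    list(toxin = consensus_toxin_dna(config),
         antidote = consensus_antidote_dna(config))
  }
}
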