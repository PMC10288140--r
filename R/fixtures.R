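filled_schema <- function(pattern, fill = "A") {
  gsub("-", fill, pattern, fixed = TRUE)
}

# a literal instance of the T4SS export pattern R-X(7)-R-X-R-X-R with
# alanine in the wildcard slots
t4ss_instance <- function(fill = "A") filled_schema(schema_t4ss, fill)

#' Construct a perfect toxin-antidote pair
#'
#' Builds a TA individual that attains the maximum fitness of 5: the toxin
#' protein carries the nuclease and deubiquitylase schemas with wildcards
#' filled by alanine (chemically neutral: charge-free and unable to create
#' spurious motif or binding hits), the KRAR nuclear-localisation signal, a
#' literal T4SS export motif and an 11-lysine tract; the antidote carries
#' the complementary 11-aspartate tract plus neutral filler. Genes are
#' reverse-translated with seed-determined synonymous codons and the genome
#' stays far below the 4,500-bp parsimony threshold.
#'
#' @param seed Integer seed controlling codon choice and filler.
#' @param antidote_aa_length Total antidote protein length (residues).
#' @return A one-row evaluated population tibble (see [ta_fitness()]).
#' @examples
#' make_perfect_ta(1)$fitness # 5
#' @export
make_perfect_ta <- function(seed = 1L, antidote_aa_length = 100L) {
  set.seed(seed)
  toxin_aa <- paste0(
    filled_schema(schema_nuclease), filled_schema(schema_dub),
    schema_nls, t4ss_instance(), strrep("K", 11L)
  )
  if (antidote_aa_length < 11L) abort("antidote must hold the 11-D tract")
  antidote_aa <- paste0(strrep("D", 11L),
                        random_protein(antidote_aa_length - 11L,
                                       neutral_residues))
  ta <- new_individuals(toxin = reverse_translate(toxin_aa),
                        antidote = reverse_translate(antidote_aa),
                        mut_rolls = 0L, born = 0L, id = 1L)
  ta_fitness(ta)
}

#' Construct a partial toxin-antidote fixture
#'
#' Installs only the requested features on a neutral-filler backbone, so
#' each scoring contract can be exercised in isolation. Features:
#' `"nuclease"`, `"dub"` (toxin domains), `"nls"`, `"t4ss"` (signals,
#' placeable in either gene via `nls_in` / `t4ss_in`), `"binding"` (an
#' 11-K tract in the toxin and 11-D tract in the antidote), and junk
#' padding in bp (rounded up to whole neutral codons) to trigger parsimony
#' pressure. Requesting a feature twice is an error.
#'
#' @param features Character vector of feature names (possibly empty).
#' @param nls_in,t4ss_in `"toxin"` or `"antidote"`.
#' @param junk_bp Extra neutral base pairs appended to the toxin.
#' @param seed Integer seed.
#' @param base_aa Length of each gene's neutral backbone (residues).
#' @return A one-row evaluated population tibble.
#' @examples
#' make_partial_ta("nls", nls_in = "antidote")$nls_loc # "antidote"
#' @export
make_partial_ta <- function(features = character(), nls_in = "toxin",
                            t4ss_in = "toxin", junk_bp = 0L, seed = 1L,
                            base_aa = 60L) {
  allowed <- c("nuclease", "dub", "nls", "t4ss", "binding")
  bad <- setdiff(features, allowed)
  if (length(bad)) {
    abort(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(features)) {
    abort("features must not overlap (each may be requested once)")
  }
  nls_in <- match.arg(nls_in, c("toxin", "antidote"))
  t4ss_in <- match.arg(t4ss_in, c("toxin", "antidote"))
  set.seed(seed)
  toxin_aa <- random_protein(base_aa, neutral_residues)
  antidote_aa <- random_protein(base_aa, neutral_residues)
  add <- function(target, piece) {
    if (target == "toxin") toxin_aa <<- paste0(toxin_aa, piece)
    else antidote_aa <<- paste0(antidote_aa, piece)
  }
  for (f in features) {
    switch(f,
      nuclease = add("toxin", filled_schema(schema_nuclease)),
      dub = add("toxin", filled_schema(schema_dub)),
      nls = add(nls_in, schema_nls),
      t4ss = add(t4ss_in, t4ss_instance()),
      binding = {
        add("toxin", strrep("K", 11L))
        add("antidote", strrep("D", 11L))
      }
    )
  }
  if (junk_bp > 0L) {
    add("toxin", random_protein(ceiling(junk_bp / 3), neutral_residues))
  }
  ta <- new_individuals(toxin = reverse_translate(toxin_aa),
                        antidote = reverse_translate(antidote_aa),
                        mut_rolls = 0L, born = 0L, id = 1L)
  ta_fitness(ta)
}
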