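clamp01 <- function(x) pmin(1, pmax(0, x))

#' Schema similarity score of a protein
#'
#' Ends-free pairwise alignment of a protein against a consensus schema with
#' affine gaps (open -1, extension -0.1, end gaps free, matching the
#' alignment model used throughout the fitness function). Required pattern
#' positions score +1 on identity and -0.5 on mismatch; wildcard positions
#' cost 0 against any residue. The raw score is divided by the perfect-match
#' score (the number of required positions) and clamped to `[0, 1]`, so a
#' protein containing the fully realised schema scores exactly 1 and partial
#' occurrences earn proportional credit.
#'
#' @param protein Character vector of protein strings.
#' @param schema A schema name (`"dub"`, `"nuclease"`, `"nls"`, `"t4ss"`) or
#'   a pattern string of residue letters and `-` wildcards.
#' @param match,mismatch Scores at required positions.
#' @param gap_open,gap_extend Gap penalties (non-positive); a length-L gap
#'   costs `gap_open + (L - 1) * gap_extend`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' score_schema("HWVTLVIAAAAAAAAAYYADSLAAAAAAAAIAAALAAAAADAAAAAAAAAQQADGAAACGAAAAEN",
#'               "dub") # 1
#' @export
score_schema <- function(protein, schema, match = 1, mismatch = -0.5,
                         gap_open = -1, gap_extend = -0.1) {
  pattern <- resolve_schema(schema)
  required <- sum(strsplit(pattern, "")[[1]] != "-")
  if (required == 0L) abort("schema has no required positions")
  raw <- vapply(protein, cpp_schema_align, numeric(1),
                b = pattern, match = match, mismatch = mismatch,
                open = -gap_open, ext = -gap_extend, USE.NAMES = FALSE)
  clamp01(raw / required)
}

#' @rdname score_schema
#' @details `score_nls()` and `score_t4ss()` return 1 whenever the full
#'   motif occurs as a substring (wildcards match any residue except the stop
#'   symbol) and otherwise fall back to the partial alignment score of the
#'   motif pattern.
#' @export
score_nls <- function(protein, ...) {
  ifelse(grepl(motif_regex[["nls"]], protein),
         1, score_schema(protein, "nls", ...))
}

#' @rdname score_schema
#' @param ... Passed on to `score_schema()`.
#' @export
score_t4ss <- function(protein, ...) {
  ifelse(grepl(motif_regex[["t4ss"]], protein),
         1, score_schema(protein, "t4ss", ...))
}

#' Toxin-antidote binding score
#'
#' Slides the two proteins along each other without gaps; at each relative
#' offset every aligned residue pair tallies +1 if one residue is positively
#' charged (K/R; optionally H) and the other negatively charged (D/E), and
#' -1 if both carry the same charge (repulsion). The best tally over all
#' offsets is floored at 0, capped at `cap` (11 residues, the number of
#' charged positions known to underlie cifA-cifB binding) and divided by
#' `cap`. Symmetric in its two arguments.
#'
#' @param toxin,antidote Protein strings (vectorised, recycled pairwise).
#' @param positive,negative Residue sets as strings, e.g. `"KR"` / `"DE"`.
#' @param cap Maximum number of scoring pairs.
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' score_binding(strrep("K", 11), strrep("D", 11)) # 1
#' @export
score_binding <- function(toxin, antidote, positive = "KR", negative = "DE",
                          cap = 11L) {
  n <- max(length(toxin), length(antidote))
  toxin <- rep_len(toxin, n)
  antidote <- rep_len(antidote, n)
  raw <- mapply(cpp_binding_tally, toxin, antidote,
                MoreArgs = list(positive = positive, negative = negative),
                USE.NAMES = FALSE)
  pmin(cap, pmax(0L, raw)) / cap
}

#' Parsimony penalty on genome length
#'
#' Zero at or below the threshold (4,500 bp, an estimate of average cif TA
#' genome size) and increasing linearly with every extra base pair beyond it,
#' mimicking the genome-reduction pressure acting on Wolbachia.
#'
#' @param genome_bp Total DNA length of the TA pair in base pairs.
#' @param threshold Threshold in bp.
#' @param coefficient Penalty per excess base pair.
#' @return Non-negative numeric vector.
#' @examples
#' parsimony_penalty(c(4000, 4500, 5500))
#' @export
parsimony_penalty <- function(genome_bp, threshold = 4500,
                              coefficient = 5e-4) {
  coefficient * pmax(0, genome_bp - threshold)
}

signal_location_code <- function(in_toxin, in_antidote) {
  dplyr::case_when(
    in_toxin & in_antidote ~ "both",
    in_toxin ~ "toxin",
    in_antidote ~ "antidote",
    .default = "absent"
  )
}

#' Evaluate the five-component fitness of toxin-antidote pairs
#'
#' The central fitness function: for each row of `pairs` (DNA columns
#' `toxin` and `antidote`), translates both genes and computes the five
#' sub-scores -- nuclease and deubiquitylase schema similarity of the toxin
#' protein, charge-complementary binding of the pair, and NLS and T4SS
#' signal scores taken as the maximum over the two proteins (so selection is
#' free to place either signal in either gene) -- plus the parsimony penalty
#' on total genome length. Total fitness is the sum of the five sub-scores
#' (each in `[0, 1]`, so at most 5) minus the penalty.
#'
#' @param pairs A data frame with character columns `toxin` and `antidote`
#'   holding DNA gene sequences; other columns are preserved.
#' @param config An [ea_config()] supplying scoring parameters.
#' @return A tibble: the input plus columns `toxin_aa`, `antidote_aa`,
#'   `binding`, `nuclease`, `dub`, `nls`, `t4ss`, `parsimony`, `fitness`,
#'   and full-motif location calls `nls_loc`, `t4ss_loc` (each one of
#'   `"toxin"`, `"antidote"`, `"both"`, `"absent"`).
#' @examples
#' ta_fitness(tibble::tibble(toxin = "ATGAAACGCGCGCGC", antidote = "GATGAC"))
#' @export
ta_fitness <- function(pairs, config = ea_config()) {
  pairs <- as_tibble(pairs)
  tox_aa <- translate_dna(pairs$toxin, config$stop_handling)
  ant_aa <- translate_dna(pairs$antidote, config$stop_handling)
  align <- function(p, schema) {
    score_schema(p, schema, match = config$match, mismatch = config$mismatch,
                 gap_open = config$gap_open, gap_extend = config$gap_extend)
  }
  positive <- if (isTRUE(config$h_positive)) "KRH" else config$positive_residues
  nls_t <- grepl(motif_regex[["nls"]], tox_aa)
  nls_a <- grepl(motif_regex[["nls"]], ant_aa)
  t4_t <- grepl(motif_regex[["t4ss"]], tox_aa)
  t4_a <- grepl(motif_regex[["t4ss"]], ant_aa)
  nls <- pmax(ifelse(nls_t, 1, align(tox_aa, "nls")),
              ifelse(nls_a, 1, align(ant_aa, "nls")))
  t4ss <- pmax(ifelse(t4_t, 1, align(tox_aa, "t4ss")),
               ifelse(t4_a, 1, align(ant_aa, "t4ss")))
  binding <- score_binding(tox_aa, ant_aa, positive = positive,
                           negative = config$negative_residues,
                           cap = config$binding_cap)
  nuclease <- align(tox_aa, "nuclease")
  dub <- align(tox_aa, "dub")
  parsimony <- parsimony_penalty(
    nchar(pairs$toxin) + nchar(pairs$antidote),
    threshold = config$parsimony_threshold,
    coefficient = config$parsimony_coefficient
  )
  cols <- as.list(pairs)
  cols[c("toxin_aa", "antidote_aa", "binding", "nuclease", "dub", "nls",
         "t4ss", "parsimony", "fitness", "nls_loc", "t4ss_loc")] <-
    list(tox_aa, ant_aa, binding, nuclease, dub, nls, t4ss, parsimony,
         binding + nuclease + dub + nls + t4ss - parsimony,
         signal_location_code(nls_t, nls_a),
         signal_location_code(t4_t, t4_a))
  tibble::new_tibble(cols, nrow = nrow(pairs))
}

#' Locate a signal motif within a TA pair
#'
#' Checks full-motif presence (no partial credit) in the toxin and antidote
#' proteins of each pair and reports where the signal resides. In the
#' population-level location bias, `"antidote"` codes 0 (the 2x1
#' architecture, signal in cifA) and `"toxin"` codes 1 (the strict
#' toxin-antidote architecture, signal in cifB).
#'
#' @param pairs A data frame with DNA columns `toxin` and `antidote`, or an
#'   evaluated population from [ta_fitness()].
#' @param signal `"nls"` or `"t4ss"`.
#' @param stop_handling Passed to [translate_dna()] when proteins are not
#'   already cached in the input.
#' @return Character vector over `"toxin"`, `"antidote"`, `"both"`,
#'   `"absent"`.
#' @export
locate_signal <- function(pairs, signal = c("nls", "t4ss"),
                          stop_handling = "symbol") {
  signal <- match.arg(signal)
  loc_col <- paste0(signal, "_loc")
  if (loc_col %in% names(pairs)) return(pairs[[loc_col]])
  tox_aa <- if ("toxin_aa" %in% names(pairs)) pairs$toxin_aa
            else translate_dna(pairs$toxin, stop_handling)
  ant_aa <- if ("antidote_aa" %in% names(pairs)) pairs$antidote_aa
            else translate_dna(pairs$antidote, stop_handling)
  rx <- motif_regex[[signal]]
  signal_location_code(grepl(rx, tox_aa), grepl(rx, ant_aa))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
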