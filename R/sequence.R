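#' Translate DNA genes to protein strings
#'
#' Reads non-overlapping codons from position 1 under the standard genetic
#' code; trailing 1-2 leftover bases are ignored. By default an in-frame stop
#' codon is rendered as the dedicated symbol `*` (which matches nothing in
#' any schema or motif) and translation continues through it, so scoring is
#' defined for arbitrary random DNA; `stop_handling = "truncate"` ends the
#' protein at the first stop instead.
#'
#' @param dna Character vector of DNA strings over `A/C/G/T` (uppercase).
#' @param stop_handling `"symbol"` (default) or `"truncate"`.
#' @return Character vector of protein strings.
#' @examples
#' translate_dna("ATGAAACGCGCGCGC") # "MKRAR"
#' translate_dna("ATGTAAATG")       # "M*M"
#' translate_dna("ATGTAAATG", stop_handling = "truncate") # "M"
#' @export
translate_dna <- function(dna, stop_handling = c("symbol", "truncate")) {
  stop_handling <- match.arg(stop_handling)
  code <- codon_table()$code64
  vapply(dna, cpp_translate, character(1), code64 = code,
         truncate_at_stop = identical(stop_handling, "truncate"),
         USE.NAMES = FALSE)
}

#' Generate uniform random DNA
#'
#' Each position is an i.i.d. uniform draw over `A/C/G/T`; reproducible under
#' a fixed RNG seed.
#'
#' @param length Non-negative integer length(s); vectorised.
#' @return Character vector of DNA strings, one per element of `length`.
#' @examples
#' set.seed(1)
#' random_dna(12)
#' @export
random_dna <- function(length) {
  if (any(length < 0)) abort("`length` must be non-negative")
  vapply(length, function(n) {
    paste(sample(dna_bases, n, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse-translate protein strings to DNA
#'
#' Each residue is replaced by a uniformly chosen synonymous codon (stops
#' `*` by a uniform stop codon), so `translate_dna(reverse_translate(p))`
#' recovers `p` exactly.
#'
#' @param protein Character vector of protein strings (20 IUPAC letters
#'   plus `*`).
#' @return Character vector of DNA strings.
#' @examples
#' translate_dna(reverse_translate("KRAR")) # "KRAR"
#' @export
reverse_translate <- function(protein) {
  by_aa <- codon_table()$codons_by_aa
  vapply(protein, function(p) {
    if (!nzchar(p)) return("")
    res <- strsplit(p, "")[[1]]
    bad <- which(!res %in% names(by_aa))
    if (length(bad)) {
      abort(sprintf("unknown residue '%s' at position %d", res[bad[1]], bad[1]))
    }
    out <- character(length(res))
    for (aa in unique(res)) {
      i <- which(res == aa)
      cods <- by_aa[[aa]]
      out[i] <- cods[sample.int(length(cods), length(i), replace = TRUE)]
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rindel_length <- function(mean_len, cap) {
  # geometric length model, mean `mean_len`, hard cap
  min(cap, rgeom(1L, prob = 1 / mean_len) + 1L)
}

#' Mutate a DNA gene with the four-sided mutation dice
#'
#' Applies `rolls` independent dice rolls; each roll picks uniformly among
#' do-nothing, substitution (a uniform random base, possibly the same one,
#' written at a uniform random position), insertion, and deletion. Indel
#' lengths follow a geometric distribution (mean `indel_mean`, capped at
#' `indel_cap` bases); a deletion never removes more bases than remain after
#' its start. `rolls = 0` is the identity.
#'
#' @param dna A single DNA string.
#' @param rolls Non-negative integer number of dice rolls.
#' @param indel_mean,indel_cap Indel length model (bases).
#' @return The mutated DNA string.
#' @examples
#' set.seed(1)
#' mutate_dna(strrep("ACGT", 10), rolls = 3)
#' @export
mutate_dna <- function(dna, rolls, indel_mean = 3, indel_cap = 30L) {
  if (rolls < 0) abort("`rolls` must be non-negative")
  for (r in seq_len(rolls)) {
    action <- sample.int(4L, 1L)
    len <- nchar(dna)
    if (action == 2L && len > 0L) {        # substitution
      pos <- sample.int(len, 1L)
      substr(dna, pos, pos) <- sample(dna_bases, 1L)
    } else if (action == 3L) {             # insertion
      pos <- sample.int(len + 1L, 1L) - 1L # insert after `pos` bases
      ins <- paste(sample(dna_bases, rindel_length(indel_mean, indel_cap),
                          replace = TRUE), collapse = "")
      dna <- paste0(substr(dna, 1L, pos), ins, substr(dna, pos + 1L, len))
    } else if (action == 4L && len > 0L) { # deletion
      start <- sample.int(len, 1L)
      L <- min(rindel_length(indel_mean, indel_cap), len - start + 1L)
      dna <- paste0(substr(dna, 1L, start - 1L), substr(dna, start + L, len))
    }
  }
  dna
}

#' n-point crossover of two DNA genes
#'
#' Draws `n_points` distinct cut positions uniformly within the shorter
#' parent and exchanges alternating segments, producing two children. The
#' tail beyond the shorter parent's length stays with its original child, so
#' the multiset of bases at each position below the minimum length is
#' conserved between the parent pair and the child pair. If the parents are
#' too short for the requested point count it degrades to the largest
#' feasible count with a warning.
#'
#' @param a,b Parent DNA strings (non-empty).
#' @param n_points One of 1, 2, 3, 4, 6 or `"mixed"` (uniform choice among
#'   those five).
#' @return Character vector of the two children.
#' @examples
#' crossover_dna("AAAAAA", "CCCCCC", n_points = 1)
#' @export
crossover_dna <- function(a, b, n_points = 4) {
  if (!nzchar(a) || !nzchar(b)) abort("crossover parents must be non-empty")
  if (identical(n_points, "mixed")) n_points <- sample(c(1, 2, 3, 4, 6), 1L)
  if (!n_points %in% c(1, 2, 3, 4, 6)) {
    abort("`n_points` must be 1, 2, 3, 4, 6 or \"mixed\"")
  }
  minlen <- min(nchar(a), nchar(b))
  feasible <- minlen - 1L
  if (feasible < n_points) {
    warn(sprintf(
      "parents support at most %d crossover points; degrading from %d",
      max(0L, feasible), as.integer(n_points)
    ))
    n_points <- max(0L, feasible)
  }
  if (n_points == 0L) return(c(a, b))
  cuts <- sort(sample.int(minlen - 1L, n_points))
  bounds <- c(0L, cuts, minlen)
  c1 <- character(length(bounds) - 1L)
  c2 <- character(length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    from <- bounds[k] + 1L
    to <- bounds[k + 1L]
    if (k %% 2L == 1L) {  # odd segments keep, even segments swap
      c1[k] <- substr(a, from, to)
      c2[k] <- substr(b, from, to)
    } else {
      c1[k] <- substr(b, from, to)
      c2[k] <- substr(a, from, to)
    }
  }
  c(
    paste0(paste(c1, collapse = ""), substr(a, minlen + 1L, nchar(a))),
    paste0(paste(c2, collapse = ""), substr(b, minlen + 1L, nchar(b)))
  )
}
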