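#' Consensus schemas and motifs scored by the fitness function
#'
#' The four sequence patterns that define toxin-antidote (TA) function in the
#' simulator. `dub` and `nuclease` are the cid deubiquitylase and cin nuclease
#' toxin-domain consensus schemas; `nls` is the nuclear-localisation signal
#' motif (KRAR) and `t4ss` the type-IV-secretion export signal
#' (R-X(7)-R-X-R-X-R). In a pattern, letters are required residues and `-` is
#' a wildcard ("do not care") position that matches any residue at zero cost.
#'
#' @return A tibble with columns `name`, `pattern`, `required_count` (number
#'   of non-wildcard positions, i.e. the perfect-match alignment score used to
#'   normalise schema scores) and `length`.
#' @examples
#' cif_schemas()
#' @export
cif_schemas <- function() {
  tibble::tibble(
    name = c("dub", "nuclease", "nls", "t4ss"),
    pattern = c(schema_dub, schema_nuclease, schema_nls, schema_t4ss),
    required_count = vapply(
      c(schema_dub, schema_nuclease, schema_nls, schema_t4ss),
      function(p) sum(strsplit(p, "")[[1]] != "-"), integer(1),
      USE.NAMES = FALSE
    ),
    length = nchar(c(schema_dub, schema_nuclease, schema_nls, schema_t4ss))
  )
}

schema_dub <-
  "HWVTLVI---------YY-DSL--------I---L-----D---------QQ-DG---CG----EN"
schema_nuclease <-
  "DL-LL-R----------PIIIELK---------------------DLVL----------PIGLELK"
schema_nls <- "KRAR"
schema_t4ss <- "R-------R-R-R"

# full-motif presence as regular expressions; wildcards match any residue
# except the stop symbol, which matches nothing in any motif
motif_regex <- c(
  nls = "KRAR",
  t4ss = "R[^*]{7}R[^*]R[^*]R"
)

#' Fixed scoring constants of the fitness model
#'
#' Machine-readable table of the non-schema constants: the binding-residue
#' cap (11 complementary charge pairs, the number known to underlie
#' cifA-cifB binding), the parsimony threshold (4,500 bp, an estimate of
#' average cif TA genome size), and the pairwise-alignment gap model used for
#' all schema scoring (gap open -1, gap extension -0.1, end gaps free).
#'
#' @return A tibble with columns `parameter` and `value`.
#' @examples
#' cif_params()
#' @export
cif_params <- function() {
  tibble::tibble(
    parameter = c("binding_max_pairs", "parsimony_threshold_bp",
                  "gap_open", "gap_extend", "match_reward",
                  "mismatch_penalty"),
    value = c(11, 4500, -1, -0.1, 1, -0.5)
  )
}

resolve_schema <- function(schema) {
  if (schema %in% c("dub", "nuclease", "nls", "t4ss")) {
    switch(schema,
      dub = schema_dub, nuclease = schema_nuclease,
      nls = schema_nls, t4ss = schema_t4ss
    )
  } else {
    ok <- grepl("^[-ACDEFGHIKLMNPQRSTVWY]*$", schema)
    if (!all(ok)) {
      abort("schema pattern must use amino-acid letters and '-' wildcards")
    }
    schema
  }
}
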