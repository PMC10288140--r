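#' Write and read populations as FASTA
#'
#' One DNA record per gene with headers `>runID|generation|id|toxin` and
#' `>runID|generation|id|antidote`, so a population round-trips through
#' FASTA unchanged and any individual can be re-used as a founder.
#'
#' @param population A population tibble.
#' @param path FASTA file path.
#' @param run_id Run identifier written into the headers.
#' @param generation Generation stamp written into the headers.
#' @return `write_population_fasta()` invisibly returns `path`;
#'   `read_population_fasta()` returns a population tibble (ids and the
#'   mutation-rate gene restored from the headers when present).
#' @export
write_population_fasta <- function(population, path, run_id = "run",
                                   generation = NULL) {
  gen <- generation %||% max(population$born)
  seqs <- Biostrings::DNAStringSet(c(population$toxin, population$antidote))
  names(seqs) <- c(
    sprintf("%s|%d|%d|toxin|rolls=%d", run_id, gen, population$id,
            population$mut_rolls),
    sprintf("%s|%d|%d|antidote|rolls=%d", run_id, gen, population$id,
            population$mut_rolls)
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_population_fasta
#' @export
read_population_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  ok <- lengths(parts) >= 4L
  if (!all(ok)) abort("malformed population FASTA: headers need runID|gen|id|gene")
  meta <- tibble(
    gen = as.integer(vapply(parts, `[[`, character(1), 2L)),
    id = as.integer(vapply(parts, `[[`, character(1), 3L)),
    gene = vapply(parts, `[[`, character(1), 4L),
    rolls = vapply(parts, function(p) {
      r <- grep("^rolls=", p, value = TRUE)
      if (length(r)) as.integer(sub("^rolls=", "", r[1])) else NA_integer_
    }, integer(1)),
    seq = unname(as.character(seqs))
  )
  if (!all(meta$gene %in% c("toxin", "antidote"))) {
    abort("malformed population FASTA: gene field must be toxin or antidote")
  }
  wide <- tidyr::pivot_wider(meta, names_from = "gene", values_from = "seq")
  if (anyNA(wide$toxin) || anyNA(wide$antidote)) {
    abort("malformed population FASTA: unpaired toxin/antidote records")
  }
  new_individuals(toxin = wide$toxin, antidote = wide$antidote,
                  mut_rolls = dplyr::coalesce(wide$rolls, 0L),
                  born = wide$gen, id = wide$id)
}

read_founder_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("founder FASTA not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  tox <- grep("(^|\\|)toxin($|\\|)", nm)
  ant <- grep("(^|\\|)antidote($|\\|)", nm)
  if (!length(tox) || !length(ant)) {
    abort("founder FASTA must contain one record labelled 'toxin' and one 'antidote'")
  }
  list(toxin = as.character(seqs[[tox[1]]]),
       antidote = as.character(seqs[[ant[1]]]))
}

#' Save a run's outputs for reproducibility
#'
#' Writes, next to each other: the configuration snapshot (`config.json`),
#' the per-generation log (`run_<seed>.csv`, the fifteen observables in
#' their canonical order plus generation and carrier denominators), the
#' terminal population (`final_<seed>.fasta`) and a plain-text manifest
#' sufficient to re-run the experiment exactly.
#'
#' @param run A `cif_ea_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
save_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.json")
  log_path <- file.path(dir, sprintf("run_%d.csv", run$seed))
  fasta_path <- file.path(dir, sprintf("final_%d.fasta", run$seed))
  write_ea_config(run$config, cfg_path)
  readr::write_csv(run$log, log_path)
  write_population_fasta(run$final, fasta_path,
                         run_id = sprintf("run_%d", run$seed))
  manifest <- file.path(dir, sprintf("manifest_%d.txt", run$seed))
  writeLines(c(
    sprintf("cifevo %s", as.character(packageVersion("cifevo"))),
    sprintf("seed: %d", run$seed),
    sprintf("generations: %d", max(run$log$generation)),
    sprintf("elapsed_seconds: %.2f", run$elapsed),
    sprintf("config: %s", basename(cfg_path)),
    sprintf("log: %s", basename(log_path)),
    sprintf("final_population: %s", basename(fasta_path)),
    sprintf("finished: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), manifest)
  invisible(manifest)
}
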