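#' Population diversity index
#'
#' Randomly samples `n_sample` toxins (all of them if the population is
#' smaller), computes the pairwise amino-acid similarity of every pair as
#' ends-free alignment identity (matched residues / aligned columns, under
#' the fitness module's gap model) and reports one minus the mean
#' similarity: 0 for a clonal population, approaching 1 for unrelated
#' random strings. Alignment is banded (half-width `band` plus the length
#' difference); `band = Inf` forces the full dynamic programme.
#'
#' @param population A population tibble (or any data frame with a
#'   `toxin_aa` column; DNA in `toxin` is translated if needed).
#' @param n_sample Number of toxins to sample (default 10, i.e. 45 pairs).
#' @param band Alignment band half-width in residues.
#' @param config Scoring parameters ([ea_config()]).
#' @return A single number in `[0, 1]`.
#' @export
diversity_index <- function(population, n_sample = 10L, band = 64L,
                            config = ea_config()) {
  prot <- if ("toxin_aa" %in% names(population)) population$toxin_aa
          else translate_dna(population$toxin, config$stop_handling)
  n <- length(prot)
  if (n < 2L) return(NA_real_)
  take <- if (n > n_sample) sample.int(n, n_sample) else seq_len(n)
  prot <- prot[take]
  w <- if (is.finite(band)) as.integer(band) else
    max(nchar(prot), 1L)
  # identical strings have identity 1 by definition: align unique sequences
  # only and weight pair counts by multiplicity (exact, order-free mean)
  uniq <- unique(prot)
  mult <- tabulate(match(prot, uniq), nbins = length(uniq))
  n_pairs <- length(prot) * (length(prot) - 1) / 2
  within <- sum(mult * (mult - 1) / 2)
  total_sim <- within  # clonal pairs contribute identity 1
  if (length(uniq) > 1L) {
    sims <- cpp_pairwise_identity(uniq, config$match, config$mismatch,
                                  -config$gap_open, -config$gap_extend, w)
    k <- 0L
    for (i in seq_len(length(uniq) - 1L)) {
      for (j in (i + 1L):length(uniq)) {
        k <- k + 1L
        total_sim <- total_sim + mult[i] * mult[j] * sims[k]
      }
    }
  }
  1 - total_sim / n_pairs
}

location_codes <- c(antidote = 0, toxin = 1, both = 0.5)

#' Population-level signal location bias
#'
#' Averages the per-individual location codes of a signal over the
#' individuals that carry the full motif: 0 when the signal sits in the
#' antidote gene (cifA, the 2x1 architecture), 1 when it sits in the toxin
#' gene (cifB, the strict toxin-antidote architecture), 0.5 for carriers
#' with the motif in both genes. Returns `NA` when no individual carries
#' the motif (never silently 0.5).
#'
#' @param population An evaluated population tibble.
#' @param signal `"nls"` or `"t4ss"`.
#' @return A number in `[0, 1]`, or `NA` if there are no carriers.
#' @export
location_bias <- function(population, signal = c("nls", "t4ss")) {
  signal <- match.arg(signal)
  loc <- locate_signal(population, signal)
  carriers <- loc != "absent"
  if (!any(carriers)) return(NA_real_)
  mean(location_codes[loc[carriers]])
}

#' Per-generation summary of the fifteen tracked observables
#'
#' Computes, over the full population: the highest and mean total TA
#' fitness; mean binding, DUB, nuclease, NLS and T4SS sub-fitness; mean
#' toxin and antidote lengths in bp and in residues; the mean self-adaptive
#' mutation rate; the NLS and T4SS location biases (carrier-only, with the
#' carrier counts logged as denominators); and the diversity index.
#'
#' @param population An evaluated population tibble.
#' @param generation Generation number for the log row.
#' @param config An [ea_config()] (diversity sampling and band).
#' @return A one-row tibble using the observables' canonical column names.
#' @export
generation_summary <- function(population, generation = 0L,
                               config = ea_config()) {
  nls_loc <- population$nls_loc
  t4ss_loc <- population$t4ss_loc
  tibble::new_tibble(list(
    generation = as.integer(generation),
    highestTAFitness_HTF = max(population$fitness),
    avgBindingFitness_ABF = mean(population$binding),
    avgDUBFitness_ADF = mean(population$dub),
    avgNucFitness_ANF = mean(population$nuclease),
    avgTAfitness_ATF = mean(population$fitness),
    avgToxinLength_ATL = mean(nchar(population$toxin)),
    avgToxinAALength_ATAL = mean(nchar(population$toxin_aa)),
    avgAntidoteLength_AAL = mean(nchar(population$antidote)),
    avgAntidoteAALength_AAAL = mean(nchar(population$antidote_aa)),
    avgTAMutationRate_ATMR = mean(population$mut_rolls),
    avgNLSSITELocation_NLSL = location_bias(population, "nls"),
    avgTypeIVSITELocation_TYPL = location_bias(population, "t4ss"),
    avgNLSFitness_ANLSF = mean(population$nls),
    avgT4SSFitness_AT4F = mean(population$t4ss),
    diversityIndex_DI = diversity_index(population,
                                        n_sample = config$diversity_sample,
                                        band = config$diversity_band,
                                        config = config),
    nlsCarriers = sum(nls_loc != "absent"),
    t4ssCarriers = sum(t4ss_loc != "absent")
  ), nrow = 1L)
}

observable_names <- c(
  "highestTAFitness_HTF", "avgBindingFitness_ABF", "avgDUBFitness_ADF",
  "avgNucFitness_ANF", "avgTAfitness_ATF", "avgToxinLength_ATL",
  "avgToxinAALength_ATAL", "avgAntidoteLength_AAL",
  "avgAntidoteAALength_AAAL", "avgTAMutationRate_ATMR",
  "avgNLSSITELocation_NLSL", "avgTypeIVSITELocation_TYPL",
  "avgNLSFitness_ANLSF", "avgT4SSFitness_AT4F", "diversityIndex_DI"
)

terminal_rows <- function(logs) {
  dplyr::slice_max(group_by(logs, .data$run), .data$generation,
                   n = 1L, with_ties = FALSE) |> ungroup()
}

#' Summarise a replicate set
#'
#' Terminal statistics (mean and standard deviation at the final generation,
#' computed per observable across runs) and, optionally via
#' [trajectory_summary()], the per-generation mean +/- sd band data of the
#' trajectory plots.
#'
#' @param replicates A `cif_ea_replicates` object (or its combined `logs`
#'   tibble with a `run` column).
#' @return A long tibble with columns `observable`, `statistic`
#'   (`"mean"`/`"sd"`) and `value`.
#' @export
replicate_summary <- function(replicates) {
  logs <- if (inherits(replicates, "cif_ea_replicates")) replicates$logs
          else replicates
  term <- terminal_rows(logs)
  long <- tidyr::pivot_longer(term, dplyr::all_of(observable_names),
                              names_to = "observable", values_to = "value")
  summarise(group_by(long, .data$observable),
            mean = mean(.data$value, na.rm = TRUE),
            sd = sd(.data$value, na.rm = TRUE),
            n = sum(!is.na(.data$value)),
            .groups = "drop") |>
    tidyr::pivot_longer(c("mean", "sd"), names_to = "statistic",
                        values_to = "value") |>
    dplyr::select("observable", "statistic", "value", "n") |>
    arrange(.data$observable, .data$statistic)
}

#' @rdname replicate_summary
#' @export
trajectory_summary <- function(replicates) {
  logs <- if (inherits(replicates, "cif_ea_replicates")) replicates$logs
          else replicates
  long <- tidyr::pivot_longer(logs, dplyr::all_of(observable_names),
                              names_to = "observable", values_to = "value")
  summarise(group_by(long, .data$generation, .data$observable),
            mean = mean(.data$value, na.rm = TRUE),
            sd = sd(.data$value, na.rm = TRUE),
            n = sum(!is.na(.data$value)),
            .groups = "drop")
}
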