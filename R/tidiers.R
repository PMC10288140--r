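#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation run
#'
#' `tidy()` returns the per-generation log (one row per generation, the
#' fifteen observables plus carrier denominators); `glance()` returns a
#' one-row terminal summary.
#'
#' @param x A `cif_ea_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cif_ea_run <- function(x, ...) x$log

#' @rdname tidy.cif_ea_run
#' @export
glance.cif_ea_run <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble(
    generations = last$generation,
    best_fitness = last$highestTAFitness_HTF,
    mean_fitness = last$avgTAfitness_ATF,
    diversity = last$diversityIndex_DI,
    nls_location = last$avgNLSSITELocation_NLSL,
    t4ss_location = last$avgTypeIVSITELocation_TYPL,
    elapsed = x$elapsed
  )
}

#' @rdname tidy.cif_ea_run
#' @export
tidy.cif_ea_replicates <- function(x, ...) x$logs

#' @rdname tidy.cif_ea_run
#' @export
glance.cif_ea_replicates <- function(x, ...) {
  term <- terminal_rows(x$logs)
  tibble(
    runs = nrow(term),
    generations = max(term$generation),
    mean_best_fitness = mean(term$highestTAFitness_HTF),
    mean_fitness = mean(term$avgTAfitness_ATF),
    mean_diversity = mean(term$diversityIndex_DI, na.rm = TRUE),
    mean_nls_location = mean(term$avgNLSSITELocation_NLSL, na.rm = TRUE),
    mean_t4ss_location = mean(term$avgTypeIVSITELocation_TYPL, na.rm = TRUE)
  )
}

default_panels <- c(
  "avgTAfitness_ATF", "highestTAFitness_HTF", "avgBindingFitness_ABF",
  "avgDUBFitness_ADF", "avgNucFitness_ANF", "avgNLSFitness_ANLSF",
  "avgT4SSFitness_AT4F", "diversityIndex_DI",
  "avgNLSSITELocation_NLSL", "avgTypeIVSITELocation_TYPL"
)

#' Trajectory plots of a run or replicate set
#'
#' Faceted generation-by-generation trajectories of the main observables:
#' fitness and sub-fitness curves, the diversity index and the NLS/T4SS
#' location-bias series (0 = signal in the antidote gene, 1 = in the toxin
#' gene). For replicate sets the mean trajectory is drawn with a +/- 1 sd
#' band.
#'
#' @param object A `cif_ea_run` or `cif_ea_replicates`.
#' @param observables Character vector of log columns to facet.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cif_ea_run <- function(object, observables = default_panels, ...) {
  long <- tidyr::pivot_longer(object$log, dplyr::all_of(observables),
                              names_to = "observable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cif_ea_run
#' @export
autoplot.cif_ea_replicates <- function(object,
                                       observables = default_panels, ...) {
  traj <- trajectory_summary(object)
  traj <- traj[traj$observable %in% observables, ]
  ggplot2::ggplot(traj, ggplot2::aes(.data$generation, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey70", na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}
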