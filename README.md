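# cifevo

`cifevo` simulates the molecular emergence of *Wolbachia*
cytoplasmic-incompatibility factor (*cif*) toxin–antidote (TA) gene pairs by
evolving raw DNA strings in a codon-based (μ + λ) evolutionary algorithm. It
is written for molecular evolutionists and phage/symbiont researchers who
want to ask *under which conditions do the eukaryotic-interaction signals of
a TA module assemble in the toxin gene (cifB — the strict TA architecture)
versus the antidote gene (cifA — the 2×1 architecture)?* — and for EA
practitioners interested in sequence-level fitness functions.

## The model

An individual is a pair of DNA genes (toxin, antidote) plus a heritable
mutation-rate gene. Genes are translated codon-wise and scored by

```
F = S_bind + S_nuc + S_dub + S_NLS + S_T4SS − c · max(0, L − 4500)
```

where each component lies in [0, 1] and a perfect pair scores 5:

* `S_nuc`, `S_dub` — ends-free affine-gap alignment similarity (gap open −1,
  extension −0.1, end gaps free) of the toxin protein to the cin nuclease and
  cid deubiquitylase consensus schemas (23 required residues each, wildcards
  elsewhere), normalised so a full schema occurrence scores exactly 1;
* `S_bind` — best ungapped sliding-window tally of complementary charge
  pairs (K/R against D/E: +1; like charges: −1), floored at 0 and capped at
  11, the number of charged residues underlying cifA–cifB binding;
* `S_NLS`, `S_T4SS` — presence of the KRAR nuclear-localisation motif and
  the R-X(7)-R-X-R-X-R type-IV-secretion signal (partial occurrences earn
  proportional alignment credit), credited as the maximum over the two
  proteins so either gene may host either signal;
* the last term is parsimony pressure on total genome length `L` (bp) above
  the 4,500-bp *cif* size estimate.

Populations evolve by K-tournament parent selection (K = 5), gene-wise
4-point crossover, a self-adaptive dice-roll mutation operator
(substitutions and geometric indels), and truncation survivor selection at
constant carrying capacity μ. Three instantiation regimes — random DNA,
consensus-seeded toxins, and mutagenised single founders — differ in
starting diversity, and per-generation logs track fifteen observables
including the NLS/T4SS location bias (0 = signal in cifA, 1 = in cifB) and
a pairwise-identity diversity index. See the methods vignette
(`vignettes/cif-evolution-model.Rmd`) for the full model, parameter
defaults and design rationale.

## Worked example

A founder-seeded desk-scale run: one consensus-built TA pair is copied into
a population of 200, diversified by burn-in mutagenesis, and evolved for
150 generations.

```r
library(cifevo)

cfg <- ea_config(mu = 200, lambda = 20, generations = 150,
                 instantiation = "founder", seed = 2026)
run <- ea_run(cfg)
run
#> <cif_ea_run> seed 2026: 150 generations, mu = 200, lambda = 20
#>   terminal best fitness 5.000, mean fitness 5.000, diversity 0.441
#>   signal location bias (0 = antidote/cifA, 1 = toxin/cifB): NLS 1, T4SS 0.145
```

By generation 150 the whole population has reached the maximum fitness of 5.
Every NLS carrier holds the signal in the toxin gene (bias 1, the strict-TA
architecture), while in this particular run the T4SS signal fixed mostly
antidote-side (bias 0.145) — individual runs fix one way or the other, and
the bias *averaged over replicates* is the headline statistic. The
per-generation log is a tibble (`tidy(run)`), `glance(run)` gives the
one-row terminal summary, and `autoplot(run)` draws the trajectory panels:

```r
generics::glance(run)
#> # A tibble: 1 × 7
#>   generations best_fitness mean_fitness diversity nls_location t4ss_location
#>         <int>        <dbl>        <dbl>     <dbl>        <dbl>         <dbl>
#> 1         150            5            5     0.441            1         0.145
```

The perfect-TA fixture demonstrates the fitness contract directly:

```r
make_perfect_ta(1)[, c("binding", "nuclease", "dub", "nls", "t4ss", "fitness")]
#> # A tibble: 1 × 6
#>   binding nuclease   dub   nls  t4ss fitness
#>     <dbl>    <dbl> <dbl> <dbl> <dbl>   <dbl>
#> 1       1        1     1     1     1       5
```

Replicate sets come from `ea_replicates(cfg, n = 30)`, with
`replicate_summary()` / `trajectory_summary()` for terminal and band
statistics and `autoplot()` for mean ± sd trajectory plots. A thin
command-line driver is installed at
`system.file("cli", "cifevo.R", package = "cifevo")` with `run`,
`replicates`, `preset` and `fixtures` subcommands.

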