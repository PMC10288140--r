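---
title: "Simulating the emergence of cif toxin-antidote modules: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the emergence of cif toxin-antidote modules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifevo)
```

## The biological question

*Wolbachia* manipulate insect reproduction through cytoplasmic
incompatibility (CI), a conditional-sterility system that behaves like a
toxin–antidote (TA) module: the *cifB* toxin sterilises embryos unless the
*cifA* antidote rescues them. Characterised *cif* pairs fall into two
functional architectures — the strict TA model (cifB alone induces, cifA
alone rescues) and the 2×1 model (both genes are needed to induce; one
rescues). `cifevo` asks, by direct simulation of evolving DNA strings, under
which conditions one architecture or the other emerges: it evolves
populations of paired toxin/antidote genes under a sequence-similarity
fitness function and tracks, generation by generation, *where* the two
eukaryotic-interaction signals — a nuclear-localisation signal (NLS) and a
type-IV-secretion (T4SS) export signal — come to reside: in the antidote
gene (cifA, the 2×1 direction) or in the toxin gene (cifB, the strict-TA
direction).

## The fitness model

An individual is a pair of DNA genes plus a small integer mutation-rate
gene. Genes are translated codon-wise under the standard genetic code;
translation starts at position 1, drops trailing partial codons, and renders
in-frame stop codons as a dedicated `*` symbol that matches nothing in any
schema or motif, continuing translation through them. The alternative
(`stop_handling = "truncate"`) is available, but the default keeps scoring
informative on arbitrary random DNA, where stops are frequent and premature
truncation would collapse most early proteins to empty strings.

Fitness of a pair is the sum of five components, each in [0, 1]:

* **nuclease** and **DUB** — similarity of the toxin protein to the cin
  nuclease and cid deubiquitylase consensus schemas (67 positions each, 23
  required residues, the rest wildcards);
* **binding** — charge complementarity of the pair: the antidote is slid
  along the toxin without gaps; each aligned (K/R, D/E) pair scores +1, each
  same-charge pair −1; the best offset's tally is floored at 0, capped at 11
  (the number of charged residues known to underlie cifA–cifB binding) and
  divided by 11. Histidine can optionally join the positive set
  (`h_positive`); the default excludes it, since only K·D pairing is attested;
* **NLS** — presence of the motif KRAR; **T4SS** — presence of
  R-X(7)-R-X-R-X-R. A full occurrence scores 1; otherwise the motif is scored
  by the same partial-alignment rule as the schemas. The pair's NLS and T4SS
  credit is the *maximum* over its two proteins, so selection is free to
  assemble either signal in either gene — the point of the location-bias
  experiments.

A parsimony penalty of `coefficient × max(0, genome_bp − 4500)` is
subtracted; 4,500 bp is an estimate of average *cif* TA size, and the default
coefficient of 5×10⁻⁴ per excess base pair makes a 1,000-bp overshoot cost
0.5 fitness — strong pressure, but never instantly lethal. A perfect pair
scores exactly 5.

### Alignment scoring

All schema and motif similarity uses ends-free ("overlap") pairwise
alignment with affine gaps: gap open −1, gap extension −0.1 (a length-L gap
costs −1 − 0.1(L−1)), end gaps free in both sequences. Required pattern
positions score +1 on identity and −0.5 on mismatch; wildcards cost 0
against any residue, so they can never help or hurt. The raw score is
normalised by the perfect-match score (the required-position count) and
clamped to [0, 1]: a protein containing the fully realised schema scores
exactly 1 and partial occurrences earn proportional credit. The mismatch
penalty of −0.5 is a deliberate midpoint: cheap enough that a near-miss
outscores an indel detour (−0.5 versus −2 for paired gaps), expensive enough
that unrelated sequence scores near zero after clamping. Under this model a
single terminal substitution in KRAR (e.g. KRAA) scores 2.5/4 = 0.625 — the
value the underlying ends-free gap model genuinely produces, as
cross-checked against an independent full-matrix dynamic programme in the
test suite.

## The evolutionary algorithm

The engine is a (μ + λ) overlapping-generations EA with defaults μ = 5,000,
λ = 100, 1,000 generations. Each generation: K-tournament parent selection
(K = 5, λ winners form the mating pool; fitness-proportional and elitist
variants available); pair formation within the pool (`mating_choice`
"mating_pool" by default, with "sorted", "random" and "mixed" variants);
gene-wise n-point crossover (default 4 points; 1/2/3/4/6/"mixed" supported)
— toxin recombines with toxin and antidote with antidote, preserving the
two-gene structure; mutation; evaluation; merging; truncation survivor
selection (sort by fitness, cull the worst λ, carrying capacity constant at
μ; a K-tournament survivor variant exists). Truncation ties break
oldest-first, then by identifier, so runs are bit-reproducible. An optional
re-instantiation step immigrates fresh de-novo individuals (10 per
generation, 1% of μ, or off — the default) to maintain diversity. A
termination-condition threshold (`max_fitness_stop`) exists as a
configuration stub and is disabled in all standard experiments.

Crossover cut points are drawn within the shorter parent; the tail beyond
the shorter length stays with its original child. If parents are too short
for the requested point count, the operator degrades to the largest feasible
count and warns.

### Mutation

Each child carries `rolls` mutation dice rolls, applied one at a time: each
roll picks uniformly among do-nothing, substitution (a uniform random base,
possibly identical, at a uniform position — so a quarter of substitutions
are silent by construction), insertion and deletion. Indel lengths follow a
geometric distribution with mean 3 bp, capped at 30 bp; insertion and
deletion share the distribution, so expected length drift per roll is zero.
Each roll targets the toxin or the antidote with probability proportional to
current gene length, i.e. a uniform position over the whole genome. The roll
count itself is heritable: a child inherits it from one parent at random and
steps it by ±1 with probability 0.1 (clamped to [0, 50]; initial value 5),
implementing a self-adaptive mutation rate without contaminating the scored
DNA.

### Instantiation regimes

Three regimes set the starting population, in decreasing order of starting
diversity — a property asserted in the test suite:

1. **random** — every gene i.i.d. uniform DNA (defaults: toxin 3,000 bp,
   antidote 1,400 bp, toxins longer than antidotes as in real *cif* pairs);
2. **consensus** — each toxin is built around the two filled consensus
   schemas (wildcards filled with random residues) embedded at a random
   position among random flanks, with per-individual total length jittered
   by ±10% around the configured length; each antidote is random sequence
   seeded with a 6-residue acidic (D/E) tract as a partial binding
   complement (deliberately below the 11-pair cap, so binding still has room
   to evolve);
3. **founder** — a single founder pair (from FASTA, or built by the
   consensus recipe) is copied μ times, each copy mutagenised with a burn-in
   of 25 dice rolls.

## Tracked observables

After instantiation and after every generation the engine logs fifteen
observables: highest and mean TA fitness; mean binding, DUB, nuclease, NLS
and T4SS sub-fitness; mean toxin and antidote lengths in bp and residues;
the mean self-adaptive mutation rate; the NLS and T4SS location biases; and
a diversity index. The location bias averages per-carrier codes — 0 for a
signal resident in the antidote, 1 in the toxin, 0.5 for both — over the
individuals that carry the full motif; carrier counts are logged alongside,
and a generation with no carriers logs a missing value, never a silent 0.5.
Non-carriers are excluded rather than averaged in, which keeps the 0–1 scale
interpretable as "fraction of carriers with the signal toxin-side".

The diversity index samples 10 toxins per generation (all 45 pairs),
computes pairwise amino-acid identity (matches / aligned columns on the
optimal ends-free alignment under the fitness gap model) and reports one
minus the mean: clonal populations score 0, unrelated random proteins score
near 1. For speed the alignment is banded: only diagonals within 64
positions of the length-difference corridor are evaluated, which is exact
whenever the optimal path stays in the band (always, for the near-clonal
populations where the index matters most, and for any pair up to 64
residues) and otherwise a lower bound on similarity. `diversity_band = Inf`
forces the full dynamic programme.

## Numerical and design choices

* **Ends-free alignment semantics.** "End gaps free" means the DP is
  anchored with a zero first row/column and read off the last row/column;
  with affine gaps this is the standard overlap alignment. The independent
  oracle in the tests implements it with full matrices and plain loops.
* **Tie-breaking.** Traceback prefers diagonal, then gap-in-pattern, then
  gap-in-protein; the traceback start is scanned last-row-ascending then
  last-column-ascending. Survivor truncation breaks fitness ties by age then
  id. These choices make every logged value bit-reproducible under a seed.
* **Degenerate inputs.** Empty proteins score 0 against every schema;
  binding with an empty partner is 0; two empty toxins count as identical in
  the diversity index; deletion never removes more bases than remain.
* **Determinism.** A run consumes a single R random stream seeded from
  `config$seed`; replicate sets derive per-run seeds from the base seed.
  Identical seeds give byte-identical logs.

## Desk-scale experiment sizes

The shipped experiments run at a deliberate desk scale chosen to keep the
full suite and the reproduction script fast while preserving the phenomena:
engine-invariant checks at μ = 200 / λ = 20 / 200 generations; the
sub-component ordering experiment at μ = 300 / λ = 20 / 300 generations ×
10 consensus-seeded replicates; the founder-bias experiment at μ = 250 /
λ = 20 / 300 generations × 20 replicates. The full-scale configuration
(μ = 5,000, λ = 100, 1,000 generations, 30 replicates) remains the default
of `ea_config()` and is reachable through the presets; `ea_preset(name,
scale = f)` scales μ, λ and generations uniformly and is the supported knob
for desk-scale replication — it is never applied silently.

At these scales the component-complexity ordering reproduces cleanly: the
short NLS/T4SS motifs assemble within a few hundred generations while the
23-residue catalytic schemas climb slowest (the test suite asserts this
ordering across replicates), and founder-seeded runs lose diversity and fix
each signal in one gene or the other early in the run. The *location* of
fixation is a near-Bernoulli per-run outcome at desk scale: the toxin's
length advantage (it usually hosts the better partial motif at
instantiation) competes against an antidote-side frameshift lottery — an
indel in the antidote re-randomises its tail at little fitness cost and
occasionally mints a complete motif, whereas toxin frameshifts are purged
because they destroy the catalytic schemas. Runs also freeze once fitness
saturates, because the self-adaptive mutation-rate gene drifts toward zero
when further mutation is mostly deleterious; terminal biases are therefore
decided early and unchanged by longer horizons. The replicate-mean location
bias is the headline statistic and is recomputed, never assumed, by the
reproduction script.

## What the synthetic data does and does not emulate

All sequences are generated in silico; no real *cif* orthologs ship with the
package. The generator reproduces the *structure* of the problem — two
linked genes of realistic unequal lengths, consensus-constrained toxin
domains, motif acquisition, charge-complementary binding, genome-size
pressure — but not codon-usage bias, frameshift-aware alignment, RNA-level
features, structural energetics of binding, or multiple/redundant motif
copies. Passing tests therefore demonstrate the evolutionary-dynamics
claims (orderings, biases, invariants) on model sequences, not statements
about any particular natural *cif* allele. Formal significance testing of
replicate contrasts is left to standard tools on the exported tables.

## Known limitations

* The binding tally assumes a single ungapped offset; discontiguous binding
  interfaces score only through their best single register. Because the
  tally does not require the scoring pairs to be contiguous, genes with
  random charged backgrounds of realistic length already reach a
  near-maximal tally at instantiation, so binding exerts most of its
  selective pressure through maintenance rather than assembly.
* Location bias is undefined (logged missing) until the first full motif
  appears, so early-generation bias trajectories start sparse.
* The banded diversity index can underestimate similarity for long, highly
  diverged pairs (it is exact in the regimes that matter for the reported
  results; see above).
* With `stop_handling = "symbol"`, proteins may contain internal stop
  symbols; downstream consumers of exported FASTA should translate
  accordingly.
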