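---
title: "Quantifying bursty introduction of phenotypic variation on GP maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bursty introduction of phenotypic variation on GP maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

When a population explores a neutral component (NC) of a genotype-phenotype
(GP) map by drift, how regularly does it produce a *particular* novel
phenotype $p_i$ as variation?  The textbook answer - a Poisson process at
the mean rate $r_i = N u L \,\phi_{p_i p_0}$ - ignores that only some
genotypes of the NC (the *portal genotypes*) have any mutation to $p_i$ at
all.  A monomorphic population therefore alternates between long quiet
stretches (no portal in the population) and bursts of repeated $p_i$
introductions (while it sits on a portal).  This package simulates that
process on explicit GP maps, provides the matched Poisson null, and
implements the closed-form scaling theory that links the burstiness to
population parameters and to the dynamics of adaptation.

## Model and scaling quantities

Populations are haploid Wright-Fisher: $N$ individuals, discrete
generations, fitness-weighted multinomial resampling, and per-site
mutation probability $u$ on genotypes of length $L$ over an alphabet of
size $K$.  In the weak-mutation (monomorphic) regime $N u L < 1$ the
population occupies essentially one genotype between neutral fixations,
and four time scales organise everything (`scaling_times()`):

* $t_{ne} = 1/(L u \rho)$ - mean generations between neutral fixations,
  with $\rho$ the NC robustness (fraction of phenotype-preserving
  mutations);
* $t_{gene} = (K-1)/(N u)$ - generations until each *specific* point
  mutation of the resident genotype has been produced once;
* $M = t_{ne}/t_{gene} = N / ((K-1) L \rho) \approx N/L$ - the burst
  size: how often the same mutational neighbour is produced during one
  residence;
* $t_{port} = t_{ne} / P_{g_{p_i}}$ - waiting time to drift onto a portal
  genotype.

Two consequences for adaptation are implemented in closed form: the
probability that a burst of $M$ mutants with single-mutant (Kimura)
fixation probability $P_{fix}$ ends in fixation,
$(1 + 1/(P_{fix} M))^{-1}$ (`p_portal_fix()`), which saturates above the
remarkably low selection threshold $s^* = 1/M$ (`selection_threshold()`);
and the origin-fixation fixation time $t_{fix} = (r_i P_{fix})^{-1}$
(`t_fix_average_rate()`) together with its multi-peak first-fixation
generalisation $(1 + t_1 \sum_{i \ge 2} 1/t_i)^{-1}$
(`first_fixation_probability()`).

## The GP maps

Four concrete maps expose one contract (`map_phenotype()`,
`point_mutation_neighbors()`):

* **RNA** (`rna_gp_map()`): sequences of length 12 fold to their
  minimum-free-energy dot-bracket structure with ViennaRNA (`RNAsubopt`
  at default parameters, invoked in batches).  A sequence whose minimum is
  attained by two or more structures is assigned the undefined phenotype
  `NONE`.  The folding engine available at build time (2.7.x) reproduces
  the published reference component of `AUACGAAACGUA` - 1,094 genotypes -
  exactly, even though that number was originally obtained with 2.4.14.
* **HP lattice** (`hp_gp_map()`): binary hydrophobic/polar chains fold
  onto all compact self-avoiding walks of a square lattice; energy is -1
  per non-bonded H-H contact.  The tie rule mirrors the RNA convention:
  a degenerate minimum gives `NONE`.  Walks are canonicalised under the 8
  lattice symmetries, and chain reversal is folded into the phenotype
  identifier, so symmetric refolds of one conformation never create
  spurious degeneracy.  (The source this model follows does not state
  either convention; both choices are therefore documented here as the
  package's own.)
* **Biomorphs** (`biomorph_gp_map()`): nine bounded integers drive a
  recursive branching drawing rasterised onto a 30x30 binary grid
  (the digest string is the phenotype).  The displacement convention is
  fixed in `biomorph_direction_table()`: directions $d = 0..7$ use
  $dx = (0, g_1, g_2, g_3, 0, -g_3, -g_2, -g_1)$ and
  $dy = (g_4, g_5, g_6, g_7, g_8, g_7, g_6, g_5)$, with growth starting
  in direction 4 and gene 9 setting the recursion depth.  Because $dx$ is
  antisymmetric and $dy$ symmetric under the direction mirror, every
  rendered biomorph is bilaterally symmetric - a property the test suite
  checks by construction rather than against the historical program,
  whose exact displacement table is not published; any fixed convention
  yields an equivalent developmental GP map.
* **Random maps** (`make_random_gp_map()`): every genotype draws an
  independent phenotype from a fixed spectrum.  The draw is a splitmix64
  hash of (genotype, seed), so the map is pure, reproducible, and lazily
  evaluable over the whole $K^L$ space; the simulation engine evaluates
  the identical hash, which is what makes desk-scale runs on a
  $4^{12}$-genotype map possible without materialising it.  Independent
  per-genotype draws (rather than an exact global composition) are the
  deliberate choice here: they are what makes lazy evaluation sound.

## Null-model hierarchy

From a reference NC, `make_topology_gp_map()` keeps the neutral graph
bit-for-bit and redraws every outside genotype from the non-neutral
spectrum (renormalised, never the initial phenotype), erasing non-neutral
correlations; `make_community_gp_map()` instead permutes non-neutral
labels only within one NC community at a time, stratified by the exact
number of mutational connections to the NC, which preserves the mutation
spectrum $\phi$ exactly while partially erasing correlations.  Community
detection (`detect_communities()`) is greedy agglomerative modularity
maximisation with a seeded tie-breaking shuffle; since the method the
reference analysis used is not specified beyond a citation, the partition
is an explicit argument and any user-supplied partition can be
substituted.  Degenerate graphs whose best modularity is no better than
zero collapse to a single community.

## Simulators

`wright_fisher_run()` simulates on a map; `average_rate_run()` is the
matched null without genotype state, in which each mutation redraws the
offspring's phenotype from the mean spectrum (robustness $\rho$ on the
diagonal).  Both use one compiled core.  Design choices that the
underlying protocol leaves open, fixed here:

* Offspring are drawn multinomially with probabilities proportional to
  parent count x parent fitness (standard Wright-Fisher selection).
* Each offspring site mutates independently with probability $u$; in the
  average-rate model the per-offspring mutation count is Binomial(L, u),
  matching $L u$ mutations per individual and generation in expectation.
  One appearance is logged per mutant *offspring individual* (an
  offspring carrying two mutations counts once); for interval statistics
  same-generation events are collapsed to one event time.
* A burn-in of $10 N$ generations of neutral drift on the initial NC
  precedes logging, randomising the forced initial condition.  The
  burn-in always uses the stabilizing-selection scheme (all non-initial
  phenotypes unviable) so that an adaptive phenotype cannot fix before
  logging starts; the configured fitness applies from logged generation
  0.  The average-rate model is stationary from the start and uses no
  burn-in.
* Fixation is declared when strictly less than 25% of the population
  carries the initial phenotype; the winner is the most abundant other
  phenotype, ties broken by identifier order.
* Unviable mutants (fitness 0) are logged as appearances and removed by
  the next resampling.
* With `restrict_to_nc = TRUE` (the default for structured maps,
  matching the simulation protocol) genotypes of the initial phenotype
  outside the initial NC get fitness 0, excluding irreproducible jumps to
  other NCs.  Random maps run unrestricted.
* On large maps the engine runs on a materialised local view: the NC,
  its 1-mutation boundary, and the boundary of viable boundary genotypes.
  A mutation from a genotype whose neighbourhood is outside the view
  falls back to a phenotype-level draw: the initial phenotype's row is
  $\phi$; any other phenotype keeps itself with probability $\rho$ and
  otherwise becomes `NONE`.  This coarse fallback is exact for the
  strong-stabilizing-selection designs (such genotypes are dead and never
  reproduce) and affects single-sweep designs only through the rare
  mutants of an already-sweeping genotype (rate $uL$ per sweeping
  individual, and only for the third mutational shell onward).
* Genotype-level substitutions (for neutral-clock diagnostics) are
  recorded when the population becomes *fully* monomorphic on a new
  genotype; a softer threshold would double-count drift flip-flops.

## Burst statistics

`interval_counts()` bins appearances into windows of $\Delta t$
generations (default 3,000).  `coefficient_of_variation()` computes
$V_t = \sigma/\mu$ of inter-appearance gaps (population standard
deviation; at least 3 distinct event times required); a Poisson process
gives $V_t = 1$.  `burst_summary()` classifies window counts against the
$\mu \pm \sigma$ band of the matched Poisson; counts equal to a boundary
are "within" (the convention is not stated in the reference analysis and
is fixed here).  `poisson_mixture_prediction()` implements the
weighted-sum-of-Poissons approximation with peaks at
$n \Delta t/t_{gene}$, weighted by the per-genotype neighbour-count
distribution; it deliberately omits the portal-escape and polymorphism
corrections of the fuller analytic treatment and is labelled approximate
in its output.

## Experiment designs and problem sizes

`run_burst_histogram()`, `run_cv_scan()`, `run_fixation_time_scan()` and
`run_two_peak()` reproduce the four standard designs.  Full-scale
defaults are the published conditions ($N = 1000$, $u = 2\times10^{-5}$,
$10^7$ generations, $\Delta t = 3000$; scan run length
$T = \max(10^6/(N u L), 10^4)$ rounded up to a power of ten; $10^3$
repetitions per selection coefficient; two-peak design at $N = 500$).
The test suite and the acceptance script run the same code at reduced
problem sizes chosen so each check retains statistical power: $2\times10^6$
generations for the random-map burst surrogate (about 85 neutral
fixations, enough residences to resolve overdispersion), 600 repetitions
for the fixation-time comparison (standard error ~4%, against a 10%
band), scan budget $10^5$ in place of $10^6$, and $\ge 10^4$
inter-appearance gaps for the Poisson baseline.  These sizes are the
package's CI presets; the full-scale parameters remain the defaults.

`make_fixture_map()` generates small exhaustively enumerable random maps
(optionally with clustered portals, produced by frequency-preserving
label swaps around growth seeds) so that every simulator feature can be
tested against brute-force oracles without any folding engine.

## What the synthetic maps do and do not emulate

Fixture and random maps reproduce the *statistical* skeleton of a real
GP map: phenotype frequencies, finite discrete neighbourhoods, portal
scarcity, and (optionally) portal clustering.  They do not reproduce
neutral correlations (the topology of real NCs), the energy-driven
structure of real non-neutral correlations, or phenotype-frequency
distributions beyond the specified spectrum.  Tests passing on fixtures
therefore validate the machinery and the scaling laws, not any claim
about a particular biological map; the RNA component statistics are the
anchor to a real map.

## Numerical and degenerate-input conventions

Exact rational counts are used for $\phi$, $\rho$ and portal fractions
(no floating accumulation); the Kimura formula uses `expm1` and returns
$1/N$ below $|s| < 10^{-12}$; a singleton NC has $\rho = 0$; an empty
event log yields empty interval counts; fewer than 3 distinct event
times is an error for $V_t$, not a silent `NA`; all simulators derive
every random draw from R's RNG, so a single `set.seed`-style `seed`
argument makes runs byte-reproducible.

## Known limitations

Only single-nucleotide substitutions are modelled (no indels,
recombination, or diploidy); dynamics are discrete-generation
Wright-Fisher, not continuous-time; the mean-spectrum fallback for
off-view mutations is a coarse approximation (see above); the full
analytic corrections for mildly polymorphic populations (the refined
count-distribution and random-map fixation-time curves) are not
implemented - comparisons against the random map's fixation times are
therefore qualitative; and exhaustive folding of the whole RNA or 5x5 HP
space is supported only as an explicit long-running choice, never a
default.
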