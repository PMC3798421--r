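---
title: "Models and methods behind IMflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind IMflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IMflow)
```

IMflow analyses multilocus nuclear sequence data from pairs of closely
related populations to separate the contributions of shared ancestry and
ongoing gene flow to their divergence.  Its motivating design is a
four-population contrast in the *Lutzomyia longipalpis* species complex:
two sibling populations that co-occur at one locality (a sympatric pair,
where hybridization is possible) and two allopatric populations of the
same two lineages (where current gene flow is impossible).  If the two
species were fully isolated everywhere, sympatric and allopatric pairs
should be about equally differentiated; systematically lower and more
heterogeneous differentiation in sympatry is the signature of
differential introgression.  This vignette documents the models, the
estimators, the numerical choices, and the limits of what the shipped
tests demonstrate.

## The site universe: complete deletion

Every statistic operates on a per-locus `LocusAlignment` whose
`keptSites` vector records the columns that survived filtering.
`filterSites()` implements complete deletion: any column containing a
gap or an ambiguous residue in any sequence is removed once, and all
downstream statistics (within- and between-population) share the
resulting site universe.  We chose complete deletion over
pairwise deletion because it gives a single consistent denominator per
locus and matches the preprocessing required by the non-recombining
block step; the cost is a slightly shorter locus when indel
polymorphism is common.  Coordinates are 1-based alignment columns
throughout.

## Per-locus statistics

For a locus with `n` sequences and `L` kept sites the package computes:

* **pi** — the mean pairwise difference over all `choose(n, 2)` pairs,
  divided by `L` (per site).  The unnormalised count-scale value
  `pi_total` is used inside the test statistics below.
* **Watterson's theta** — `S / (a1 * L)` with
  `a1 = sum(1/i), i < n`.
* **Tajima's D** — the classical standardised difference between
  `pi_total` and `S/a1`, with the finite-sample constants computed from
  `n`.  `D` is reported as `NA` when `S = 0` (a locus without variation
  carries no information; printing 0 would be misleading).
* **Fu's Fs** — with `theta` estimated by `pi_total`, the probability
  `S' = P(K >= k_obs)` that a neutral sample shows at least the observed
  number of distinct haplotypes, mapped to `Fs = ln(S'/(1-S'))`.  The
  Ewens distribution of `K` is evaluated by convolving the independent
  Bernoulli indicators `K = sum_i Bern(theta/(theta+i-1))`, which is
  numerically stable for any `n`; a direct unsigned-Stirling-number
  summation is kept in the test suite as an independent oracle (IEEE
  doubles hold `|s(n,k)|` exactly enough for `n <= 64`, so extended
  precision is unnecessary).  When `S'` reaches 0 or 1 the log-odds is
  clamped at ±1000 and flagged.
* **R2** — the Ramos-Onsins–Rozas singleton statistic
  `sqrt(mean((U_i - pi_total/2)^2)) / S`, where `U_i` counts the
  singleton variants carried by sequence `i` (folded: a variant present
  in exactly one sequence).
* **Differentiation** — Hudson's `FST = 1 - Hw/Hb` with `Hw` the mean of
  the two within-population mean pairwise differences and `Hb` the
  between-population mean (`Dxy`, per site when divided by `L`).
  Negative estimates are reported as computed; truncating them at zero
  would bias the downstream normalized-difference statistic.  `FST` is
  undefined (`NA`) when `Hb = 0`.
* **Site classification** — each kept column falls in exactly one of:
  fixed difference (`Sf`), shared polymorphism (`Ss`, the same two or
  more residues segregating in both populations), or an exclusive
  polymorphism (`Sx1`/`Sx2`).  We adopted the stricter
  same-residues-segregating definition of a shared site; with biallelic
  data the two definitions coincide.

Significance of per-locus `FST` uses a label permutation test
(sequences shuffled between the two populations, sample sizes
preserved) with the add-one estimator `p = (1 + #{FST* >= FST}) /
(B + 1)`, so `p` is never exactly zero.  Significance of the neutrality
statistics (`neutralityTest()`) comes from the standard neutral
coalescent conditional on `n` and `S`: genealogies are simulated, `S`
mutations are placed uniformly on branches, and two-tailed (D, Fs) or
lower-tail (R2) empirical p-values are returned.

## The multilocus HKA test

Under neutrality, polymorphism within each population and divergence
between them should be proportional across loci.  The package fits, per
locus *i*:

* `E[S1_i] = theta_i * a(n1_i)`
* `E[S2_i] = f * theta_i * a(n2_i)`
* `E[D_i]  = theta_i * (T + (1+f)/2)`

where `f` is the relative size of population 2 and `T` the scaled
divergence time, with the classical variances
`Var[S] = E[S] + (scale * theta_i)^2 * b(n)` and
`Var[D] = E[D] + (theta_i (1+f)/2)^2`.  The moment system is solved
with `theta_i` given in closed form conditional on `(T, f)` and a
Nelder-Mead/BFGS search over `(T, f)` from a grid of starts
(tolerance 1e-10 on the squared pooled residuals).  The goodness-of-fit
statistic sums `(obs - exp)^2 / var` over all `3L` cells and is referred
to a chi-square distribution with `df = 2L - 2` (40 for a 21-locus
panel).  The divergence cell is the mean between-population pairwise
difference on the count scale, which includes within-species
polymorphism — consistent with the `2L - 2` degrees of freedom of the
two-population design.  We verify internal consistency (chi-square of
zero at exact expectations; agreement with an independent joint
optimiser) rather than bit-equality with any particular legacy
implementation, whose exact variance conventions are not published.

## The comparison layer

`comparePanel()` condenses the sympatric-versus-allopatric contrast:

* the mean/SD of the two per-locus FST vectors with a pooled-variance
  two-sample t (sign convention `t = (mean_symp - mean_allo)/SE`);
* the count of loci where the sympatric pair is the more differentiated;
* the normalized difference `d_i = (allo_i - symp_i)/allo_i`, ranked and
  correlated (Spearman, i.e. Pearson on average ranks) against the rank
  of a chosen FST vector.  Under differential introgression `d_i` is
  strongly negatively correlated with sympatric FST: loci that resist
  introgression are already near their allopatric differentiation.  The
  ranking direction is exposed as a parameter; the allopatric direction
  is weakly and unstably correlated, and no published value is asserted
  for it.

`njFstTree()` builds the four-population neighbor-joining tree from the
entrywise mean of per-locus FST matrices (negative means floored at
zero, flagged), and `locusBootstrapSupport()` resamples loci — not
sequences — with replacement to attach split support percentages.

## Non-recombining blocks

Coalescent-based IM inference assumes no intra-locus recombination.
`extractNrb()` searches for the contiguous kept-site window and sequence
subset that maximise `nSeq^w * nSites` (default `w = 1`) subject to the
four-gamete criterion evaluated over biallelic site pairs (sites with
more than two residues are excluded from pair testing but retained in
the emitted block).  Samples of at most eight sequences over at most 30
kept sites are solved by exhaustive enumeration; larger inputs use a
deterministic greedy that alternates between dropping the sequence
implicated in the most remaining violations (ties resolved by dropping
the lexicographically last identifier) and shrinking the window past the
boundary-most violating site, keeping whichever branch scores better.
The greedy's result is guaranteed four-gamete compatible but only
maximal over the explored space; the exhaustive branch is the reference
in tests.  `applyBlock()` lets a block chosen on one population pair be
imposed on another pair of the same locus for cross-pair consistency.

## The isolation-with-migration simulator

The two-population IM model has six scaled parameters: `theta1`,
`theta2`, `thetaA` (4 N mu per locus for the two daughters and the
ancestor), the split time `t`, and migration rates `m1`, `m2`.  Time is
measured in mutational units (1/mu generations), giving the structured
coalescent these rates:

* pair coalescence within population *j*: `2 / theta_j`;
* per-lineage backward migration out of population *j*: `m_j`;
* mutation along every lineage: 1 per unit branch length.

This convention satisfies the classical identities `E[pi] = theta`
(n = 2), `E[S] = theta * a_n`, and `2Nm_j = theta_j * m_j / 2` — the
latter being the scale on which the package converts and reports the
effective number of migrant gene copies per generation.  At time `t`
all lineages merge into the ancestral population.  Mutations follow the
infinite-sites model and are mapped to distinct uniformly chosen
alignment columns; a draw with more mutations than columns is retried
with a fresh random substream and errors after a bounded number of
attempts.  The event loop is implemented in C++ (tracking only
descendant-copy counts per lineage, never tip identities) with an R
twin used as a cross-implementation consistency check; both use R's RNG
so `set.seed()` governs reproducibility end to end.

Demographic conversions use per-locus mutation rates
`mu_i = L_i (f_syn * 1.56e-8 + (1 - f_syn) * 1.91e-9)` per year
(Drosophila nuclear synonymous/non-synonymous rates), their geometric
mean `mu_gm` (default 1.77e-6 per locus per year — the exact
synonymous-site partition behind that published value is not
recoverable, so `mu_gm` is configurable), ten generations per year, and

* `N_j = theta_j * g / (4 mu_gm)`
* `t_years = t / mu_gm`
* `2Nm_j = theta_j * m_j / 2`.

## Rejection ABC

Full-likelihood MCMC over genealogies is the classical estimator for
this model; IMflow deliberately substitutes desk-scale rejection ABC
over the identical six-parameter model, trading posterior sharpness for
testability: parameters are drawn from uniform box priors, the full
multilocus design is simulated per draw, and the `acceptFrac` draws
closest to the observed summary vector (normalized Euclidean distance)
are kept.  The summary vector is the across-locus mean and variance of
pi1, pi2, FST, Ss, Sf, Sx1, Sx2 and Dxy.

Three practical points matter:

* **Prior scale.**  The default box (`imPriors()`: theta to 10, t to 5,
  m to 25) mirrors conventional IM run settings.  A 2000-draw rejection
  sampler, however, places almost no mass at migration rates below ~1
  under `m <= 25` (P(m < 0.2) = 0.8%), so analyses targeting weak
  migration should use a box a few-fold above the plausible scale
  (e.g. `mMax = 5` when published point estimates are near 1), or more
  draws.  This is a sampler-resolution argument, not a prior belief.
* **Summary noise.**  With few loci the across-locus variance components
  are dominated by sampling noise; `statSubset = "means"` restricts the
  distance to the mean components and is the right choice for focused
  reanalyses such as a migration-only refinement
  (`migrationRefinePriors()` pins the demography at point estimates and
  re-runs the same rejection machinery over `(m1, m2)`).
* **Directional power.**  The direction of migration asymmetry is only
  weakly identified by these summaries at small locus counts: the
  response of `(Sx1, Sx2, pi1, pi2)` to `(m1, m2)` is non-monotone
  (moderate immigration raises the receiving population's exclusive
  polymorphism, strong immigration erases differentiation entirely), so
  with about five loci the posterior orders the two rates correctly in
  only roughly two out of three datasets.  Magnitude recovery for
  `theta1`, `theta2` and `t` (posterior intervals bracketing the
  generating values) is robust at the same scale.  Single-locus
  migration profiles (`perLocusMigrationProfile()`) inherit the same
  limitation; aggregated over replicate loci the ordering is reliable,
  per-locus it is noisy, and loci without information are flagged as
  flat rather than estimated.

## The synthetic-study generator

`generateStudy()` produces complete four-population datasets with known
truth: per locus, one IM simulation for the sympatric pair and an
independent one for the allopatric pair (the joint four-population
history is deliberately not modelled; cross-pair comparisons in
generated data are therefore structurally arbitrary).  Defaults are the
published study's shape: the 21 locus lengths (89–664 bp) and
per-population sample sizes (10–42), pair histories set to the
published scaled estimates, per-locus `theta` proportional to locus
length (`theta_i = theta * L_i / geomMean(L)`), and sympatric per-locus
migration multipliers drawn once per configuration — about one third of
loci set to zero ("barrier" loci) and the rest lognormal with unit
median — to emulate differential introgression.  Generated data are
ordinary FASTA plus a two-column popmap, byte-reproducible from the
seed, with the generating parameters in a JSON sidecar.

What the generator does *not* emulate: indels and alignment ambiguity,
codon structure and selection, intra-locus recombination, and
cross-pair genealogical correlation.  Tests passing on synthetic data
therefore demonstrate the pipeline's statistical machinery, not
robustness to alignment artefacts.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run at reduced scale chosen to
exercise every code path with stable statistics: oracle comparisons at
`n <= 8`, simulator calibration with 4,000–10,000 replicates,
synthetic studies of 3–8 loci, ABC passes of 1,000–2,000 draws over
five loci, and exhaustive NRB checks at `n <= 6`, `L <= 10`.  The
published panel statistics (mean FST contrast, rank correlation,
exceedance and fixed-site counts, 2Nm conversions) are recomputed
exactly from the shipped reference tables.

## Known limitations

* The ABC stand-in yields credible posterior location for `theta` and
  `t` but underpowered migration-direction inference at small locus
  counts (above); the published full-likelihood posteriors are not
  reproducible at desk scale and are not targeted.
* The HKA variance terms follow the standard formulation; legacy
  software may differ in unpublished details.
* `FST` permutation p-values are bounded below by `1/(B+1)`.
* The NRB greedy is heuristic beyond the exhaustive regime; its
  invariant is four-gamete compatibility, not global optimality.
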