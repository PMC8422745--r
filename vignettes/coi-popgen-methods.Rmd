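---
title: "Methods behind coipopgen: single-locus mtDNA population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind coipopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coipopgen)
```

`coipopgen` implements the complete analysis chain that intraspecific
mtDNA surveys apply to a single aligned locus (typically a COI fragment):
haplotype collapsing, molecular diversity indices, neutrality tests,
mismatch-distribution demographic inference, AMOVA/SAMOVA
Phi-statistics, substitution-model distances with dendrograms, and a
statistical-parsimony haplotype network. This vignette documents the
models, the defaults and why they are what they are, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Data model and missing-data conventions

The input is an equal-length nucleotide alignment (alphabet
`A,C,G,T,N,-`) plus a sample-to-population map. Two missing-data
conventions coexist deliberately, mirroring the tools whose outputs this
package reproduces:

* **Complete deletion** for haplotype collapsing, segregating sites,
  `K` and `pi`: any column containing `-` or `N` in any sequence is
  dropped before computation, and the number of excluded columns is
  always reported. This is the convention of the classic polymorphism
  software whose tables these statistics mirror.
* **Pairwise deletion** for Kimura 2-parameter distances: each sequence
  pair uses every column where both members are unambiguous, matching
  the distance/tree tool chain.

Haplotype identifiers are assigned `Hap_1, Hap_2, ...` in descending
order of total frequency (ties by first occurrence), so the modal —
typically central and plausibly ancestral — haplotype is always
`Hap_1`.

## Diversity indices

Haplotype (gene) diversity uses the unbiased estimator
$H_d = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ with the Nei (1987,
eq. 8.12) large-sample sampling variance. Nucleotide diversity is the
raw per-site p-distance averaged over all pairs,
$\pi = K / L_{\text{incl}}$, where $K$ is the mean pairwise difference
count; its standard deviation is the Nei (1987, eq. 10.7) total
(no-recombination) variance. No substitution-model correction is applied
to $\pi$ — corrected distances belong to the distance/tree stage. The
"Mean" summary row printed by many surveys is treated here as
pooled-sample diversity (all sequences analyzed together) rather than an
arithmetic mean of rows, which is what the published values are
consistent with.

## Neutrality tests

**Tajima's D** is computed from $(n, S, K)$ with the 1989 constants. At
$S=0$ the statistic is undefined and reported as `NA` with a warning
rather than 0.

**Fu's Fs** uses the Ewens sampling distribution of the allele count:
$\Pr(K=k) = |s(n,k)|\,\theta^k / \theta^{(n)}$ with unsigned Stirling
numbers of the first kind. The driving $\theta$ is the pairwise estimate
($\theta_\pi = K$), as in the standard implementation the published
tables come from. Stirling numbers are computed by a log-space
recurrence because $|s(n,k)|$ overflows doubles near $n \approx 50$,
while surveys routinely have deme sizes of 44–48 and pooled sizes in the
hundreds.

**Significance** is simulation-based and lower-tailed for both
statistics: neutral constant-size coalescent samples are generated
conditional on the observed quantity — the fixed-$S$ scheme for $D$
(mutations multinomially placed on branches), and Poisson mutation with
$\theta_\pi$ for $Fs$ — and $p$ is the fraction of simulated statistics
at or below the observed one. Whether to condition on $S$ or on
$\theta$ is not standardized across tools; this package documents the
scheme above and exposes the full null sample. For $Fs$, the customary
reading is that $p < 0.02$ corresponds to significance at the 5% level;
the raw $p$ is always reported.

## Mismatch distributions and sudden expansion

The observed mismatch distribution is the relative frequency of pairwise
difference counts. The sudden-expansion model (a population of scaled
size $\theta_0$ jumping to $\theta_1$ at $\tau$ units of mutational time
ago) has the closed form implemented in `expected_mismatch()`, derived
by conditioning on whether a pair coalesces before or after the
expansion:

$$F(i) = G(i,\theta_1)\,P\!\left[\Gamma\!\left(i+1,
\tfrac{1+\theta_1}{\theta_1}\right) \le \tau\right] +
e^{-\tau/\theta_1} \sum_{j=0}^{i}
\operatorname{Pois}(i-j;\tau)\,G(j,\theta_0),$$

with $G(i,\theta) = \theta^i/(1+\theta)^{i+1}$ the equilibrium
geometric. At $\tau = 0$ (or $\theta_0=\theta_1$) this reduces exactly
to $G$, which the tests assert algebraically.

Fitting minimizes the sum of squared deviations over
$(\tau,\theta_0,\theta_1)$: a coarse grid ($\tau$ over
$[0, 2\cdot\max\text{class}]$, $\theta_0$ up to $\theta_\pi$, $\theta_1$
over a log-spaced set plus the cap) followed by box-constrained
(L-BFGS-B) and Nelder–Mead polish, with $\theta_0 \le \theta_1$
enforced, $\theta_0$ floored at 0, and $\theta_1$ capped at 99,999 — the
ceiling the standard software prints when the post-expansion size is
effectively unbounded, kept here so outputs are comparable.
Goodness of fit uses SSD and Harpending's raggedness index (squared
steps over the zero-padded class range), with parametric-bootstrap
p-values: coalescent samples are simulated under the fitted expansion,
refitted, and compared. Degenerate single-class observations return the
$\tau = 0$ fit with a warning.

Expansion times use $T = \tau/(2\mu)$ with
$\mu = \text{generation time} \times \text{sites} \times \text{rate}$;
defaults are the conventional arthropod COI clock of 1.4% per million
years, a 1.5-year generation time, and 674 sites. The year-vs-generation
units in this conversion are dimensionally loose in common practice; the
implementation follows the convention under which the published times
(e.g. $\tau = 3.000 \to 0.106$ Ma) are reproduced exactly, and reports
both years and Ma.

## AMOVA, pairwise differentiation, and group search

Variance is decomposed from pairwise difference counts used as squared
distances (the haplotype-distance AMOVA convention), giving
Phi-statistics even where surveys label them $F_{ST}$. One-level and
two-level designs follow the Excoffier–Smouse–Quattro (1992)
method-of-moments equations; negative variance components are retained,
which is why slightly negative pairwise values occur. Permutation
schemes: samples among populations for $\Phi_{ST}$; whole populations
among groups for $\Phi_{CT}$; samples among populations within groups
for $\Phi_{SC}$. With every population its own group the two-level
design degenerates consistently ($\Phi_{SC}$ undefined and signaled,
$\Phi_{CT} = \Phi_{ST}$).

The SAMOVA-style search maximizes $\Phi_{CT}$ over assignments of
populations to $K$ groups. With seven populations the partition space is
tiny, so exhaustive enumeration (restricted-growth strings) is used
automatically below $10^5$ candidate partitions; above that, simulated
annealing with single-population moves, geometric cooling and multiple
restarts. Geographic contiguity is *not* enforced: a defensible
contiguity notion for a handful of scattered sites is unclear, and with
exhaustive enumeration the unconstrained optimum is exact; users can
judge its geography from the reported partition.

## Distances and dendrograms

`k2p_distance()` is the closed-form Kimura (1980) two-parameter
distance, $d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$; saturation
(non-positive log arguments) is an explicit per-pair error.
Between-population distance is the plain average K2P distance over
inter-population pairs (the convention of the software behind published
"Ds" tables); the net distance, subtracting mean within-population
distances, is available with `net = TRUE`. UPGMA uses size-weighted
average linkage with heights $d/2$ (hence ultrametric output); NJ is
Saitou–Nei with negative branch lengths zeroed and the deficit moved to
the adjacent branch. A dendrogram "isolates" a population when, after
midpoint rooting if needed, that population is sister to everything
else — the property figures are read for.

## Haplotype network

The network is the minimum-spanning-network variant of statistical
parsimony (all co-minimal connections retained, i.e. epsilon = 0):
haplotype pairs join in ascending mutational distance, cycles are kept
when alternatives tie, and unsampled intermediates appear as median
nodes so every drawn edge is one step. The full original
statistical-parsimony machinery additionally weights connections by
outgroup probabilities; that weighting does not change which haplotypes
can connect and is not needed to reproduce the structure of published
intraspecific networks, so it is deliberately not implemented.

The connection limit is the largest step count $j$ whose parsimony
probability — the probability that $j$ mutations on $L$ sites all strike
distinct sites, so that no superimposed change hides a step — stays at
or above the confidence level, computed by the recursion
$P(1) = 1,\; P(j) = P(j-1)\,(1 - (j-1)/L)$. For $L = 674$ at 95% this
gives 8 steps. This is a deliberately transparent model of the parsimony
criterion; implementations differ in how they estimate multiple-hit
probabilities, so limits from other software can differ by a step or
two. Ambiguous median placements are resolved by ascending site order,
making networks deterministic.

## The synthetic-data generator

`simulate_coalescent()` is a haploid (maternally inherited mtDNA)
structured coalescent: island migration at per-lineage rate $M/2$,
optional sudden expansion (all demes `fold` times smaller beyond the
expansion time), optional single diverged deme that exchanges no
migrants and joins another deme at a split time, and finite-sites
mutation with a configurable transition:transversion ratio (default
10:1, typical of COI) so parallel and back mutations can occur as in
real data. Time is in units of $N_0$ generations with
$\theta = 2N_0u$ per locus, so a constant-size deme has expected
pairwise difference $\theta$ and expected segregating sites
$\theta\sum 1/i$ — both asserted against simulation in the tests. All
randomness flows through R's seeded Mersenne Twister, so outputs are
byte-identical under a fixed seed.

`make_fixture()` writes a seven-deme survey-shaped dataset: deme sizes
46, 44, 47, 47, 48, 48, 46 over 674 sites, $\theta = 0.7$, a recent
100-fold sudden expansion at 1.0 coalescent time units (star-like
genealogies with one dominant haplotype), migration $M = 10$ among six
demes, and one deme (`JNlike`) isolated since 4.5 units. These values
were chosen once to land the downstream summaries in the ranges a
low-diversity freshwater mtDNA survey reports: per-deme haplotype
diversity 0.2–0.85, per-site nucleotide diversity 0.0003–0.003, and
strong differentiation ($\Phi_{ST} > 0.4$) of the isolated deme. Because
one coalescent draw has large genealogical variance, the generator
conditions on those observable ranges: sub-seeded replicates are drawn
until the realized summaries qualify (still fully deterministic in the
seed). What this emulates is the statistical *shape* of such surveys;
what it does not emulate includes selection, sequencing error,
heteroplasmy, codon structure, and rate heterogeneity across sites — so
green tests on fixtures demonstrate correct inference under the stated
model, not robustness to those realities.

## Numerical choices and problem sizes

* Mismatch fit stops refining below an SSD change of about $10^{-10}$
  (optimizer tolerances); the bootstrap refits with the same strategy.
* Ewens/Stirling computations are entirely in log space; tail sums use
  log-sum-exp.
* Tie-breaks everywhere are deterministic (first occurrence for
  haplotype ranks, ascending site order for medians, lexicographic ids
  for central-haplotype ties).
* The test suite and acceptance script scale Monte-Carlo sizes to what
  a laptop runs comfortably: 1000 neutral replicates for the D/Fs
  calibration (with per-$S$ cached null distributions of 400 draws for
  the type-I check), 200 island-model replicates, 50 expansion-recovery
  replicates at $n = 48$, and bootstrap sizes of 100–200 inside unit
  tests; `run_all()` defaults to 1000 replicates and permutations, and
  10,000 permutations remain the recommendation for publication-grade
  p-values.

## Known limitations

* Single locus, haploid: no recombination, no multi-locus clocks.
* The mismatch model is the demographic sudden-expansion form; the
  spatial-expansion variant is not implemented.
* Fu & Li's statistics, R2, Bayesian skylines, Mantel tests and
  migration-rate estimation are out of scope.
* The connection-limit model documents its own multiple-hit
  approximation (above) rather than reproducing any specific program's
  table of limits.
* Reproducing a specific survey's printed tables requires that survey's
  deposited sequences and haplotype count table; the package ships only
  printed summary tables (distances, fitted expansion parameters) and
  synthetic data.
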