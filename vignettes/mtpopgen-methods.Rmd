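---
title: "Methods: mtDNA population genetics on partial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA population genetics on partial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpopgen)
```

## Scope and data model

`mtpopgen` analyses aligned human mitochondrial DNA restricted to a
configurable set of rCRS windows. The shipped defaults mirror a common
partial-genome screening design: a statistics window of the coding
regions 8001–9000 and 9801–10900 plus HVS-I 16051–16400 (2450 sites,
`stat_regions()`), cut from a wider sequencing window whose HVS-I part
runs 16001–16569 (`screened_regions()`, 2669 sites). Window lengths are
always computed from the configured bounds and never hard-coded, so any
other screening design is a one-line change.

Each sample is reduced to its substitutions relative to the reference
(a variant profile) plus a set of uncallable positions. Indels and
heteroplasmies are excluded by design: every downstream statistic
operates on substitution differences. Missing data are handled by
pairwise deletion — a site uncallable in either member of a pair is
excluded from both the difference count and the compared-site count, and
nucleotide diversity uses the per-pair compared-site denominators.
Haplotype identity is exact equality of called variant sets; this is
deterministic and close to the convention of standard population-genetics
packages, at the price of splitting samples that differ only in
missingness.

## Diversity and neutrality statistics

Per population the package reports the classical summary set: haplotype
count `k`, polymorphic sites `S`, Nei's gene diversity
$H = \frac{n}{n-1}(1 - \sum p_i^2)$ with Nei's sampling variance, the
mean number of pairwise differences (MNPd), and nucleotide diversity
$\pi$ (mean per-site pairwise difference). The standard error of $\pi$
is a Monte-Carlo bootstrap over individuals (default 100 resamples);
the full covariance formula is deliberately not implemented.

Tajima's D uses the 1989 constants; `S = 0` returns `NA`. Fu's Fs is
computed from the Ewens sampling formula,
$S' = P(K \ge k_{\mathrm{obs}})$ and $F_s = \ln(S'/(1-S'))$, with
unsigned Stirling numbers of the first kind evaluated in log-space by
their recurrence so that sample sizes of several hundred remain finite.
The mass is split at $k$ before forming the ratio, so extreme tails stay
accurate. The $\theta$ plugged into Fs and into all null simulations is
the pairwise estimator MNPd ($\theta_\pi$), the convention of the
standard AMOVA software this package follows.

P-values for both tests come from coalescent simulation under selective
neutrality and constant size, with $\theta$ fixed at the observed MNPd
and matched `n`; the reported p is the left-tail fraction (the direction
in which demographic expansion pushes both statistics). The default is
1000 replicates. Significance stars in reports follow the thresholds
`*` p ≤ 0.02, `**` p ≤ 0.01, `***` p ≤ 0.001, and populations under 20
samples are flagged, since their indices are unstable.

## Population structure

Pairwise Fst is the two-population AMOVA on the pairwise
substitution-difference matrix (Excoffier–Smouse–Quattro sums of
squares and variance components). Small negative estimates are reported
as computed — they are informative about sampling noise — and floored at
zero only where downstream mathematics requires it (gene flow, MDS),
with a warning. Significance is by permutation of individuals between
the two populations (default 1000, seedable); the p-value uses the
inclusive $(c+1)/(B+1)$ estimator. Gene flow is the haploid island-model
inversion $M = N_e m = (1-F_{st})/(2F_{st})$, with `Inf` for
non-positive Fst. Note that AMOVA Fst is not exactly invariant to
replicating every sample — the variance components carry $N-2$ and
$\bar n$ terms that only cancel asymptotically — so such invariance is
only checked at its exact boundary cases.

Ordination is classical (Torgerson) metric MDS of the Fst matrix via
double-centering and eigendecomposition (`stats::cmdscale`); the
reported stress is the fraction of total absolute eigenvalue mass not
captured by the retained axes, and Euclidean-embeddable matrices are
recovered exactly.

## Mismatch distributions and the sudden-expansion model

The mismatch spectrum is the histogram of all pairwise differences. Its
expectation under a sudden expansion
($\theta_0 \to \theta_1$ at $\tau$ mutational units ago) is the
Rogers–Harpending form
$$F_j = \hat F_j(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
\sum_{i=0}^{j} \frac{\tau^i}{i!}\left[\hat F_{j-i}(\theta_0) -
\hat F_{j-i}(\theta_1)\right], \qquad
\hat F_j(\theta) = \frac{\theta^j}{(\theta+1)^{j+1}},$$
with $\theta_1 = \infty$ handled by its limit (the Poisson
$e^{-\tau}\tau^j/j!$ when additionally $\theta_0 = 0$). Fitting
minimises the plain sum of squared deviations (SSD) over
$(\tau, \theta_0, \theta_1)$ — generalised least squares is not used
because SSD is the statistic being tested — by Nelder–Mead from a
27-point grid of starts ($\tau \in \{MNPd/2, MNPd, 2\,MNPd\}$,
$\theta_0 \in \{0, 0.1, 1\}$, $\theta_1 \in \{10, 100, \infty\}$) on a
log parameterisation that keeps all parameters positive and
$\theta_1 > \theta_0$, followed by a simplex restart from the incumbent.
$\theta_1$ is bounded at $10^5$, and at the bound the objective evaluates
the exact infinite-size limit, so the bound is a sentinel for $\infty$
rather than an approximation. Model mass beyond the largest observed
class is pooled into the last class before the SSD. A one-class
spectrum returns a $\tau = 0$ fit with a warning.

Harpending's raggedness is $r = \sum (x_i - x_{i-1})^2$ over the
relative frequencies. Bootstrap p-values for SSD and raggedness
simulate the fitted expansion with the package's own coalescent,
refit each replicate (a light four-start refit), and report the
fraction of replicates at or above the observed statistic. The combined
verdict labels a population "expansion" when Fu's Fs is significantly
negative (p ≤ 0.02) and the SSD does not reject the expansion model
(p > 0.02).

## Rho-based dating

A clade's age is estimated from an explicit rooted genealogy whose
branch lengths are substitution counts — the package does not infer
trees. $\rho$ is the mean root-to-tip substitution count and Saillard's
$\sigma = \frac{1}{n}\sqrt{\sum_l n_l^2 m_l}$ its standard error. The
complete-genome clock converts $\rho$ to kyr as
$$T = m\,\rho\,\exp(-\exp(-g_1(\rho + g_2)))$$
with defaults $m = 3.624$ kyr per substitution, $g_1 = 0.0263$,
$g_2 = 40.28$: a Gompertz-type factor in $(0,1)$, increasing in $\rho$,
that compensates the young-clade substitution deficit caused by
purifying selection. Confidence bounds apply the correction factor
evaluated at the central $\rho$ to $\rho \pm 1.96\sigma$, producing
intervals symmetric around the point estimate; lower bounds may be
negative and are reported as computed. Report rounding is one decimal,
half away from zero. For collections without a resolved genealogy,
`star_rho()` computes $\rho$ against a supplied founder haplotype with
the star-tree closed form $\sigma = \sqrt{\rho/n}$.

Partial-sequence dating converts a per-sequence substitution interval
into kyr. `combine_rates()` forms the length-weighted mean of per-site
segment rates; with the shipped calibration (HVS-I
$1.602\times10^{-7}$/site/yr, coding $3.42\times10^{-8}$/site/yr over
2121 sites — one substitution per 13,786 years) a 350-site HVS-I window
yields a combined rate near $5.21\times10^{-8}$. Published analyses
sometimes print a slightly different combined constant (e.g.
$5.27\times10^{-8}$, one substitution per 8,940 years) whose length
bookkeeping cannot be reproduced from the stated inputs; such printed
constants can be supplied verbatim through `interval_override`, and both
routes are exposed rather than silently reconciled.

```{r dating-example}
clk <- clock_model()
corrected_time(c(0.5, 1, 2), clk)
time_ci(0.5, 0.5, clk)
```

## Median-joining networks

Haplotypes are encoded as allele vectors over the union of variant
positions, with the reference state as ancestral. The minimum spanning
network (union of all minimum spanning trees) is built Kruskal-style;
median joining then repeatedly proposes, for every MSN-linked triple,
the per-position majority vector — a three-way tie keeps the ancestral
state — adds medians that reduce the total spanning cost (within
`epsilon`, default 0, the standard mtDNA setting), prunes medians whose
removal leaves the cost unchanged, and stops at a fixpoint. All
positions are weighted equally. Output order and tie-breaks are
lexicographic on haplotype keys, so the network is deterministic. On
infinite-sites (homoplasy-free) data the final network realises the
minimal cost — the number of mutation events separating distinct
haplotypes — with medians standing in for unsampled internal
haplotypes.

## The coalescent simulator

The synthetic-data generator is a Kingman coalescent for a
non-recombining locus, with time measured in mutational units (expected
substitutions per lineage), so the mismatch model's $\tau$ and the
simulator's epoch times live on the same scale. Demographies: constant
size $\theta_0$; sudden expansion (size $\theta_1$, possibly infinite,
back to $\tau/2$, then $\theta_0$); and a clean two-deme split with no
migration for structure tests. Mutations are Poisson per branch,
assigned to regions proportionally to per-site rate times region length
and to previously unused positions within the region — an
infinite-sites approximation on finite coordinates, chosen so the
analytic oracles (Watterson's $E[S] = \theta a_1$, the geometric
two-sample mismatch, the Rogers–Harpending expectation) hold exactly.
The default per-region rates are the HVS-I/coding calibration above, so
the HVS-I window evolves about 4.7 times faster per site than the
coding windows, as in real data.

What the simulator does **not** emulate: finite-sites homoplasy and
back-mutation (HVS-I hotspots revert in real data), rate heterogeneity
within regions, indels and heteroplasmy, sequencing error, migration
beyond the clean split, and selection. Tests passing on this generator
therefore validate the estimators' arithmetic and sampling behaviour
under their own model assumptions, not robustness to the noise of real
mtDNA surveys; the haplogroup classifier in particular is a
deterministic path-matching tool for clean data, not a replacement for
database-backed callers.

```{r sim-example}
sim <- simulate_dataset(c(A = 12, B = 12),
                        demographic_model("constant", 4),
                        split_time = 10, seed = 7)
diversity_summary(sim$dataset, reps = 100, seed = 8)[, 1:8]
```

## Numerical and design choices

- Coordinates are 1-based inclusive rCRS positions throughout.
- The admixture partition works on frequency mass at whatever haplogroup
  resolution the caller supplies, with parent-1 precedence for shared
  haplogroups (the second pool is defined as "not shared with" the
  first); count-based sharing is not implemented because published
  share tables are percentage-of-lineages based.
- Classification ties break by matched count, then matched fraction,
  then path depth, then name — the fraction step keeps a fully matched
  node ahead of its partially matched descendants.
- Seeds: every stochastic routine accepts a `seed` and restores the RNG
  state afterwards (`withr`), so pipelines are byte-reproducible.
- Problem sizes in the shipped test suite are chosen to finish on one
  CPU in minutes while keeping Monte-Carlo error well inside the
  asserted bands: 2000 replicates for the simulator's moment checks,
  200 fits for $\tau$ recovery (n = 100), 500 star clades for TMRCA
  coverage (n = 50), and a 200 x 150 nested design (n = 25) for p-value
  calibration.

## Known limitations

Beyond the simulator's idealisations: the SSD bootstrap refits with a
reduced start grid (a speed/robustness trade-off that can slightly
inflate replicate SSDs); hierarchical AMOVA, non-metric MDS, Fu & Li
tests, Bayesian skyline reconstruction and tree inference are out of
scope; and the gene-flow inversion assumes island-model equilibrium,
so `M` should be read as a relative, not literal, migrant count.
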