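# mtpopgen

Population-genetic analysis of aligned human mitochondrial DNA restricted
to configurable rCRS windows — the partial-genome design (coding regions
8001–9000 and 9801–10900 plus HVS-I) used by many mtDNA surveys of East
and Southeast Asian populations. The package is aimed at researchers who
have region-screened mtDNA alignments and want the full classical
analysis battery, reproducibly and scriptably, together with a coalescent
simulator to validate every estimator on data with known truth.

## What it computes

* **Variant profiles & haplotypes** — rCRS-relative substitution sets
  with pairwise-deletion handling of missing calls; haplotype collapsing.
* **Molecular diversity** — Nei's gene diversity
  $H = \frac{n}{n-1}(1-\sum p_i^2)$ with its sampling SE, nucleotide
  diversity $\pi$, mean pairwise differences (MNPd), polymorphic sites.
* **Neutrality tests** — Tajima's $D$ and Fu's
  $F_s = \ln\!\frac{S'}{1-S'}$ with $S' = P(K \ge k_{obs})$ from the
  Ewens sampling formula (log-space Stirling numbers), p-values by
  coalescent simulation under neutrality.
* **Structure** — AMOVA pairwise $F_{st}$ on the difference matrix with
  permutation significance, island-model gene flow
  $M = N_e m = (1-F_{st})/(2F_{st})$, classical MDS of the $F_{st}$
  matrix.
* **Demography** — mismatch distributions, Rogers–Harpending
  sudden-expansion fits $(\tau, \theta_0, \theta_1)$ by SSD
  minimisation, Harpending's raggedness, parametric-bootstrap p-values,
  and the combined $F_s$ + SSD expansion verdict.
* **Dating** — the $\rho$ statistic and Saillard's $\sigma$ on
  substitution-count genealogies, converted to kyr by the corrected
  clock $T = m\rho\,\exp(-\exp(-g_1(\rho+g_2)))$
  (defaults $m = 3.624$, $g_1 = 0.0263$, $g_2 = 40.28$), plus
  length-weighted substitution-rate calibration for partial sequences.
* **Networks** — deterministic median-joining haplotype networks
  (minimum spanning network + majority-median vectors).
* **Synthetic data** — a seeded Kingman coalescent (constant size,
  sudden expansion, clean two-deme split) with region-structured
  mutation rates under the infinite-sites approximation.

All user-facing functions take a data frame (or the `mt_dataset`
container) first and return tibbles; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(mtpopgen)

sim <- simulate_dataset(c(Coastal = 25, Highland = 25),
                        demographic_model("constant", 5),
                        split_time = 6, seed = 42)
ds <- sim$dataset

diversity_summary(ds, reps = 200, seed = 1)
#>   population  n k  S     H      pi MNPd tajima_D   p_D fu_Fs  p_Fs
#> 1    Coastal 25 6 14 0.717 0.00155 3.79   0.0802 0.570  2.24 0.860
#> 2   Highland 25 6 12 0.537 0.00111 2.71  -0.4968 0.337  1.04 0.759

f <- pairwise_fst(ds, "Coastal", "Highland", n_perm = 200, seed = 2)
c(fst = f$fst, p = f$p, M = gene_flow_m(f$fst))
#>   fst     p     M
#> 0.639 0.005 0.280
```

The two demes split six mutational time units ago with no migration, so
both carry modest within-population diversity (neither neutrality test
rejects, both p ≈ 0.3–0.9) while differentiation is strong and
significant ($F_{st} = 0.64$, permutation p = 0.005), implying well
under one effective migrant per generation (M = 0.28).

Dating a clade genealogy with substitution-count branch lengths:

```r
clades <- ape::read.tree(system.file("extdata", "example_clades.nwk",
                                     package = "mtpopgen"))
date_clades(stats::setNames(clades, c("c1", "c2", "c3")))
#>   clade n rho sigma t_kyr  ci_low ci_high t_rounded low_rounded high_rounded
#> 1    c1 3   1 0.577  2.59 -0.3403    5.51       2.6        -0.3         5.5
#> 2    c2 3   2 0.943  5.22  0.3967   10.04       5.2         0.4        10.0
#> 3    c3 4   1 0.500  2.59  0.0517    5.12       2.6         0.1         5.1
```

A clade whose tips average one substitution from the root dates to
2.6 kyr under the corrected clock; the negative lower bound for `c1` is
reported as computed, as is conventional for $\rho$-based intervals.

An end-to-end run (diversity → structure/MDS → mismatch → haplogroups →
admixture → dating → network, each stage written as TSV with a seeded
log) is one call:

```r
cfg <- pipeline_config(fasta = "samples.fasta", pops = "pops.tsv",
                       reference = "reference.fasta", out_dir = "out",
                       seed = 1)
run_pipeline(cfg)
```

A thin command-line wrapper with `simulate`, `all` and `date`
subcommands is installed at
`system.file("scripts", "mtpopgen", package = "mtpopgen")`.

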