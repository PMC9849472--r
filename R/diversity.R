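#' Gene (haplotype) diversity with Nei's standard error
#'
#' \eqn{H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} with sampling
#' variance (Nei 1987)
#' \eqn{V = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#' \left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
#' \left(\sum p_i^2\right)^2\right\}}.
#'
#' @param counts Integer vector of haplotype (or haplogroup) counts.
#' @return List with `H` and `se`.
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) abort("Gene diversity needs at least 2 samples.")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- (2 / (n * (n - 1))) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, se = sqrt(max(V, 0)))
}

#' Nucleotide diversity and mean pairwise differences
#'
#' MNPd is the mean count of substitution differences over all
#' \eqn{n(n-1)/2} sample pairs; \eqn{\pi} is the mean over pairs of
#' differences per compared site (pairwise deletion of missing data).
#'
#' @param ds An `mt_dataset` (single population expected; subset first).
#' @param dist Optional precomputed [pairwise_diff_matrix()].
#' @return List with `pi`, `MNPd`.
#' @export
nucleotide_diversity <- function(ds, dist = NULL) {
  d <- dist %||% pairwise_diff_matrix(ds)
  ut <- upper.tri(d$differences)
  if (!any(ut)) return(list(pi = 0, MNPd = 0))
  list(
    pi = mean(d$differences[ut] / d$compared_sites[ut]),
    MNPd = mean(d$differences[ut])
  )
}

#' Number of polymorphic (segregating) sites
#'
#' A site is polymorphic when at least two distinct alleles (reference
#' or derived) are observed among the samples with a call at that site.
#'
#' @param ds An `mt_dataset`.
#' @return Integer count.
#' @export
segregating_sites <- function(ds) {
  pos_all <- sort(unique(unlist(purrr::map(ds$variants,
                                           \(v) as.integer(names(v))))))
  if (length(pos_all) == 0) return(0L)
  n_seg <- 0L
  for (p in pos_all) {
    key <- as.character(p)
    alleles <- purrr::map2_chr(ds$variants, ds$missing, function(v, m) {
      if (p %in% m) NA_character_
      else if (key %in% names(v)) v[[key]]
      else "ref"
    })
    if (length(unique(stats::na.omit(alleles))) > 1) n_seg <- n_seg + 1L
  }
  n_seg
}

#' Tajima's D
#'
#' Compares the pairwise-difference estimator of theta with Watterson's
#' estimator from the number of segregating sites; strongly negative
#' values indicate an excess of rare variants, as after a population
#' expansion.
#'
#' @param n Sample size.
#' @param S Number of segregating sites.
#' @param MNPd Mean number of pairwise differences.
#' @return D, or `NA` when `S == 0`.
#' @export
tajimas_d <- function(n, S, MNPd) {
  if (n < 2) abort("Tajima's D needs n >= 2.")
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (MNPd - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log unsigned Stirling numbers of the first kind, row n (j = 1..n),
# computed by the recurrence |s(n+1,j)| = n|s(n,j)| + |s(n,j-1)| in
# log-space; cached per n (cheap up to n of several hundred)
stirling_cache <- new.env(parent = emptyenv())

stirling_log_row <- function(n) {
  key <- as.character(n)
  hit <- stirling_cache[[key]]
  if (!is.null(hit)) return(hit)
  row <- 0 # n = 1: |s(1,1)| = 1
  if (n > 1) {
    for (m in 1:(n - 1)) {
      row <- logaddexp(c(-Inf, row), c(log(m) + row, -Inf))
    }
  }
  stirling_cache[[key]] <- row
  row
}

#' Fu's Fs neutrality statistic
#'
#' Uses the Ewens sampling formula: with theta estimated from the mean
#' pairwise differences, \eqn{S' = P(K \ge k_{obs})} is the probability
#' of observing at least the observed number of haplotypes, and
#' \eqn{F_s = \ln(S'/(1-S'))}. Allele-count probabilities are computed
#' from unsigned Stirling numbers of the first kind in log-space.
#'
#' @param n Sample size.
#' @param k Observed number of distinct haplotypes.
#' @param theta Theta estimate (conventionally MNPd).
#' @return Fs; `NA` when `theta <= 0`; `Inf` when `S'` is numerically 1
#'   (e.g. `k = 1`).
#' @export
fus_fs <- function(n, k, theta) {
  if (n < 1 || k < 1 || k > n) abort("Need 1 <= k <= n.")
  if (is.na(theta) || theta <= 0) return(NA_real_)
  ls <- stirling_log_row(n)
  j <- seq_len(n)
  log_p <- ls + j * log(theta) - sum(log(theta + 0:(n - 1)))
  # Ewens probabilities sum to 1; split the mass at k for stable tails
  log_Sp <- logsumexp(log_p[j >= k])
  log_Sm <- if (k == 1) -Inf else logsumexp(log_p[j < k])
  if (is.infinite(log_Sm)) return(Inf)
  if (is.infinite(log_Sp)) return(-Inf)
  log_Sp - log_Sm
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Simulation p-values for Tajima's D and Fu's Fs
#'
#' Simulates `reps` constant-size coalescent samples of matched size with
#' theta fixed at the observed MNPd, and reports the left-tail fraction
#' of simulated statistics at or below the observed values (the
#' direction in which population expansion pushes both statistics).
#'
#' @param n Sample size.
#' @param D_obs,Fs_obs Observed statistics.
#' @param theta Theta used for the null simulations (observed MNPd).
#' @param reps Number of coalescent simulations (default 1000).
#' @param seed Optional integer seed.
#' @return List with `p_D`, `p_Fs`.
#' @export
neutrality_pvalues <- function(n, D_obs, Fs_obs, theta,
                               reps = 1000, seed = NULL) {
  if (reps < 100) warn("Fewer than 100 simulations: p-values are coarse.")
  if (is.na(theta) || theta <= 0) return(list(p_D = NA_real_, p_Fs = NA_real_))
  sims <- with_seed_(seed, purrr::map(seq_len(reps), function(i) {
    st <- sim_summary_stats(n, list(kind = "constant", theta0 = theta))
    list(
      D = if (st$S == 0) NA_real_ else tajimas_d(n, st$S, st$MNPd),
      Fs = if (st$MNPd <= 0) NA_real_ else fus_fs(n, st$k, st$MNPd)
    )
  }))
  D_sim <- purrr::map_dbl(sims, "D")
  Fs_sim <- purrr::map_dbl(sims, "Fs")
  list(
    p_D = if (is.na(D_obs)) NA_real_ else
      mean(D_sim[!is.na(D_sim)] <= D_obs),
    p_Fs = if (is.na(Fs_obs)) NA_real_ else
      mean(Fs_sim[!is.na(Fs_sim)] <= Fs_obs)
  )
}

#' Per-population molecular diversity summary
#'
#' One row per population with the classical summary statistics of an
#' mtDNA survey: sample size `n`, haplotype count `k`, `k/n`, polymorphic
#' sites `S`, gene diversity `H` with Nei's SE, nucleotide diversity `pi`
#' with a bootstrap SE (resampling individuals), mean pairwise
#' differences `MNPd`, Tajima's D and Fu's Fs with coalescent-simulation
#' p-values and significance stars (`*` p <= 0.02, `**` p <= 0.01,
#' `***` p <= 0.001). Populations with fewer than 20 samples are flagged
#' `small_n`, a caution echoed in the reporting conventions of mtDNA
#' surveys.
#'
#' @param ds An `mt_dataset`.
#' @param reps Coalescent simulations per population for p-values
#'   (default 1000); `0` skips p-values.
#' @param boot Bootstrap replicates for the SE of `pi` (default 100).
#' @param seed Optional integer seed.
#' @return A tibble, one row per population.
#' @export
diversity_summary <- function(ds, reps = 1000, boot = 100, seed = NULL) {
  rs <- dataset_regions(ds)
  pops <- unique(ds$population)
  with_seed_(seed, purrr::map(pops, function(p) {
    sub <- ds[ds$population == p, , drop = FALSE]
    attr(sub, "region_set") <- rs
    n <- nrow(sub)
    counts <- haplotype_counts(sub)
    dm <- pairwise_diff_matrix(sub)
    nd <- nucleotide_diversity(sub, dm)
    S <- segregating_sites(sub)
    gd <- if (n >= 2) gene_diversity(counts) else list(H = NA_real_, se = NA_real_)
    D <- if (n >= 2) tajimas_d(n, S, nd$MNPd) else NA_real_
    Fs <- if (n >= 2) fus_fs(n, length(counts), nd$MNPd) else NA_real_
    pi_se <- if (boot > 0 && n >= 3) {
      boots <- purrr::map_dbl(seq_len(boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        db <- dm$differences[idx, idx] / dm$compared_sites[idx, idx]
        mean(db[upper.tri(db)])
      })
      stats::sd(boots)
    } else NA_real_
    pv <- if (reps > 0 && n >= 4 && nd$MNPd > 0) {
      neutrality_pvalues(n, D, Fs, nd$MNPd, reps = reps)
    } else list(p_D = NA_real_, p_Fs = NA_real_)
    tibble(
      population = p, n = n, k = length(counts), k_over_n = length(counts) / n,
      S = S, H = gd$H, H_se = gd$se, pi = nd$pi, pi_se = pi_se,
      MNPd = nd$MNPd, tajima_D = D, p_D = pv$p_D, D_sig = p_stars(pv$p_D),
      fu_Fs = Fs, p_Fs = pv$p_Fs, Fs_sig = p_stars(pv$p_Fs),
      small_n = n < 20
    )
  })) |> bind_rows()
}
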