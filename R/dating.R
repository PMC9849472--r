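#' Clock model for corrected rho-based dating
#'
#' The complete-genome molecular clock used for TMRCA estimation: `m`
#' kyr per substitution, with a Gompertz-type correction factor
#' \eqn{\exp(-\exp(-g_1(\rho + g_2)))} that compensates the deficit of
#' old substitutions removed by purifying selection. Defaults are the
#' complete-mtDNA calibration (one substitution per 3.624 kyr,
#' `g1 = 0.0263`, `g2 = 40.28`).
#'
#' @param m Kyr per substitution (default 3.624).
#' @param g1,g2 Correction constants.
#' @param label Free-text label.
#' @return A `clock_model` list.
#' @export
clock_model <- function(m = 3.624, g1 = 0.0263, g2 = 40.28,
                        label = "complete mtDNA") {
  if (m <= 0) abort("Clock rate m must be positive.")
  structure(list(m = m, g1 = g1, g2 = g2, label = label),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("<clock_model> ", x$label, ": ", x$m, " kyr/substitution, g1 = ",
      x$g1, ", g2 = ", x$g2, "\n", sep = "")
  invisible(x)
}

# correction factor in (0, 1), increasing in rho
clock_correction <- function(rho, clock) {
  exp(-exp(-clock$g1 * (rho + clock$g2)))
}

#' Validate a clade genealogy for dating
#'
#' Dating operates on an explicit rooted tree whose branch lengths are
#' substitution counts (the package does not infer trees). Reads Newick
#' via [ape::read.tree()] upstream; this validator checks the contract.
#'
#' @param phy A rooted `phylo` with non-negative integer branch lengths.
#' @return The validated `phylo`, invisibly classed as before.
#' @export
clade_genealogy <- function(phy) {
  if (!inherits(phy, "phylo")) abort("Expected an ape 'phylo' tree.")
  if (is.null(phy$edge.length)) abort("Tree has no branch lengths.")
  if (ape::Ntip(phy) < 2) abort("Need at least 2 tips.")
  bl <- phy$edge.length
  if (any(bl < 0) || any(abs(bl - round(bl)) > 1e-8)) {
    abort("Branch lengths must be non-negative integer substitution counts.")
  }
  phy
}

#' Rho statistic of a clade
#'
#' Mean number of substitutions on the root-to-tip path, averaged over
#' all sampled tips; the raw molecular-clock age estimator.
#'
#' @param phy A `phylo` with substitution-count branch lengths.
#' @return Rho (numeric).
#' @export
rho_statistic <- function(phy) {
  phy <- clade_genealogy(phy)
  depths <- ape::node.depth.edgelength(phy)
  mean(depths[seq_len(ape::Ntip(phy))])
}

#' Saillard standard error of rho
#'
#' \eqn{\sigma = \frac{1}{n}\sqrt{\sum_l n_l^2 m_l}} where `m_l` is the
#' substitution count of branch `l` and `n_l` the number of sampled tips
#' descending from it.
#'
#' @param phy A `phylo` with substitution-count branch lengths.
#' @return Sigma (numeric).
#' @export
saillard_sigma <- function(phy) {
  phy <- clade_genealogy(phy)
  n <- ape::Ntip(phy)
  # tips below each edge's child node
  n_l <- purrr::map_int(phy$edge[, 2], function(node) {
    if (node <= n) 1L else {
      length(unlist(ape::prop.part(phy)[[node - n]]))
    }
  })
  sqrt(sum(n_l^2 * phy$edge.length)) / n
}

#' Corrected TMRCA from rho
#'
#' \eqn{T(\mathrm{ka}) = m\,\rho\,\exp(-\exp(-g_1(\rho + g_2)))}: the
#' raw rho-clock age multiplied by the purifying-selection correction.
#'
#' @param rho Rho statistic (vectorised, `>= 0`).
#' @param clock A [clock_model()].
#' @return Age(s) in kyr.
#' @export
corrected_time <- function(rho, clock = clock_model()) {
  if (any(rho < 0)) abort("rho must be non-negative.")
  clock$m * rho * clock_correction(rho, clock)
}

#' 95% confidence interval of the corrected TMRCA
#'
#' Bounds are \eqn{m\,\exp(-\exp(-g_1(\rho+g_2)))\,(\rho \pm 1.96\sigma)}:
#' the correction factor is evaluated at the central rho and applied to
#' both bounds, giving intervals symmetric around the point estimate.
#' Lower bounds may be negative and are reported as computed.
#'
#' @param rho,sigma Rho and its Saillard standard error.
#' @param clock A [clock_model()].
#' @return List with `low` and `high` in kyr.
#' @export
time_ci <- function(rho, sigma, clock = clock_model()) {
  if (any(rho < 0) || any(sigma < 0)) abort("rho and sigma must be >= 0.")
  f <- clock$m * clock_correction(rho, clock)
  list(low = f * (rho - 1.96 * sigma), high = f * (rho + 1.96 * sigma))
}

#' Date a set of clade genealogies
#'
#' @param clades A named list of `phylo` trees (or a `multiPhylo`), each
#'   with substitution-count branch lengths.
#' @param clock A [clock_model()].
#' @param digits Decimals for the rounded report columns (half-up,
#'   default 1).
#' @return A tibble: `clade`, `n`, `rho`, `sigma`, `t_kyr`, `ci_low`,
#'   `ci_high` plus rounded report columns `t_rounded`, `low_rounded`,
#'   `high_rounded`.
#' @export
date_clades <- function(clades, clock = clock_model(), digits = 1) {
  if (inherits(clades, "phylo")) clades <- list(clade = clades)
  nms <- names(clades) %||% paste0("clade", seq_along(clades))
  purrr::map2(clades, nms, function(phy, nm) {
    rho <- rho_statistic(phy)
    sigma <- saillard_sigma(phy)
    t_kyr <- corrected_time(rho, clock)
    ci <- time_ci(rho, sigma, clock)
    tibble(
      clade = nm, n = ape::Ntip(phy), rho = rho, sigma = sigma,
      t_kyr = t_kyr, ci_low = ci$low, ci_high = ci$high,
      t_rounded = round_half_up(t_kyr, digits),
      low_rounded = round_half_up(ci$low, digits),
      high_rounded = round_half_up(ci$high, digits)
    )
  }) |> bind_rows()
}

#' Star-genealogy rho from a root haplotype
#'
#' Fallback when no resolved genealogy is available: rho is the mean
#' number of differences between each sample and a supplied root
#' (founder) haplotype, and sigma takes the star-tree closed form
#' \eqn{\sqrt{\rho/n}}.
#'
#' @param ds An `mt_dataset` (one clade's samples).
#' @param root_variants Named character vector of the root haplotype's
#'   variants (position -> base), in the dataset's region set.
#' @return List with `rho`, `sigma`, `n`.
#' @export
star_rho <- function(ds, root_variants = character(0)) {
  rs <- dataset_regions(ds)
  root <- list(variants = canonical_variants(root_variants),
               missing = integer(0))
  diffs <- purrr::map_dbl(seq_len(nrow(ds)), function(i) {
    pairwise_differences(list(variants = ds$variants[[i]],
                              missing = ds$missing[[i]]),
                         root, rs)$differences
  })
  n <- nrow(ds)
  rho <- mean(diffs)
  list(rho = rho, sigma = sqrt(rho / n), n = n)
}

#' Combine per-region substitution rates
#'
#' Length-weighted mean of per-site rates across sequence segments, plus
#' the implied waiting time for one substitution anywhere on the
#' concatenated sequence:
#' `combined = sum(rate * length) / sum(length)`,
#' `interval = 1 / (combined * sum(length))` years.
#'
#' @param rate Per-site substitution rates (substitutions/site/year).
#' @param length Segment lengths in sites.
#' @return An object of class `rate_calibration`: list with `segments`
#'   tibble, `combined_per_site_rate`, `per_sequence_interval_years`.
#' @export
combine_rates <- function(rate, length) {
  if (any(rate <= 0) || any(length <= 0)) {
    abort("Rates and lengths must be positive.")
  }
  combined <- sum(rate * length) / sum(length)
  structure(
    list(
      segments = tibble(rate = rate, length = as.integer(length)),
      combined_per_site_rate = combined,
      per_sequence_interval_years = 1 / (combined * sum(length))
    ),
    class = "rate_calibration"
  )
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat("<rate_calibration> combined ", signif(x$combined_per_site_rate, 4),
      " subs/site/yr; one substitution per ",
      round(x$per_sequence_interval_years), " years\n", sep = "")
  invisible(x)
}

#' @rdname combine_rates
#' @param x A `rate_calibration`.
#' @param ... Unused.
#' @method glance rate_calibration
#' @export
glance.rate_calibration <- function(x, ...) {
  tibble(
    n_segments = nrow(x$segments),
    total_length = sum(x$segments$length),
    combined_per_site_rate = x$combined_per_site_rate,
    per_sequence_interval_years = x$per_sequence_interval_years
  )
}

#' Date a clade from partial-sequence rho
#'
#' Converts a rho computed on partial (concatenated-region) sequences to
#' an age using a per-sequence substitution interval, optionally applying
#' the same Gompertz-type correction as the complete-genome clock. The
#' interval normally comes from [combine_rates()]; a printed literature
#' constant (e.g. one substitution per 8,940 years) can be supplied as
#' `interval_override`.
#'
#' @param rho Rho on the partial sequence (`>= 0`).
#' @param calibration A [combine_rates()] result.
#' @param correct Apply the Gompertz correction? (default `FALSE`).
#' @param clock Clock supplying `g1`, `g2` when `correct = TRUE`.
#' @param interval_override Years per substitution, overriding the
#'   calibration.
#' @return Age in kyr.
#' @export
date_clade_partial <- function(rho, calibration = NULL, correct = FALSE,
                               clock = clock_model(),
                               interval_override = NULL) {
  if (any(rho < 0)) abort("rho must be non-negative.")
  interval <- interval_override %||%
    calibration$per_sequence_interval_years
  if (is.null(interval)) abort("Need a calibration or an interval override.")
  t_kyr <- rho * interval / 1000
  if (correct) t_kyr <- t_kyr * clock_correction(rho, clock)
  t_kyr
}
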