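#' Mismatch distribution of a sample
#'
#' Histogram of the \eqn{n(n-1)/2} pairwise substitution differences.
#' Smooth unimodal spectra are the signature of a past sudden demographic
#' expansion; ragged multimodal spectra indicate stationary history.
#'
#' @param x An `mt_dataset`, or a numeric vector of pairwise difference
#'   counts.
#' @param population Optional label(s) to subset an `mt_dataset`.
#' @return An object of class `mismatch_spectrum`: list with `counts`
#'   (integer vector over 0..J), `relative` (frequencies summing to 1),
#'   `n_pairs`, `MNPd`, `n` (samples, when known).
#' @export
mismatch_spectrum <- function(x, population = NULL) {
  if (inherits(x, "mt_dataset") || is.data.frame(x)) {
    rs <- dataset_regions(x)
    if (!is.null(population)) {
      x <- x[x$population %in% population, , drop = FALSE]
      attr(x, "region_set") <- rs
    }
    n <- nrow(x)
    d <- pairwise_diff_matrix(x)$differences
    diffs <- d[upper.tri(d)]
  } else {
    diffs <- as.numeric(x)
    n <- NA_integer_
  }
  if (length(diffs) == 0) abort("Need at least one pair of samples.")
  J <- max(diffs)
  counts <- tabulate(diffs + 1, nbins = J + 1)
  structure(
    list(counts = counts, relative = counts / sum(counts),
         n_pairs = length(diffs), MNPd = mean(diffs), n = n),
    class = "mismatch_spectrum"
  )
}

#' @export
print.mismatch_spectrum <- function(x, ...) {
  cat("<mismatch_spectrum> ", x$n_pairs, " pairs, classes 0..",
      length(x$counts) - 1, ", MNPd = ", signif(x$MNPd, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname mismatch_spectrum
#' @param ... Unused.
#' @method tidy mismatch_spectrum
#' @export
tidy.mismatch_spectrum <- function(x, ...) {
  tibble(differences = seq_along(x$counts) - 1L,
         count = x$counts, frequency = x$relative)
}

#' Expected mismatch probabilities under sudden expansion
#'
#' Rogers-Harpending expectation for a population of scaled size
#' `theta0` that jumped to `theta1` at `tau` mutational time units ago:
#' with the equilibrium distribution
#' \eqn{\hat F_j(\theta) = \theta^j/(\theta+1)^{j+1}},
#' \deqn{F_j(\tau,\theta_0,\theta_1) = \hat F_j(\theta_1) +
#'   e^{-\tau(\theta_1+1)/\theta_1} \sum_{i=0}^{j} \frac{\tau^i}{i!}
#'   \left[\hat F_{j-i}(\theta_0) - \hat F_{j-i}(\theta_1)\right].}
#' `theta1 = Inf` is handled by its limit (\eqn{\hat F_j(\infty) = 0},
#' damping \eqn{e^{-\tau}}); `theta0 = 0, theta1 = Inf` collapses to the
#' Poisson \eqn{e^{-\tau}\tau^j/j!}.
#'
#' @param j Vector of mismatch classes (non-negative integers).
#' @param tau,theta0,theta1 Model parameters (all `>= 0`).
#' @return Probabilities, one per element of `j`.
#' @export
expected_mismatch <- function(j, tau, theta0, theta1) {
  if (tau < 0 || theta0 < 0 || theta1 < 0) {
    abort("tau, theta0 and theta1 must be non-negative.")
  }
  jmax <- max(j)
  idx <- 0:jmax
  f0 <- equilibrium_mismatch(idx, theta0)
  f1 <- equilibrium_mismatch(idx, theta1)
  # damped Poisson-like weights tau^i/i! * exp(-tau (theta1+1)/theta1)
  damp_rate <- if (is.infinite(theta1)) tau else tau * (theta1 + 1) / theta1
  log_w <- idx * log(tau) - lgamma(idx + 1) - damp_rate
  if (tau == 0) log_w <- c(0 - damp_rate, rep(-Inf, jmax))
  w <- exp(log_w)
  delta <- f0 - f1
  conv <- purrr::map_dbl(idx, \(jj) sum(w[1:(jj + 1)] * delta[(jj + 1):1]))
  (f1 + conv)[j + 1]
}

equilibrium_mismatch <- function(j, theta) {
  if (is.infinite(theta)) return(rep(0, length(j)))
  if (theta == 0) return(as.numeric(j == 0))
  exp(j * log(theta) - (j + 1) * log(theta + 1))
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{i=1}^{J} (x_i - x_{i-1})^2} over the relative mismatch
#' frequencies; small for smooth (expansion-like) spectra.
#'
#' @param spec A [mismatch_spectrum()] or a numeric vector of relative
#'   frequencies.
#' @return The index.
#' @export
raggedness <- function(spec) {
  x <- if (inherits(spec, "mismatch_spectrum")) spec$relative else
    as.numeric(spec)
  if (length(x) < 2) return(0)
  sum(diff(x)^2)
}

# SSD between an observed relative spectrum and the model expectation,
# with model tail mass (classes > J_obs) pooled into the last class
model_spectrum <- function(J_obs, tau, theta0, theta1) {
  f <- expected_mismatch(0:J_obs, tau, theta0, theta1)
  f[J_obs + 1] <- max(1 - sum(f[seq_len(J_obs)]), 0)
  f
}

ssd_objective <- function(x_obs, tau, theta0, theta1) {
  # the upper bound 1e5 is a sentinel for an infinite post-expansion size
  if (theta1 >= 1e5) theta1 <- Inf
  f <- model_spectrum(length(x_obs) - 1, tau, theta0, theta1)
  sum((x_obs - f)^2)
}

#' Fit the sudden-expansion model to a mismatch spectrum
#'
#' Minimises the sum of squared deviations between the observed relative
#' spectrum and the Rogers-Harpending expectation over
#' \eqn{(\tau, \theta_0, \theta_1)} by multi-start Nelder-Mead on a log
#' parameterisation that enforces \eqn{\theta_1 > \theta_0}. Starting
#' values cover \eqn{\tau \in \{MNPd/2, MNPd, 2 MNPd\}},
#' \eqn{\theta_0 \in \{0, 0.1, 1\}} and
#' \eqn{\theta_1 \in \{10, 100, \infty\}}; `theta1` is capped at `1e5`
#' (numerically infinite). Model tail mass beyond the largest observed
#' class is pooled into the last class.
#'
#' @param spec A [mismatch_spectrum()].
#' @param n Sample size (stored for bootstrapping; taken from the
#'   spectrum when available).
#' @return An object of class `expansion_fit`: list with `tau`,
#'   `theta0`, `theta1`, `ssd`, `raggedness`, `p_ssd`, `p_rag` (filled
#'   by [expansion_test()]), `n`, `spectrum`.
#' @export
fit_expansion <- function(spec, n = NULL) {
  if (!inherits(spec, "mismatch_spectrum")) abort("Expected a mismatch_spectrum.")
  n <- n %||% spec$n
  x <- spec$relative
  if (length(x) < 2) {
    warn("Degenerate one-class spectrum: returning a tau = 0 fit.")
    fit <- list(tau = 0, theta0 = 0, theta1 = 1e5,
                ssd = ssd_objective(x, 0, 0, 1e5))
  } else {
    mnpd <- max(spec$MNPd, 0.02)
    starts <- expand.grid(
      tau = c(mnpd / 2, mnpd, 2 * mnpd),
      theta0 = c(1e-3, 0.1, 1),
      theta1 = c(10, 100, 1e5)
    )
    obj <- function(par) {
      tau <- exp(par[1])
      theta0 <- exp(par[2])
      theta1 <- min(theta0 + exp(par[3]), 2e5)
      ssd_objective(x, tau, min(theta0, 1e5), min(theta1, 1e5))
    }
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      par0 <- c(log(starts$tau[s]), log(starts$theta0[s]),
                log(starts$theta1[s]))
      o <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # simplex restart from the incumbent sharpens near-converged optima
    best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 1500, reltol = 1e-14))
    fit <- list(
      tau = exp(best$par[1]),
      theta0 = min(exp(best$par[2]), 1e5),
      theta1 = min(exp(best$par[2]) + exp(best$par[3]), 1e5),
      ssd = best$value
    )
  }
  structure(
    c(fit, list(raggedness = raggedness(spec), p_ssd = NA_real_,
                p_rag = NA_real_, n = n, spectrum = list(spec))),
    class = "expansion_fit"
  )
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat("<expansion_fit> tau = ", signif(x$tau, 4),
      ", theta0 = ", signif(x$theta0, 4),
      ", theta1 = ", signif(x$theta1, 4),
      ", SSD = ", signif(x$ssd, 4),
      ", raggedness = ", signif(x$raggedness, 4), "\n", sep = "")
  if (!is.na(x$p_ssd)) {
    cat("  p(SSD) = ", x$p_ssd, ", p(raggedness) = ", x$p_rag, "\n", sep = "")
  }
  invisible(x)
}

#' @rdname fit_expansion
#' @param x An `expansion_fit`.
#' @param ... Unused.
#' @method tidy expansion_fit
#' @export
tidy.expansion_fit <- function(x, ...) {
  tibble(
    term = c("tau", "theta0", "theta1"),
    estimate = c(x$tau, x$theta0, x$theta1)
  )
}

#' @rdname fit_expansion
#' @method glance expansion_fit
#' @export
glance.expansion_fit <- function(x, ...) {
  tibble(ssd = x$ssd, p_ssd = x$p_ssd, raggedness = x$raggedness,
         p_rag = x$p_rag, n = x$n %||% NA_integer_)
}

#' Parametric-bootstrap p-values for SSD and raggedness
#'
#' Simulates `B` coalescent samples of the observed size under the
#' fitted sudden-expansion model, refits each simulated spectrum, and
#' reports the fraction of replicates whose statistic is at least the
#' observed one. A non-significant SSD means the expansion model cannot
#' be rejected.
#'
#' @param fit An [fit_expansion()] result with known `n`.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param refit_starts Number of Nelder-Mead starts per replicate
#'   (default 4: the observed fit plus a small grid).
#' @return The `expansion_fit` with `p_ssd` and `p_rag` filled in.
#' @export
expansion_test <- function(fit, B = 1000, seed = NULL, refit_starts = 4) {
  if (!inherits(fit, "expansion_fit")) abort("Expected an expansion_fit.")
  n <- fit$n
  if (is.null(n) || is.na(n)) abort("Sample size unknown; pass n to fit_expansion().")
  model <- demographic_model("sudden_expansion", theta0 = fit$theta0,
                             theta1 = fit$theta1, tau = fit$tau)
  stats_b <- with_seed_(seed, purrr::map(seq_len(B), function(b) {
    sim <- sim_summary_stats(n, model, want_diffs = TRUE)
    spec_b <- mismatch_spectrum(sim$diffs[upper.tri(sim$diffs)])
    fit_b <- refit_quick(spec_b, fit, refit_starts)
    list(ssd = fit_b$ssd, rag = raggedness(spec_b))
  }))
  ssd_b <- purrr::map_dbl(stats_b, "ssd")
  rag_b <- purrr::map_dbl(stats_b, "rag")
  fit$p_ssd <- mean(ssd_b >= fit$ssd)
  fit$p_rag <- mean(rag_b >= fit$raggedness)
  fit
}

# light refit used inside the bootstrap: observed fit plus a small grid
refit_quick <- function(spec, fit, n_starts) {
  x <- spec$relative
  if (length(x) < 2) return(list(ssd = ssd_objective(x, 0, 0, 1e5)))
  mnpd <- max(spec$MNPd, 0.02)
  starts <- list(
    c(fit$tau, max(fit$theta0, 1e-3), fit$theta1),
    c(mnpd, 1e-3, 1e5),
    c(mnpd / 2, 0.1, 100),
    c(2 * mnpd, 1, 1e5)
  )[seq_len(max(1, min(4, n_starts)))]
  obj <- function(par) {
    theta0 <- exp(par[2])
    ssd_objective(x, exp(par[1]), min(theta0, 1e5),
                  min(theta0 + exp(par[3]), 1e5))
  }
  best <- Inf
  for (s in starts) {
    par0 <- c(log(max(s[1], 1e-3)), log(s[2]), log(max(s[3] - s[2], 1e-3)))
    o <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
    if (o$value < best) best <- o$value
  }
  list(ssd = best)
}

#' Expansion verdict from the combined decision rule
#'
#' A population is labelled as expanded when Fu's Fs is significantly
#' negative and the sudden-expansion model is not rejected by SSD
#' (non-significant), the combined rule used when reading neutrality
#' tests together with mismatch fits.
#'
#' @param fs Observed Fu's Fs.
#' @param p_fs Its simulation p-value.
#' @param p_ssd Bootstrap p-value of the SSD.
#' @param alpha_fs,alpha_ssd Thresholds (default 0.02 each).
#' @return `"expansion"` or `"no expansion"` (NA inputs give
#'   `"undetermined"`).
#' @export
expansion_verdict <- function(fs, p_fs, p_ssd,
                              alpha_fs = 0.02, alpha_ssd = 0.02) {
  if (any(is.na(c(fs, p_fs, p_ssd)))) return("undetermined")
  if (fs < 0 && p_fs <= alpha_fs && p_ssd > alpha_ssd) "expansion"
  else "no expansion"
}
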