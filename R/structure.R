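#' AMOVA-based pairwise Fst between two populations
#'
#' Fst from an analysis of molecular variance on the pairwise
#' substitution-difference matrix (Excoffier-Smouse-Quattro): with
#' \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}},
#' \eqn{SS_{within} = \sum_p \frac{1}{n_p}\sum_{i<j \in p} d_{ij}},
#' \eqn{\sigma_b^2 = SS_{within}/(N-2)},
#' \eqn{\bar n = (N - \sum_p n_p^2/N)/(P-1)} and
#' \eqn{\sigma_a^2 = (SS_{among}/(P-1) - \sigma_b^2)/\bar n},
#' \eqn{F_{st} = \sigma_a^2 / (\sigma_a^2 + \sigma_b^2)}. Small negative
#' values are reported as computed, not clipped. Significance is by
#' permutation of individuals between the two populations.
#'
#' @param ds An `mt_dataset`.
#' @param pop_a,pop_b Population labels.
#' @param n_perm Label permutations for the p-value (0 = none).
#' @param seed Optional integer seed.
#' @param dist Optional precomputed [pairwise_diff_matrix()] of `ds`.
#' @return List with `fst` and `p` (`NA` when not permuted, and
#'   `fst = NA` when all sequences are identical).
#' @export
pairwise_fst <- function(ds, pop_a, pop_b, n_perm = 0, seed = NULL,
                         dist = NULL) {
  sub_idx <- which(ds$population %in% c(pop_a, pop_b))
  labels <- ds$population[sub_idx]
  if (sum(labels == pop_a) < 2 || sum(labels == pop_b) < 2) {
    abort("Each population needs at least 2 samples.")
  }
  d <- if (is.null(dist)) {
    sub <- ds[sub_idx, , drop = FALSE]
    attr(sub, "region_set") <- dataset_regions(ds)
    pairwise_diff_matrix(sub)$differences
  } else {
    dist$differences[sub_idx, sub_idx]
  }
  obs <- amova_fst(d, labels)
  p <- NA_real_
  if (n_perm > 0 && !is.na(obs)) {
    p <- with_seed_(seed, {
      perm <- purrr::map_dbl(seq_len(n_perm), function(i) {
        f <- amova_fst(d, sample(labels))
        if (is.na(f)) -Inf else f
      })
      (sum(perm >= obs) + 1) / (n_perm + 1)
    })
  }
  list(fst = obs, p = p)
}

amova_fst <- function(d, labels) {
  N <- length(labels)
  pops <- unique(labels)
  P <- length(pops)
  ut <- upper.tri(d)
  ss_total <- sum(d[ut]) / N
  ss_within <- 0
  n_p <- numeric(P)
  for (i in seq_len(P)) {
    idx <- which(labels == pops[i])
    n_p[i] <- length(idx)
    dp <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dp[upper.tri(dp)]) / n_p[i]
  }
  ss_among <- ss_total - ss_within
  sigma_b <- ss_within / (N - 2)
  n_bar <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ss_among / (P - 1) - sigma_b) / n_bar
  denom <- sigma_a + sigma_b
  if (denom == 0) return(NA_real_)
  sigma_a / denom
}

#' Pairwise Fst matrix over all populations
#'
#' @param ds An `mt_dataset` with at least two populations.
#' @param n_perm Permutations per pair for significance (default 1000;
#'   0 skips).
#' @param seed Optional integer seed.
#' @return An object of class `fst_matrix`: list with `populations`,
#'   `fst` (symmetric matrix, zero diagonal), `p` (permutation
#'   p-values). `tidy()` gives the long pair table with gene flow M.
#' @export
fst_matrix <- function(ds, n_perm = 1000, seed = NULL) {
  pops <- unique(ds$population)
  if (length(pops) < 2) abort("Need at least two populations.")
  dist <- pairwise_diff_matrix(ds)
  fst <- p <- matrix(NA_real_, length(pops), length(pops),
                     dimnames = list(pops, pops))
  diag(fst) <- 0
  with_seed_(seed, {
    for (i in seq_len(length(pops) - 1)) {
      for (j in seq.int(i + 1, length(pops))) {
        r <- pairwise_fst(ds, pops[i], pops[j], n_perm = n_perm, dist = dist)
        fst[i, j] <- fst[j, i] <- r$fst
        p[i, j] <- p[j, i] <- r$p
      }
    }
  })
  structure(list(populations = pops, fst = fst, p = p),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix> ", length(x$populations), " populations\n", sep = "")
  print(round(x$fst, 4))
  invisible(x)
}

#' @rdname fst_matrix
#' @param x An `fst_matrix`.
#' @param ... Unused.
#' @method tidy fst_matrix
#' @export
tidy.fst_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$fst), arr.ind = TRUE)
  tibble(
    pop_a = x$populations[idx[, 1]],
    pop_b = x$populations[idx[, 2]],
    fst = x$fst[idx],
    p = x$p[idx],
    M = gene_flow_m(x$fst[idx])
  )
}

#' Gene flow M = Nem from Fst (haploid island model)
#'
#' Inverts the island-model equilibrium \eqn{F_{st} = 1/(2M + 1)} for a
#' haploid maternally inherited locus: \eqn{M = (1 - F_{st})/(2 F_{st})}.
#' Non-positive Fst maps to `Inf` (unbounded gene flow); Fst of 1 maps
#' to 0.
#'
#' @param fst Numeric vector of Fst values.
#' @return Numeric vector of M values.
#' @export
gene_flow_m <- function(fst) {
  out <- ifelse(fst <= 0, Inf, (1 - fst) / (2 * fst))
  out[!is.na(fst) & fst >= 1] <- 0
  out[is.na(fst)] <- NA_real_
  out
}

#' Classical (metric) MDS of an Fst matrix
#'
#' Double-centers the squared distance matrix and embeds the populations
#' on the top eigenvectors (Torgerson scaling, via [stats::cmdscale()]).
#' Negative Fst entries are floored at 0 before embedding (with a
#' warning); negative eigenvalues are excluded from the coordinates.
#' `stress` is the fraction of total absolute eigenvalue mass not
#' captured by the retained axes.
#'
#' @param x An `fst_matrix` or a symmetric distance matrix with
#'   dimnames.
#' @param dims Number of output dimensions (default 2).
#' @return An object of class `mds_embedding`: list with `populations`,
#'   `coordinates` (tibble `population`, `axis1`, `axis2`, ...),
#'   `eigenvalues`, `stress`.
#' @export
classical_mds <- function(x, dims = 2) {
  d <- if (inherits(x, "fst_matrix")) x$fst else as.matrix(x)
  if (nrow(d) < 3) abort("Need at least 3 populations for MDS.")
  if (any(is.na(d))) {
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- paste(rownames(d)[idx[, 1]], colnames(d)[idx[, 2]],
                   sep = "-", collapse = ", ")
    abort(paste0("Distance matrix has NA entries for pairs: ", pairs))
  }
  if (any(d < 0)) {
    warn("Negative distances floored at 0 for MDS.")
    d[d < 0] <- 0
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < dims) {
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  lambda <- fit$eig
  stress <- 1 - sum(pmax(lambda, 0)[seq_len(dims)]) / sum(abs(lambda))
  coordinates <- as_tibble(coords, .name_repair = \(x) paste0("axis", seq_along(x)))
  coordinates <- bind_cols(tibble(population = rownames(d)), coordinates)
  structure(
    list(populations = rownames(d), coordinates = coordinates,
         eigenvalues = lambda, stress = stress),
    class = "mds_embedding"
  )
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("<mds_embedding> stress = ", signif(x$stress, 3), "\n", sep = "")
  print(x$coordinates)
  invisible(x)
}

#' @rdname classical_mds
#' @param ... Unused.
#' @method tidy mds_embedding
#' @export
tidy.mds_embedding <- function(x, ...) x$coordinates

#' @rdname classical_mds
#' @method glance mds_embedding
#' @export
glance.mds_embedding <- function(x, ...) {
  tibble(
    n_populations = length(x$populations),
    stress = x$stress,
    eig1 = x$eigenvalues[1],
    eig2 = x$eigenvalues[2]
  )
}
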