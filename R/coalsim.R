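#' Demographic model for the coalescent simulator
#'
#' Time is measured in mutational units: one unit is the expected number
#' of substitutions per lineage over the whole region set, so the
#' sudden-expansion time `tau` is directly comparable to the mismatch
#' model's tau. Under `"constant"` the scaled size is `theta0`
#' throughout; under `"sudden_expansion"` the population has size
#' `theta1` from the present back to `tau/2` mutational units, and
#' `theta0` before that (`theta1 = Inf` means no coalescence more
#' recently than the expansion).
#'
#' @param kind `"constant"` or `"sudden_expansion"`.
#' @param theta0 Scaled size (before expansion, or throughout).
#' @param theta1 Scaled size after expansion (may be `Inf`).
#' @param tau Expansion time in mutational units.
#' @return A `demographic_model` list.
#' @export
demographic_model <- function(kind = c("constant", "sudden_expansion"),
                              theta0, theta1 = NULL, tau = NULL) {
  kind <- match.arg(kind)
  if (theta0 < 0) abort("theta0 must be >= 0.")
  if (kind == "sudden_expansion") {
    if (is.null(theta1) || is.null(tau) || theta1 < 0 || tau < 0) {
      abort("sudden_expansion needs theta1 >= 0 and tau >= 0.")
    }
  }
  structure(list(kind = kind, theta0 = theta0, theta1 = theta1, tau = tau),
            class = "demographic_model")
}

theta_at <- function(model, t) {
  if (model$kind == "constant") return(model$theta0)
  if (t < model$tau / 2) model$theta1 else model$theta0
}

# next epoch boundary strictly after time t (Inf when none)
next_boundary <- function(model, t) {
  if (model$kind == "sudden_expansion" && t < model$tau / 2) {
    model$tau / 2
  } else {
    Inf
  }
}

#' Simulate a Kingman coalescent genealogy
#'
#' Coalescence intensity for `k` lineages at time `t` (mutational units
#' before present) is `k (k - 1) / theta(t)`. With `demes` given (an
#' integer vector of deme labels, one per sample) and a `split_time`,
#' lineages coalesce only within their deme until `split_time`, after
#' which all surviving lineages form a single pool — a clean two-deme
#' split with no migration.
#'
#' @param n Number of tips.
#' @param model A [demographic_model()].
#' @param seed Optional integer seed.
#' @param demes Optional deme label per tip (default: one deme).
#' @param split_time Deme merge time (mutational units); required with
#'   `demes`.
#' @return An object of class `mt_genealogy`: list with `n`, `edges`
#'   (tibble `parent`, `child`, `length`), `node_time` (coalescence time
#'   per node; tips are `1..n` at time 0, root is node `2n - 1`) and
#'   `desc` (per-edge tip index sets).
#' @export
simulate_genealogy <- function(n, model, seed = NULL, demes = NULL,
                               split_time = NULL) {
  if (n < 2) abort("Need n >= 2 tips.")
  with_seed_(seed, {
    if (is.null(demes)) demes <- rep(1L, n)
    if (length(demes) != n) abort("`demes` must have one label per tip.")
    if (length(unique(demes)) > 1 && is.null(split_time)) {
      abort("`split_time` is required with more than one deme.")
    }
    split_time <- split_time %||% 0
    active <- seq_len(n)
    deme_of <- as.integer(factor(demes))
    node_time <- numeric(2 * n - 1)
    parent <- child <- integer(2 * (n - 1))
    next_node <- n + 1L
    t <- 0
    e <- 0L
    while (length(active) > 1) {
      merged <- t >= split_time
      groups <- if (merged) list(active) else split(active, deme_of[active])
      ks <- purrr::map_int(groups, length)
      th <- theta_at(model, t)
      rate <- sum(ks * (ks - 1)) / th
      bnd <- min(next_boundary(model, t),
                 if (!merged) split_time else Inf)
      if (rate == 0) {
        if (is.infinite(bnd)) abort("Coalescent cannot proceed (rate 0).")
        t <- bnd
        next
      }
      dt <- stats::rexp(1, rate)
      if (t + dt > bnd) {
        t <- bnd
        next
      }
      t <- t + dt
      # choose a group proportionally to its pair count, then a pair
      w <- ks * (ks - 1)
      g <- groups[[sample.int(length(groups), 1, prob = w)]]
      pair <- sample(g, 2)
      node_time[next_node] <- t
      for (c_ in pair) {
        e <- e + 1L
        parent[e] <- next_node
        child[e] <- c_
      }
      deme_of[next_node] <- deme_of[pair[1]]
      active <- c(setdiff(active, pair), next_node)
      next_node <- next_node + 1L
    }
    edges <- tibble(
      parent = parent, child = child,
      length = node_time[parent] - node_time[child]
    )
    structure(
      list(n = n, edges = edges, node_time = node_time,
           desc = edge_descendants(n, edges)),
      class = "mt_genealogy"
    )
  })
}

# tip index set below each edge's child node
edge_descendants <- function(n, edges) {
  n_nodes <- 2 * n - 1
  below <- vector("list", n_nodes)
  for (i in seq_len(n)) below[[i]] <- i
  # children appear before parents because internal ids increase with time
  for (v in seq.int(n + 1, n_nodes)) {
    kids <- edges$child[edges$parent == v]
    below[[v]] <- sort(unlist(below[kids]))
  }
  purrr::map(seq_len(nrow(edges)), \(i) below[[edges$child[i]]])
}

#' Convert a simulated genealogy to an ape `phylo`
#' @param gen An `mt_genealogy`.
#' @param lengths `"time"` (mutational-unit branch lengths) or a numeric
#'   vector of per-edge values (e.g. mutation counts) in edge order.
#' @return A rooted `phylo`.
#' @export
genealogy_to_phylo <- function(gen, lengths = "time") {
  n <- gen$n
  # ape wants internal ids n+1..2n-1 with root = n+1; ours has root 2n-1
  remap <- c(seq_len(n), rev(seq.int(n + 1, 2 * n - 1)))
  edge <- cbind(remap[gen$edges$parent], remap[gen$edges$child])
  len <- if (identical(lengths, "time")) gen$edges$length else lengths
  phy <- list(edge = edge, edge.length = as.numeric(len),
              Nnode = n - 1L, tip.label = paste0("t", seq_len(n)))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# default per-region per-site substitution rates: HVS-I-like windows
# (start >= 16000) evolve at 1.602e-7 subs/site/yr, coding windows at
# 3.42e-8 — the calibration used throughout the package
default_region_rates <- function(region_set) {
  ifelse(region_set$regions$start >= 16000, 1.602e-7, 3.42e-8)
}

#' Drop mutations onto a genealogy (infinite sites on rCRS positions)
#'
#' Each edge receives `Poisson(length)` mutations (edge lengths are in
#' mutational units, i.e. expected substitutions per lineage). Every
#' mutation is assigned to a region with probability proportional to
#' `rate * region length`, then to a previously unused position within
#' that region, and a derived base drawn uniformly from the three
#' non-reference bases.
#'
#' @param gen An `mt_genealogy`.
#' @param region_set A [region_set()].
#' @param rates Per-region per-site relative rates (default:
#'   HVS-I-fast/coding-slow, see [simulate_dataset()]).
#' @param reference Reference bases as in [read_profiles()]; default a
#'   seeded synthetic reference.
#' @param seed Optional integer seed.
#' @return A list: `profiles` tibble (`sample_id`, `variants`,
#'   `missing`), `reference` (concatenated string), `mutations` tibble
#'   (`edge`, `position`, `base`).
#' @export
drop_mutations <- function(gen, region_set, rates = NULL,
                           reference = NULL, seed = NULL) {
  stopifnot_region_set(region_set)
  rates <- rates %||% default_region_rates(region_set)
  if (length(rates) != nrow(region_set$regions)) {
    abort("Need one rate per region.")
  }
  with_seed_(seed, {
    ref <- if (is.null(reference)) {
      paste(sample(c("A", "C", "G", "T"), region_set$total_length,
                   replace = TRUE), collapse = "")
    } else reference
    ref_bases <- reference_bases(ref, region_set)
    share <- rates * region_set$regions$length
    if (sum(share) <= 0) abort("All region rates are zero.")
    share <- share / sum(share)
    pool <- purrr::map2(region_set$regions$start, region_set$regions$end,
                        seq.int)
    m_l <- stats::rpois(nrow(gen$edges), gen$edges$length)
    mut <- list()
    for (e in which(m_l > 0)) {
      for (j in seq_len(m_l[e])) {
        r <- sample.int(length(pool), 1, prob = share)
        if (length(pool[[r]]) == 0) {
          abort("Region positions exhausted; lower theta or widen regions.")
        }
        pos <- pool[[r]][sample.int(length(pool[[r]]), 1)]
        pool[[r]] <- setdiff(pool[[r]], pos)
        base <- sample(setdiff(c("A", "C", "G", "T"),
                               ref_bases[[as.character(pos)]]), 1)
        mut[[length(mut) + 1]] <- list(edge = e, position = pos, base = base)
      }
    }
    mutations <- if (length(mut)) {
      tibble(edge = purrr::map_int(mut, \(x) as.integer(x$edge)),
             position = purrr::map_int(mut, \(x) as.integer(x$position)),
             base = purrr::map_chr(mut, "base"))
    } else {
      tibble(edge = integer(0), position = integer(0), base = character(0))
    }
    profiles <- purrr::map(seq_len(gen$n), function(i) {
      carries <- mutations$edge %in%
        which(purrr::map_lgl(gen$desc, \(d) i %in% d))
      v <- stats::setNames(mutations$base[carries],
                           as.character(mutations$position[carries]))
      canonical_variants(v)
    })
    list(
      profiles = tibble(
        sample_id = paste0("s", seq_len(gen$n)),
        variants = profiles,
        missing = purrr::map(seq_len(gen$n), \(i) integer(0))
      ),
      reference = ref,
      mutations = mutations
    )
  })
}

#' Simulate a complete dataset with ground truth
#'
#' End-to-end synthetic data: a seeded coalescent genealogy under the
#' requested demography (optionally a clean two-deme split), mutations
#' dropped region-proportionally under the infinite-sites approximation,
#' and the resulting variant profiles packaged as an [mt_dataset()]. The
#' defaults emulate the partial-genome design the package targets: the
#' 2450-site statistics window with the HVS-I window mutating roughly
#' 4.7x faster per site than the coding windows.
#'
#' @param n Named integer vector of samples per population (one or two
#'   populations).
#' @param model A [demographic_model()].
#' @param region_set Region set (default [stat_regions()]).
#' @param rates Per-region per-site relative rates.
#' @param split_time Two-deme split time in mutational units (required
#'   for two populations).
#' @param reference Optional reference bases; default synthetic.
#' @param seed Optional integer seed.
#' @return A list: `dataset` (an `mt_dataset`), `genealogy`
#'   (`mt_genealogy`), `reference`, `truth` (model, split time, seed).
#' @export
simulate_dataset <- function(n, model, region_set = stat_regions(),
                             rates = NULL, split_time = NULL,
                             reference = NULL, seed = NULL) {
  if (is.null(names(n))) names(n) <- paste0("pop", seq_along(n))
  if (length(n) > 2) abort("At most two populations are supported.")
  with_seed_(seed, {
    demes <- rep(seq_along(n), n)
    gen <- simulate_genealogy(sum(n), model, demes = demes,
                              split_time = if (length(n) > 1) split_time else NULL)
    dm <- drop_mutations(gen, region_set, rates, reference)
    ds <- mt_dataset(
      dm$profiles,
      stats::setNames(rep(names(n), n), dm$profiles$sample_id),
      region_set
    )
    list(dataset = ds, genealogy = gen, reference = dm$reference,
         truth = list(model = model, split_time = split_time, seed = seed))
  })
}

#' Fast summary statistics of one coalescent replicate
#'
#' Simulates a genealogy plus per-edge Poisson mutation counts and
#' returns the summary statistics needed by null distributions and
#' bootstraps without materialising sequences: segregating sites `S`,
#' mean pairwise differences `MNPd`, haplotype count `k`, and (when
#' `want_diffs`) the full pairwise-difference matrix.
#'
#' @param n Sample size.
#' @param model A [demographic_model()] (or compatible list).
#' @param want_diffs Return the pairwise difference matrix?
#' @return List with `S`, `MNPd`, `k` and optionally `diffs`.
#' @export
sim_summary_stats <- function(n, model, want_diffs = FALSE) {
  if (!inherits(model, "demographic_model")) {
    model <- do.call(demographic_model, model)
  }
  gen <- simulate_genealogy(n, model)
  m_l <- stats::rpois(nrow(gen$edges), gen$edges$length)
  mutated <- which(m_l > 0)
  S <- sum(m_l)
  # each mutation on an edge with a descendant tips separates a*(n-a) pairs
  a <- purrr::map_int(gen$desc, length)
  n_pairs <- n * (n - 1) / 2
  MNPd <- sum(m_l[mutated] * a[mutated] * (n - a[mutated])) / n_pairs
  hap_key <- rep("", n)
  for (e in mutated) {
    d <- gen$desc[[e]]
    hap_key[d] <- paste(hap_key[d], e)
  }
  out <- list(S = S, MNPd = MNPd, k = length(unique(hap_key)))
  if (want_diffs) {
    D <- matrix(0, n, n)
    for (e in mutated) {
      d <- gen$desc[[e]]
      D[d, -d] <- D[d, -d] + m_l[e]
    }
    out$diffs <- D + t(D)
  }
  out
}
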