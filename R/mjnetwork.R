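#' Minimum spanning network of haplotypes
#'
#' The union of all minimum spanning trees: an edge belongs to the MSN
#' exactly when its weight equals the minimax path weight between its
#' endpoints. Computed Kruskal-style, adding at each distinct weight
#' level every edge that joins two still-separate components before
#' merging them.
#'
#' @param labels Haplotype identifiers (ordered; ties in construction
#'   are broken by this order).
#' @param d Symmetric non-negative distance matrix.
#' @return A tibble of edges: `from`, `to`, `weight`.
#' @export
minimum_spanning_network <- function(labels, d) {
  n <- length(labels)
  if (n == 1) return(tibble(from = character(0), to = character(0),
                            weight = numeric(0)))
  comp <- seq_len(n)
  edges <- list()
  for (w in sort(unique(d[upper.tri(d)]))) {
    idx <- which(d == w & upper.tri(d), arr.ind = TRUE)
    # keep edges bridging distinct components at this level
    keep <- comp[idx[, 1]] != comp[idx[, 2]]
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx)) {
      edges[[length(edges) + 1]] <- tibble(
        from = labels[idx[, 1]], to = labels[idx[, 2]], weight = w
      )
      for (r in seq_len(nrow(idx))) {
        ci <- comp[idx[r, 1]]
        cj <- comp[idx[r, 2]]
        if (ci != cj) comp[comp == cj] <- ci
      }
    }
    if (length(unique(comp)) == 1) break
  }
  bind_rows(edges) |> arrange(.data$weight, .data$from, .data$to)
}

# hamming distance between rows of a character matrix
hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  d
}

# total weight of a minimum spanning tree over rows of allele matrix
mst_cost <- function(d) {
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}

#' Median-joining haplotype network
#'
#' Bandelt's algorithm on binary-encoded variant presence: iteratively
#' build the minimum spanning network, propose for every linked triple
#' the per-position majority (median) haplotype — ties at a position
#' keep the ancestral (reference) state — add median vectors that reduce
#' the total spanning cost (within `epsilon`), prune medians that no
#' longer contribute, and stop at a fixpoint. With `epsilon = 0` (the
#' standard choice for mtDNA) only cost-reducing medians survive. All
#' positions carry equal weight.
#'
#' @param ds An `mt_dataset`, or a character allele matrix (rows =
#'   haplotypes, columns = positions, `"."` = ancestral state) with row
#'   names.
#' @param epsilon Relaxation parameter (default 0).
#' @param max_iter Safety cap on outer iterations.
#' @return An object of class `haplotype_network`: list with `nodes`
#'   (tibble `id`, `type` observed/median, per-population counts),
#'   `edges` (tibble `from`, `to`, `weight`), `alleles` (final matrix).
#' @export
median_joining <- function(ds, epsilon = 0, max_iter = 25) {
  enc <- encode_haplotypes(ds)
  mat <- enc$matrix
  if (nrow(mat) > 5000) abort("More than 5000 haplotypes: refusing.")
  observed <- rownames(mat)
  repeat {
    max_iter <- max_iter - 1
    d <- hamming_matrix(mat)
    msn <- minimum_spanning_network(rownames(mat), d)
    cand <- median_candidates(mat, msn)
    if (nrow(mat) >= 2) {
      base_cost <- mst_cost(d)
      added <- character(0)
      for (key in rownames(cand)) {
        if (key %in% rownames(mat)) next
        trial <- rbind(mat, cand[key, , drop = FALSE])
        if (mst_cost(hamming_matrix(trial)) < base_cost + epsilon) {
          mat <- trial
          base_cost <- mst_cost(hamming_matrix(mat))
          added <- c(added, key)
        }
      }
    } else added <- character(0)
    # prune medians whose removal leaves the spanning cost unchanged
    pruned <- TRUE
    while (pruned) {
      pruned <- FALSE
      medians <- setdiff(rownames(mat), observed)
      for (key in medians) {
        rest <- mat[setdiff(rownames(mat), key), , drop = FALSE]
        if (nrow(rest) >= 1 &&
            (nrow(rest) == 1 ||
             mst_cost(hamming_matrix(rest)) <=
               mst_cost(hamming_matrix(mat)))) {
          mat <- rest
          pruned <- TRUE
        }
      }
    }
    if (length(added) == 0 || max_iter <= 0) break
  }
  d <- hamming_matrix(mat)
  edges <- minimum_spanning_network(rownames(mat), d)
  counts <- enc$counts
  nodes <- tibble(
    id = rownames(mat),
    type = ifelse(rownames(mat) %in% observed, "observed", "median")
  )
  if (!is.null(counts)) {
    nodes <- left_join(nodes, counts, by = "id") |>
      mutate(across(where(is.numeric), \(v) tidyr::replace_na(v, 0L)))
  }
  structure(list(nodes = nodes, edges = edges, alleles = mat),
            class = "haplotype_network")
}

# encode dataset (or matrix) as allele matrix over variant positions,
# "." = ancestral/reference; duplicate haplotypes collapse with counts
encode_haplotypes <- function(ds) {
  if (is.matrix(ds)) {
    if (is.null(rownames(ds))) abort("Allele matrix needs row names.")
    return(list(matrix = ds, counts = NULL))
  }
  haps <- collapse_haplotypes(ds)
  counts <- haps |>
    tidyr::pivot_wider(names_from = "population", values_from = "n",
                       values_fill = 0L) |>
    rename(id = "haplotype")
  keys <- unique(haps$haplotype)
  pos_all <- sort(unique(unlist(purrr::map(ds$variants,
                                           \(v) as.integer(names(v))))))
  mat <- matrix(".", nrow = length(keys), ncol = length(pos_all),
                dimnames = list(keys, as.character(pos_all)))
  key_of <- purrr::map_chr(ds$variants, haplotype_key)
  for (k in keys) {
    v <- ds$variants[[match(k, key_of)]]
    if (length(v)) mat[k, names(v)] <- v
  }
  list(matrix = mat, counts = counts)
}

# majority-state medians of all MSN-linked triples, tie -> ancestral "."
median_candidates <- function(mat, msn) {
  out <- list()
  if (nrow(msn) == 0) {
    return(matrix(character(0), 0, ncol(mat),
                  dimnames = list(NULL, colnames(mat))))
  }
  nodes <- rownames(mat)
  adj <- purrr::map(nodes, function(u) {
    unique(c(msn$to[msn$from == u], msn$from[msn$to == u]))
  })
  names(adj) <- nodes
  seen <- character(0)
  for (v in nodes) {
    nb <- adj[[v]]
    if (length(nb) < 2) next
    pairs <- utils::combn(sort(nb), 2)
    for (c_ in seq_len(ncol(pairs))) {
      trip <- sort(c(v, pairs[1, c_], pairs[2, c_]))
      tag <- paste(trip, collapse = "|")
      if (tag %in% seen) next
      seen <- c(seen, tag)
      rows <- mat[trip, , drop = FALSE]
      med <- apply(rows, 2, function(col) {
        tb <- table(col)
        if (max(tb) >= 2) names(tb)[which.max(tb)] else "."
      })
      out[[tag]] <- med
    }
  }
  if (length(out) == 0) {
    return(matrix(character(0), 0, ncol(mat),
                  dimnames = list(NULL, colnames(mat))))
  }
  m <- do.call(rbind, out)
  rownames(m) <- apply(m, 1, median_key)
  colnames(m) <- colnames(mat)
  m[!duplicated(rownames(m)), , drop = FALSE]
}

median_key <- function(row) {
  on <- row != "."
  if (!any(on)) return("rCRS")
  paste0(names(row)[on], row[on], collapse = "/")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$type == "median"), " medians), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @rdname median_joining
#' @param x A `haplotype_network`.
#' @param ... Unused.
#' @method tidy haplotype_network
#' @export
tidy.haplotype_network <- function(x, ...) x$edges

#' Export a haplotype network to node/edge TSV files
#' @param net A `haplotype_network`.
#' @param prefix Output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @return The two paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  nodes_path <- paste0(prefix, "_nodes.tsv")
  edges_path <- paste0(prefix, "_edges.tsv")
  readr::write_tsv(net$nodes, nodes_path)
  readr::write_tsv(net$edges, edges_path)
  invisible(c(nodes_path, edges_path))
}
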