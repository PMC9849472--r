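# shared toy-data builders; every stochastic test sets its own seed

toy_regions <- function() region_set(1, 1000)

# profiles from a list of named character vectors (position -> base)
toy_dataset <- function(variant_sets, populations,
                        missing = NULL, rs = toy_regions()) {
  n <- length(variant_sets)
  missing <- missing %||% purrr::map(seq_len(n), \(i) integer(0))
  profiles <- tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    variants = purrr::map(variant_sets, \(v) {
      if (length(v) == 0) stats::setNames(character(0), character(0)) else v
    }),
    missing = missing
  )
  mt_dataset(profiles,
             stats::setNames(populations, profiles$sample_id), rs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random A/C/G/T reference over a region set
random_reference <- function(rs) {
  paste(sample(c("A", "C", "G", "T"), rs$total_length, replace = TRUE),
        collapse = "")
}

# one draw of the allele-count K under the Ewens sampling formula via the
# Chinese restaurant process -- the brute-force oracle for Fu's Fs
crp_k <- function(n, theta) {
  k <- 1L
  for (i in seq_len(n - 1)) {
    if (stats::runif(1) < theta / (theta + i)) k <- k + 1L
  }
  k
}

# a small haplogroup tree table written to a temp file
write_toy_tree_table <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(rows, path)
  path
}

# total edge weight of a network's minimum spanning tree
network_mst_cost <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$id)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}
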