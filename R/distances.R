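#' Pairwise sequence differences between two profiles
#'
#' Counts substitution differences over the sites callable in both
#' samples (pairwise deletion): a site missing in either sample is
#' excluded from both the difference count and the compared-site count.
#'
#' @param a,b One-row slices of an `mt_dataset`/profile tibble, or lists
#'   with elements `variants` and `missing`.
#' @param region_set The shared [region_set()].
#' @return A list with `differences` and `compared_sites`.
#' @export
pairwise_differences <- function(a, b, region_set) {
  stopifnot_region_set(region_set)
  a <- as_profile(a)
  b <- as_profile(b)
  excluded <- union(a$missing, b$missing)
  pos <- union(as.integer(names(a$variants)), as.integer(names(b$variants)))
  pos <- setdiff(pos, excluded)
  key <- as.character(pos)
  base_a <- ifelse(key %in% names(a$variants), a$variants[key], "")
  base_b <- ifelse(key %in% names(b$variants), b$variants[key], "")
  list(
    differences = sum(base_a != base_b),
    compared_sites = region_set$total_length - length(excluded)
  )
}

as_profile <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("Expected a single profile (one row).")
    list(variants = x$variants[[1]], missing = x$missing[[1]])
  } else {
    list(variants = x$variants, missing = x$missing)
  }
}

#' All pairwise differences within a dataset
#'
#' @param ds An `mt_dataset`.
#' @return An object of class `mt_distances`: list with `labels`,
#'   `differences` (symmetric count matrix) and `compared_sites`
#'   (symmetric matrix of callable sites per pair). `tidy()` returns the
#'   long pair table.
#' @export
pairwise_diff_matrix <- function(ds) {
  rs <- dataset_regions(ds)
  n <- nrow(ds)
  # allele matrix over the union of variant positions; "" = reference
  pos_all <- sort(unique(unlist(purrr::map(ds$variants,
                                           \(v) as.integer(names(v))))))
  key <- as.character(pos_all)
  allele <- matrix("", nrow = n, ncol = length(pos_all),
                   dimnames = list(ds$sample_id, key))
  for (i in seq_len(n)) {
    v <- ds$variants[[i]]
    if (length(v)) allele[i, names(v)] <- v
    m <- intersect(ds$missing[[i]], pos_all)
    if (length(m)) allele[i, as.character(m)] <- NA_character_
  }
  d <- matrix(0L, n, n, dimnames = list(ds$sample_id, ds$sample_id))
  cs <- matrix(rs$total_length, n, n,
               dimnames = list(ds$sample_id, ds$sample_id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        d[i, j] <- d[j, i] <-
          sum(allele[i, ] != allele[j, ], na.rm = TRUE)
        n_excl <- length(union(ds$missing[[i]], ds$missing[[j]]))
        cs[i, j] <- cs[j, i] <- rs$total_length - n_excl
      }
    }
  }
  diag(cs) <- rs$total_length - purrr::map_int(ds$missing, length)
  structure(list(labels = ds$sample_id, differences = d,
                 compared_sites = cs),
            class = "mt_distances")
}

#' @export
print.mt_distances <- function(x, ...) {
  cat("<mt_distances> ", length(x$labels), " samples\n", sep = "")
  invisible(x)
}

#' @rdname pairwise_diff_matrix
#' @param x An `mt_distances` object.
#' @param ... Unused.
#' @method tidy mt_distances
#' @export
tidy.mt_distances <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$differences), arr.ind = TRUE)
  tibble(
    sample_i = x$labels[idx[, 1]],
    sample_j = x$labels[idx[, 2]],
    differences = x$differences[idx],
    compared_sites = x$compared_sites[idx]
  )
}

#' Haplotype key of a variant set
#'
#' Canonical slash-joined representation, e.g. `"8281C/16223T"`; the
#' reference-identical haplotype is `"rCRS"`.
#'
#' @param variants Named character vector (position -> derived base).
#' @return A single string.
#' @export
haplotype_key <- function(variants) {
  if (length(variants) == 0) return("rCRS")
  pos <- as.integer(names(variants))
  o <- order(pos)
  paste0(pos[o], variants[o], collapse = "/")
}

#' Collapse samples into haplotypes
#'
#' Haplotype identity is exact equality of the variant set (missing
#' positions excluded), so two samples sharing all called substitutions
#' collapse into one haplotype.
#'
#' @param ds An `mt_dataset`.
#' @return A tibble with columns `haplotype`, `population`, `n`
#'   (per-population counts; `sum(n)` equals the number of samples).
#' @export
collapse_haplotypes <- function(ds) {
  tibble(
    haplotype = purrr::map_chr(ds$variants, haplotype_key),
    population = ds$population
  ) |>
    count(.data$haplotype, .data$population, name = "n") |>
    arrange(.data$haplotype, .data$population)
}

#' Haplotype counts of one population
#' @param ds An `mt_dataset`.
#' @param population Population label; default pools all samples.
#' @return Integer vector of haplotype counts.
#' @export
haplotype_counts <- function(ds, population = NULL) {
  if (!is.null(population)) ds <- ds[ds$population %in% population, ]
  keys <- purrr::map_chr(ds$variants, haplotype_key)
  as.integer(table(keys))
}
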