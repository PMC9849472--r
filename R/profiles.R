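#' Build a population dataset of rCRS-relative variant profiles
#'
#' The central data container. Each sample is stored as its set of
#' substitutions relative to the reference (a named character vector,
#' names = rCRS positions, values = derived base) plus a set of positions
#' with missing/ambiguous calls. Insertions, deletions and heteroplasmies
#' are outside the data model: every analysed difference is a base
#' substitution at an aligned rCRS position.
#'
#' @param profiles A tibble/data frame with columns `sample_id`,
#'   `variants` (list of named character vectors) and `missing` (list of
#'   integer vectors).
#' @param populations Either a named character vector
#'   (`sample_id -> population`) or a two-column data frame
#'   (`sample_id`, `population`).
#' @param region_set A [region_set()]; every variant or missing position
#'   must fall inside it.
#' @return A tibble of class `mt_dataset` with columns `sample_id`,
#'   `population`, `variants`, `missing`, carrying the region set as an
#'   attribute (retrieve with [dataset_regions()]).
#' @export
mt_dataset <- function(profiles, populations, region_set) {
  stopifnot_region_set(region_set)
  profiles <- as_tibble(profiles)
  if (!all(c("sample_id", "variants", "missing") %in% names(profiles))) {
    abort("`profiles` needs columns sample_id, variants, missing.")
  }
  if (is.data.frame(populations)) {
    pops <- stats::setNames(as.character(populations$population),
                            populations$sample_id)
  } else {
    pops <- populations
  }
  missing_pop <- setdiff(profiles$sample_id, names(pops))
  if (length(missing_pop) > 0) {
    abort(paste0("No population label for sample(s): ",
                 paste(utils::head(missing_pop, 5), collapse = ", ")))
  }
  out <- profiles |>
    mutate(
      population = unname(pops[.data$sample_id]),
      variants = purrr::map(.data$variants, canonical_variants),
      missing = purrr::map(.data$missing, \(m) sort(unique(as.integer(m))))
    ) |>
    select("sample_id", "population", "variants", "missing")
  purrr::pwalk(out, function(sample_id, population, variants, missing) {
    pos <- as.integer(names(variants))
    if (length(pos) && !all(in_regions(pos, region_set))) {
      abort(paste0("Sample ", sample_id, ": variant outside region set."))
    }
    if (length(missing) && !all(in_regions(missing, region_set))) {
      abort(paste0("Sample ", sample_id, ": missing site outside region set."))
    }
    if (length(intersect(pos, missing)) > 0) {
      abort(paste0("Sample ", sample_id, ": position both variant and missing."))
    }
  })
  attr(out, "region_set") <- region_set
  class(out) <- c("mt_dataset", class(out))
  out
}

canonical_variants <- function(v) {
  if (length(v) == 0) return(stats::setNames(character(0), character(0)))
  pos <- as.integer(names(v))
  if (anyDuplicated(pos)) abort("Duplicate variant position in a profile.")
  v <- toupper(as.character(v))
  if (!all(v %in% c("A", "C", "G", "T"))) {
    abort("Derived bases must be A, C, G or T.")
  }
  stats::setNames(v, as.character(pos))[order(pos)]
}

#' Region set attached to a dataset
#' @param ds An `mt_dataset`.
#' @return The [region_set()] the dataset was built against.
#' @export
dataset_regions <- function(ds) {
  rs <- attr(ds, "region_set")
  if (is.null(rs)) abort("Dataset has lost its region_set attribute.")
  rs
}

#' Read aligned mtDNA sequences into variant profiles
#'
#' Sequences must already be aligned to rCRS coordinates. Three record
#' layouts are accepted: a full-length 16569-base alignment; a
#' concatenation of the region set's windows in ascending order (length =
#' `region_set$total_length`); or a single-region record whose header
#' carries a `region=start-end` token. Bases equal to the reference yield
#' no variant; IUPAC ambiguity codes, `N` and gaps are recorded as
#' missing.
#'
#' @param path FASTA file of sample sequences.
#' @param region_set A [region_set()] delimiting the analysed windows.
#' @param reference Reference sequence: a path to a FASTA file or a
#'   character string, either full-length (16569) or concatenated to the
#'   region set.
#' @return A tibble with columns `sample_id`, `variants`, `missing`
#'   (profile tibble; combine with labels via [mt_dataset()]).
#' @export
read_profiles <- function(path, region_set, reference) {
  stopifnot_region_set(region_set)
  ref <- reference_bases(reference, region_set)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  profiles <- purrr::map2(
    as.character(seqs), names(seqs),
    \(s, hdr) profile_from_sequence(s, hdr, region_set, ref)
  )
  tibble(
    sample_id = ids,
    variants = purrr::map(profiles, "variants"),
    missing = purrr::map(profiles, "missing")
  )
}

# reference as named character vector base-per-position over the region set
reference_bases <- function(reference, region_set) {
  if (length(reference) == 1 && file.exists(reference)) {
    reference <- as.character(Biostrings::readDNAStringSet(reference)[[1]])
  }
  reference <- toupper(reference)
  pos <- region_positions(region_set)
  n <- nchar(reference)
  if (n == 16569L) {
    bases <- substring(reference, pos, pos)
  } else if (n == region_set$total_length) {
    bases <- substring(reference, seq_along(pos), seq_along(pos))
  } else {
    abort("Reference length matches neither 16569 nor the region set.")
  }
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    abort("Reference must be unambiguous A/C/G/T over the region set.")
  }
  stats::setNames(bases, as.character(pos))
}

profile_from_sequence <- function(s, header, region_set, ref) {
  s <- toupper(s)
  pos_all <- as.integer(names(ref))
  n <- nchar(s)
  region_tok <- regmatches(header, regexpr("region=\\d+-\\d+", header))
  if (n == 16569L) {
    pos <- pos_all
    obs <- substring(s, pos, pos)
  } else if (n == region_set$total_length) {
    pos <- pos_all
    obs <- substring(s, seq_along(pos), seq_along(pos))
  } else if (length(region_tok) == 1) {
    b <- as.integer(strsplit(sub("region=", "", region_tok), "-")[[1]])
    if (n != b[2] - b[1] + 1) {
      abort(paste0("Record '", header, "': length ", n,
                   " inconsistent with declared region ", region_tok, "."))
    }
    pos <- seq.int(b[1], b[2])
    keep <- in_regions(pos, region_set)
    pos <- pos[keep]
    obs <- substring(s, which(keep), which(keep))
  } else {
    abort(paste0("Record '", header, "': length ", n,
                 " matches neither 16569, the region set (",
                 region_set$total_length, "), nor a declared region."))
  }
  ref_here <- ref[as.character(pos)]
  is_base <- obs %in% c("A", "C", "G", "T")
  miss <- pos[!is_base]
  diff <- is_base & obs != ref_here
  list(
    variants = stats::setNames(obs[diff], as.character(pos[diff])),
    missing = as.integer(miss)
  )
}

#' Write variant profiles back to FASTA
#'
#' Reconstructs each sample as the concatenation of the region set's
#' windows (reference base where no variant, `N` at missing sites) and
#' writes a FASTA file. Inverse of [read_profiles()] up to case.
#'
#' @param ds An `mt_dataset` (or profile tibble with a `region_set`
#'   argument supplied).
#' @param path Output FASTA path.
#' @param reference As in [read_profiles()].
#' @param region_set Region set; defaults to the dataset's own.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(ds, path, reference, region_set = NULL) {
  rs <- region_set %||% dataset_regions(ds)
  ref <- reference_bases(reference, rs)
  seqs <- purrr::map2_chr(ds$variants, ds$missing, function(v, m) {
    bases <- ref
    if (length(v)) bases[names(v)] <- v
    if (length(m)) bases[as.character(m)] <- "N"
    paste(bases, collapse = "")
  })
  x <- Biostrings::DNAStringSet(stats::setNames(seqs, ds$sample_id))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a sample-to-population table
#'
#' @param path Two-column TSV `sample_id<TAB>population`, no header
#'   required (a header line `sample_id\tpopulation` is tolerated).
#' @return A tibble with columns `sample_id`, `population`.
#' @export
read_pop_table <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("sample_id", "population"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tab) && tab$sample_id[1] == "sample_id") tab <- tab[-1, ]
  tab
}
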