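#' Define a set of rCRS coordinate regions
#'
#' A region set is the coordinate frame for every analysis in the package:
#' variant positions must fall inside it and its total length is the `L`
#' used by per-site statistics such as nucleotide diversity. Coordinates
#' are 1-based inclusive positions on the revised Cambridge Reference
#' Sequence (rCRS, positions 1-16569).
#'
#' @param start,end Integer vectors of equal length: 1-based inclusive
#'   bounds of each region.
#' @return An object of class `region_set`: a list with a `regions` tibble
#'   (`start`, `end`, `length`) sorted by start, and `total_length`.
#' @examples
#' stat_regions()          # 8001-9000, 9801-10900, 16051-16400 (L = 2450)
#' region_set(16001, 16569)
#' @export
region_set <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end) || length(start) == 0) {
    abort("`start` and `end` must be non-empty vectors of equal length.")
  }
  if (any(is.na(start)) || any(is.na(end)) || any(end < start) || any(start < 1)) {
    abort("Region bounds must satisfy 1 <= start <= end.")
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  if (length(start) > 1 && any(start[-1] <= end[-length(end)])) {
    abort("Regions must be non-overlapping.")
  }
  regions <- tibble(start = start, end = end, length = end - start + 1L)
  structure(
    list(regions = regions, total_length = sum(regions$length)),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", nrow(x$regions), " region(s), total ",
      x$total_length, " sites\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' Default region sets for partial mtDNA genomes
#'
#' `stat_regions()` is the window used for the diversity, structure,
#' mismatch and network statistics: coding regions 8001-9000 and
#' 9801-10900 plus HVS-I 16051-16400 (2450 sites). `screened_regions()`
#' is the wider sequencing window (HVS-I 16001-16569) from which the
#' statistics window is cut.
#'
#' @return A `region_set`.
#' @export
stat_regions <- function() {
  region_set(c(8001L, 9801L, 16051L), c(9000L, 10900L, 16400L))
}

#' @rdname stat_regions
#' @export
screened_regions <- function() {
  region_set(c(8001L, 9801L, 16001L), c(9000L, 10900L, 16569L))
}

# all positions of a region set, ascending
region_positions <- function(rs) {
  unlist(purrr::map2(rs$regions$start, rs$regions$end, seq.int),
         use.names = FALSE)
}

# membership test for rCRS positions
in_regions <- function(pos, rs) {
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(rs$regions))) {
    out <- out | (pos >= rs$regions$start[i] & pos <= rs$regions$end[i])
  }
  out
}

stopifnot_region_set <- function(rs) {
  if (!inherits(rs, "region_set")) abort("Expected a `region_set` object.")
  rs
}
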