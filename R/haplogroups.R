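#' Load a haplogroup tree table
#'
#' The tree table is a simplified stand-in for a full mtDNA phylogeny
#' database: one row per haplogroup with its parent and its defining
#' variants. Variants are written `<pos><BASE>` (e.g. `16223T`); a
#' trailing `!` marks a back-mutation, which removes the corresponding
#' expectation inherited from an ancestor.
#'
#' @param path TSV with columns `name<TAB>parent<TAB>variants`
#'   (space-separated variant tokens; the root row has an empty parent
#'   and may have no variants). A header row is tolerated.
#' @return An object of class `haplogroup_tree`: list with `nodes`
#'   tibble (`name`, `parent`, `variants` list-column of tibbles
#'   `position`, `base`, `back`) and `root`.
#' @export
read_tree_table <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && identical(tolower(parts[[1]][1]), "name")) {
    parts <- parts[-1]
  }
  rows <- purrr::imap(parts, function(p, i) {
    if (length(p) < 2) {
      abort(paste0("Tree table row ", i, ": expected name<TAB>parent."))
    }
    list(name = trimws(p[1]), parent = trimws(p[2]),
         variants = parse_variant_tokens(if (length(p) >= 3) p[3] else "", i))
  })
  nodes <- tibble(
    name = purrr::map_chr(rows, "name"),
    parent = purrr::map_chr(rows, "parent"),
    variants = purrr::map(rows, "variants")
  )
  if (anyDuplicated(nodes$name)) {
    abort(paste0("Duplicate haplogroup name in row ",
                 which(duplicated(nodes$name))[1], "."))
  }
  root <- nodes$name[nodes$parent == ""]
  if (length(root) != 1) {
    abort("Tree table must contain exactly one root row (empty parent).")
  }
  bad <- which(nodes$parent != "" & !(nodes$parent %in% nodes$name))
  if (length(bad)) {
    abort(paste0("Row ", bad[1], " ('", nodes$name[bad[1]],
                 "'): unknown parent '", nodes$parent[bad[1]], "'."))
  }
  # cycle check by walking each node to the root
  for (i in seq_len(nrow(nodes))) {
    seen <- character(0)
    cur <- nodes$name[i]
    while (cur != root) {
      if (cur %in% seen) abort(paste0("Cycle involving '", cur, "'."))
      seen <- c(seen, cur)
      cur <- nodes$parent[match(cur, nodes$name)]
    }
  }
  structure(list(nodes = nodes, root = root), class = "haplogroup_tree")
}

parse_variant_tokens <- function(s, row) {
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) {
    return(tibble(position = integer(0), base = character(0),
                  back = logical(0)))
  }
  m <- regmatches(toks, regexec("^(\\d+)([ACGTacgt])(!?)$", toks))
  bad <- purrr::map_int(m, length) != 4
  if (any(bad)) {
    abort(paste0("Tree table row ", row, ": cannot parse variant token '",
                 toks[bad][1], "'."))
  }
  tibble(
    position = as.integer(purrr::map_chr(m, 2)),
    base = toupper(purrr::map_chr(m, 3)),
    back = purrr::map_chr(m, 4) == "!"
  )
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("<haplogroup_tree> ", nrow(x$nodes), " haplogroups, root '",
      x$root, "'\n", sep = "")
  invisible(x)
}

# expected variant set on the root->node path; back-mutations delete the
# matching earlier expectation. Returns named character (pos -> base).
expected_path_variants <- function(tree, node, region_set = NULL) {
  chain <- character(0)
  cur <- node
  while (TRUE) {
    chain <- c(cur, chain)
    if (cur == tree$root) break
    cur <- tree$nodes$parent[match(cur, tree$nodes$name)]
  }
  expected <- character(0)
  for (nm in chain) {
    v <- tree$nodes$variants[[match(nm, tree$nodes$name)]]
    if (nrow(v) == 0) next
    for (r in seq_len(nrow(v))) {
      key <- as.character(v$position[r])
      if (v$back[r]) {
        expected <- expected[names(expected) != key]
      } else {
        expected[key] <- v$base[r]
      }
    }
  }
  if (!is.null(region_set) && length(expected)) {
    keep <- in_regions(as.integer(names(expected)), region_set)
    expected <- expected[keep]
  }
  expected
}

node_depth <- function(tree, node) {
  d <- 0L
  cur <- node
  while (cur != tree$root) {
    d <- d + 1L
    cur <- tree$nodes$parent[match(cur, tree$nodes$name)]
  }
  d
}

#' Assign a haplogroup to a variant profile
#'
#' A deliberately simple deterministic classifier for clean (synthetic or
#' curated) data, not a replacement for database-backed callers on noisy
#' real data: each node's expected variant set is the union of defining
#' variants along the root-to-node path (back-mutations remove inherited
#' expectations, and expectations are restricted to the profile's region
#' set); the score is the matched fraction of expected variants; the best
#' node maximises the matched count, ties broken by higher score (so a
#' fully matched node beats its partially matched descendants), then
#' greater path depth, then lexicographically smaller name. Private
#' variants of the profile are not penalised.
#'
#' @param profile One profile (one-row tibble or list with `variants`).
#' @param tree A [read_tree_table()] tree.
#' @param region_set Optional [region_set()] restricting the defining
#'   variants considered.
#' @return A tibble with columns `haplogroup`, `score`, `matched`,
#'   `expected`, `runner_up`.
#' @export
assign_haplogroup <- function(profile, tree, region_set = NULL) {
  if (!inherits(tree, "haplogroup_tree") || nrow(tree$nodes) == 0) {
    abort("`tree` must be a non-empty haplogroup_tree.")
  }
  obs <- as_profile_variants(profile)
  scored <- purrr::map(tree$nodes$name, function(nm) {
    exp_v <- expected_path_variants(tree, nm, region_set)
    n_exp <- length(exp_v)
    matched <- if (n_exp == 0) 0L else {
      sum(names(exp_v) %in% names(obs) &
            obs[names(exp_v)] == exp_v, na.rm = TRUE)
    }
    list(name = nm, matched = matched, expected = n_exp,
         score = if (n_exp == 0) 1 else matched / n_exp,
         depth = node_depth(tree, nm))
  })
  tab <- tibble(
    name = purrr::map_chr(scored, "name"),
    matched = purrr::map_int(scored, \(s) as.integer(s$matched)),
    expected = purrr::map_int(scored, \(s) as.integer(s$expected)),
    score = purrr::map_dbl(scored, "score"),
    depth = purrr::map_int(scored, \(s) as.integer(s$depth))
  ) |>
    arrange(desc(.data$matched), desc(.data$score), desc(.data$depth),
            .data$name)
  tibble(
    haplogroup = tab$name[1],
    score = tab$score[1],
    matched = tab$matched[1],
    expected = tab$expected[1],
    runner_up = if (nrow(tab) > 1) tab$name[2] else NA_character_
  )
}

as_profile_variants <- function(profile) {
  if (is.data.frame(profile)) profile$variants[[1]] else
    if (is.list(profile) && !is.null(profile$variants)) profile$variants else
      profile
}

#' Assign haplogroups to every sample of a dataset
#'
#' @param ds An `mt_dataset`.
#' @param tree A haplogroup tree.
#' @return A tibble `sample_id`, `population`, `haplogroup`, `score`,
#'   `runner_up`.
#' @export
assign_haplogroups <- function(ds, tree) {
  rs <- dataset_regions(ds)
  calls <- purrr::map(ds$variants,
                      \(v) assign_haplogroup(list(variants = v), tree, rs))
  bind_cols(
    ds |> as_tibble() |> select("sample_id", "population"),
    bind_rows(calls) |> select("haplogroup", "score", "runner_up")
  )
}

#' Name a novel subhaplogroup
#'
#' Novel clades get the basal haplogroup name plus an underscore and the
#' position of the clade-exclusive substitution closest to the tip,
#' preferring a variant inside the screening windows (e.g. `M7b2a_8389`).
#'
#' @param parent_name Basal haplogroup name.
#' @param exclusive_variants Character vector of variant tokens
#'   (`<pos><BASE>`) exclusive to the clade, ordered root-side to tip
#'   (the last element is tip-most).
#' @param screened_regions A [region_set()] of the screening protocol.
#' @return The new name, a string.
#' @export
name_novel_subhaplogroup <- function(parent_name, exclusive_variants,
                                     screened_regions) {
  if (length(exclusive_variants) == 0) {
    abort("Need at least one exclusive variant to name a subhaplogroup.")
  }
  pos <- as.integer(sub("^(\\d+).*$", "\\1", exclusive_variants))
  inside <- in_regions(pos, screened_regions)
  pick <- if (any(inside)) max(which(inside)) else length(pos)
  paste0(parent_name, "_", pos[pick])
}

#' Per-population haplogroup frequency table
#'
#' @param calls A tibble with `sample_id`, `population`, `haplogroup`
#'   (e.g. from [assign_haplogroups()]).
#' @return An object of class `frequency_table`: tibble `population`,
#'   `haplogroup`, `n`, `freq`, with `freq` summing to 1 within each
#'   population.
#' @export
haplogroup_frequencies <- function(calls) {
  if (nrow(calls) == 0) abort("No haplogroup calls supplied.")
  out <- calls |>
    count(.data$population, .data$haplogroup, name = "n") |>
    group_by(.data$population) |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$population, .data$haplogroup)
  class(out) <- c("frequency_table", class(out))
  out
}

#' Two-parent shared-haplogroup admixture partition
#'
#' Splits a hybrid population's haplogroup frequency mass into the
#' fraction shared with a first parental pool, the fraction shared with a
#' second pool, and the unshared remainder. Haplogroups present in both
#' parental sets count toward the first parent: the second pool is
#' defined as its raw set minus the first parent's set (the construction
#' used for an indigenous pool "not shared with" the majority parent).
#' Shares are frequency mass at whatever haplogroup resolution the caller
#' supplies.
#'
#' @param freqs A [haplogroup_frequencies()] table (or compatible tibble
#'   with `population`, `haplogroup`, `freq`).
#' @param hybrid Population label(s) to partition; default: all
#'   populations in `freqs` not used as parents.
#' @param parent1,parent2_raw Character vectors of haplogroup names
#'   defining the two parental pools (parent2 before subtraction).
#' @param parent_names Length-2 labels for the output columns.
#' @return A tibble `population`, `parent1_share`, `parent2_share`,
#'   `unshared` (rows sum to 1), with parent labels as an attribute.
#' @export
admixture_partition <- function(freqs, parent1, parent2_raw,
                                hybrid = NULL,
                                parent_names = c("parent1", "parent2")) {
  parent2 <- setdiff(parent2_raw, parent1)
  pops <- hybrid %||% unique(freqs$population)
  out <- purrr::map(pops, function(p) {
    row <- freqs[freqs$population == p, ]
    if (nrow(row) == 0) abort(paste0("Population '", p, "' not in table."))
    tot <- sum(row$freq)
    if (abs(tot - 1) > 1e-9) {
      abort(paste0("Frequencies of '", p, "' do not sum to 1."))
    }
    s1 <- sum(row$freq[row$haplogroup %in% parent1])
    s2 <- sum(row$freq[row$haplogroup %in% parent2])
    tibble(population = p, parent1_share = s1, parent2_share = s2,
           unshared = 1 - s1 - s2)
  }) |> bind_rows()
  attr(out, "parent_names") <- parent_names
  out
}
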