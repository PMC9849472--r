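toy_tree_rows <- c(
  "mt-MRCA\t\t",
  "N\tmt-MRCA\t100A 200C",
  "B\tN\t300T",
  "B4\tB\t400G 500A",
  "B4a\tB4\t600T",
  "B5\tB\t450C",
  "M\tmt-MRCA\t150G",
  "M7b2a_8389\tM\t250A",
  "M_back\tM\t150G! 350T"
)

test_that("tree tables load, validate and keep underscore names", {
  tree <- read_tree_table(write_toy_tree_table(toy_tree_rows))
  expect_s3_class(tree, "haplogroup_tree")
  expect_equal(tree$root, "mt-MRCA")
  expect_true("M7b2a_8389" %in% tree$nodes$name)
  expect_error(
    read_tree_table(write_toy_tree_table(c("root\t\t", "A\tnope\t100A"))),
    "unknown parent"
  )
  expect_error(
    read_tree_table(write_toy_tree_table(c("root\t\t", "A\troot\t1A",
                                           "A\troot\t2C"))),
    "Duplicate"
  )
  expect_error(
    read_tree_table(write_toy_tree_table(c("root\t\t", "A\tB\t1A",
                                           "B\tA\t2C"))),
    "Cycle"
  )
  expect_error(
    read_tree_table(write_toy_tree_table(c("root\t\t", "A\troot\t1X"))),
    "variant token"
  )
})

test_that("back-mutations remove inherited expectations on the path", {
  tree <- read_tree_table(write_toy_tree_table(toy_tree_rows))
  exp_m <- expected_path_variants(tree, "M")
  expect_equal(exp_m, c("150" = "G"))
  exp_back <- expected_path_variants(tree, "M_back")
  expect_equal(exp_back, c("350" = "T"))
})

test_that("classification matches path variants with documented tie rules", {
  tree <- read_tree_table(write_toy_tree_table(toy_tree_rows))
  # full B4a path: N + B + B4 + B4a
  prof <- list(variants = c("100" = "A", "200" = "C", "300" = "T",
                            "400" = "G", "500" = "A", "600" = "T"))
  call <- assign_haplogroup(prof, tree)
  expect_equal(call$haplogroup, "B4a")
  expect_equal(call$score, 1)
  # empty profile -> root with score 1 on an empty expected set
  call0 <- assign_haplogroup(list(variants = character(0)), tree)
  expect_equal(call0$haplogroup, "mt-MRCA")
  expect_equal(call0$score, 1)
  # equal matched count and depth: lexicographically smaller of B4/B5
  tie <- list(variants = c("100" = "A", "200" = "C", "300" = "T"))
  call_tie <- assign_haplogroup(tie, tree)
  expect_equal(call_tie$haplogroup, "B")
  # private variants are not penalised
  noisy <- list(variants = c("100" = "A", "200" = "C", "300" = "T",
                             "999" = "G"))
  expect_equal(assign_haplogroup(noisy, tree)$haplogroup, "B")
  expect_error(assign_haplogroup(prof, structure(list(), class = "x")),
               "haplogroup_tree")
})

test_that("profiles synthesised from a node's path classify back to it", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      # random chain/branch tree with unique defining positions
      n_nodes <- sample(4:8, 1)
      names_ <- c("root", paste0("H", seq_len(n_nodes)))
      parents <- c("", purrr::map_chr(seq_len(n_nodes), function(i) {
        if (i == 1) "root" else names_[sample(i, 1)]
      }))
      pos_pool <- sample(1:1000, n_nodes * 2)
      rows <- purrr::map_chr(seq_along(names_), function(i) {
        if (i == 1) return("root\t\t")
        v <- paste0(pos_pool[2 * (i - 1) - 1], "A ",
                    pos_pool[2 * (i - 1)], "C")
        paste0(names_[i], "\t", parents[i], "\t", v)
      })
      tree <- read_tree_table(write_toy_tree_table(rows))
      target <- sample(names_[-1], 1)
      prof <- list(variants = expected_path_variants(tree, target))
      expect_equal(assign_haplogroup(prof, tree)$haplogroup, target)
    }
  })
})

test_that("novel subhaplogroup naming prefers tip-most screened variants", {
  scr <- screened_regions()
  expect_equal(
    name_novel_subhaplogroup("M7b2a", c("16129A", "8389C"), scr),
    "M7b2a_8389"
  )
  expect_equal(
    name_novel_subhaplogroup("Z4", c("16248T"), scr),
    "Z4_16248"
  )
  # tip-most variant outside the screen, next inside at 10310 -> 10310
  expect_equal(
    name_novel_subhaplogroup("C7a", c("10310T", "5000G"), scr),
    "C7a_10310"
  )
  # none inside -> tip-most overall
  expect_equal(
    name_novel_subhaplogroup("X", c("5000G", "6000T"), scr),
    "X_6000"
  )
  expect_error(name_novel_subhaplogroup("X", character(0), scr),
               "at least one")
})

test_that("frequency tables normalise per population, order-invariant", {
  calls <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    population = c("P", "P", "P", "P", "Q", "Q"),
    haplogroup = c("B4", "B4", "D4", "D4", "M7", "B4")
  )
  ft <- haplogroup_frequencies(calls)
  expect_equal(ft$freq[ft$population == "P"], c(0.5, 0.5))
  ft2 <- haplogroup_frequencies(calls[sample(6), ])
  expect_equal(ft, ft2, ignore_attr = TRUE)
  expect_equal(
    ft |> dplyr::group_by(population) |> dplyr::summarise(s = sum(freq)) |>
      dplyr::pull(s),
    c(1, 1)
  )
  expect_error(haplogroup_frequencies(calls[0, ]), "No haplogroup calls")
})

test_that("admixture partition sums to one with parent-1 precedence", {
  freqs <- tibble::tibble(
    population = "H",
    haplogroup = c("X", "Y", "Z"),
    freq = c(0.5, 0.3, 0.2)
  )
  part <- admixture_partition(freqs, parent1 = "X", parent2_raw = "Y")
  expect_equal(unlist(part[, -1]),
               c(parent1_share = 0.5, parent2_share = 0.3, unshared = 0.2))
  # a haplogroup in both parental sets counts toward parent 1
  freqs2 <- tibble::tibble(population = "H",
                           haplogroup = c("W", "Z"), freq = c(0.4, 0.6))
  part2 <- admixture_partition(freqs2, parent1 = "W", parent2_raw = c("W"))
  expect_equal(part2$parent1_share, 0.4)
  expect_equal(part2$parent2_share, 0)
  # nothing shared with either parent
  part3 <- admixture_partition(freqs, parent1 = "A", parent2_raw = "B")
  expect_equal(part3$unshared, 1)
  # permuting haplogroup rows changes nothing; fractions always sum to 1
  part4 <- admixture_partition(freqs[c(3, 1, 2), ], parent1 = "X",
                               parent2_raw = "Y")
  expect_equal(part4, part, ignore_attr = TRUE)
  expect_equal(part$parent1_share + part$parent2_share + part$unshared, 1)
})
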