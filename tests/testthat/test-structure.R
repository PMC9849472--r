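test_that("AMOVA Fst matches hand-computed toys", {
  # two internally monomorphic populations, fixed difference
  ds1 <- toy_dataset(
    list(character(0), character(0), c("10" = "A", "20" = "C"),
         c("10" = "A", "20" = "C")),
    c("A", "A", "B", "B")
  )
  expect_equal(pairwise_fst(ds1, "A", "B")$fst, 1)
  # pop1 = {h1, h1}, pop2 = {h1, h2}, d(h1, h2) = 1:
  # SS_total = 0.75, SS_within = 0.5, sigma_a = 0 -> Fst = 0
  ds2 <- toy_dataset(
    list(character(0), character(0), character(0), c("10" = "A")),
    c("A", "A", "B", "B")
  )
  expect_equal(pairwise_fst(ds2, "A", "B")$fst, 0)
  # all identical -> NA
  ds3 <- toy_dataset(rep(list(character(0)), 4), c("A", "A", "B", "B"))
  expect_true(is.na(pairwise_fst(ds3, "A", "B")$fst))
  expect_error(pairwise_fst(ds2, "A", "missing"), "at least 2")
})

test_that("Fst is stable under duplicating every sample", {
  duplicate_ds <- function(ds) {
    dup <- dplyr::bind_rows(
      ds, ds |> dplyr::mutate(sample_id = paste0(sample_id, "_d"))
    )
    attr(dup, "region_set") <- dataset_regions(ds)
    class(dup) <- class(ds)
    dup
  }
  # exact on the boundary toys (Fst = 1 and sigma_a = 0)
  ds_fixed <- toy_dataset(
    list(character(0), character(0), c("10" = "A"), c("10" = "A")),
    c("A", "A", "B", "B")
  )
  expect_equal(pairwise_fst(duplicate_ds(ds_fixed), "A", "B")$fst, 1)
  # approximate on generic data (variance components carry N - 2 terms
  # that only cancel asymptotically)
  withr::with_seed(41, {
    sim <- simulate_dataset(c(A = 6, B = 6),
                            demographic_model("constant", 3),
                            split_time = 4)
  })
  f1 <- pairwise_fst(sim$dataset, "A", "B")$fst
  f2 <- pairwise_fst(duplicate_ds(sim$dataset), "A", "B")$fst
  expect_equal(f1, f2, tolerance = 0.1)
})

test_that("random labels of a panmictic sample give Fst near zero", {
  withr::with_seed(42, {
    sim <- simulate_dataset(c(P = 20), demographic_model("constant", 5))
    ds <- sim$dataset
    d <- pairwise_diff_matrix(ds)$differences
    fsts <- purrr::map_dbl(1:200, function(i) {
      labs <- sample(rep(c("X", "Y"), 10))
      amova_fst(d, labs)
    })
    expect_lt(abs(mean(fsts)), 0.05)
  })
})

test_that("permutation p-values flag structured data, not panmixia", {
  withr::with_seed(43, {
    deep <- simulate_dataset(c(A = 8, B = 8),
                             demographic_model("constant", 3),
                             split_time = 25)
  })
  r <- pairwise_fst(deep$dataset, "A", "B", n_perm = 200, seed = 44)
  expect_gt(r$fst, 0.5)
  expect_lt(r$p, 0.05)
})

test_that("gene flow inverts the haploid island model", {
  expect_equal(gene_flow_m(0.2), 2)
  expect_equal(gene_flow_m(0.5), 0.5)
  expect_identical(gene_flow_m(0), Inf)
  expect_identical(gene_flow_m(-0.01), Inf)
  expect_equal(gene_flow_m(1), 0)
  # round trip through the analytic equilibrium Fst = 1/(2M + 1)
  M <- c(0.25, 1, 4, 100)
  expect_equal(gene_flow_m(1 / (2 * M + 1)), M, tolerance = 1e-12)
})

test_that("Fst rises with divergence time between two demes", {
  withr::with_seed(45, {
    grid <- c(1, 5, 25)
    mean_fst <- purrr::map_dbl(grid, function(ts) {
      reps <- purrr::map_dbl(1:25, function(i) {
        sim <- simulate_dataset(c(A = 6, B = 6),
                                demographic_model("constant", 3),
                                split_time = ts)
        f <- pairwise_fst(sim$dataset, "A", "B")$fst
        if (is.na(f)) 0 else f
      })
      mean(reps)
    })
    expect_true(all(diff(mean_fst) > 0))
  })
})

test_that("classical MDS recovers Euclidean configurations exactly", {
  withr::with_seed(46, {
    pts <- matrix(rnorm(10), ncol = 2,
                  dimnames = list(paste0("P", 1:5), NULL))
  })
  d <- as.matrix(stats::dist(pts))
  emb <- classical_mds(d)
  got <- as.matrix(emb$coordinates[, c("axis1", "axis2")])
  expect_equal(as.matrix(stats::dist(got)), d, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_lt(emb$stress, 1e-9)
  # coordinates are centred
  expect_equal(colSums(got), c(0, 0), ignore_attr = TRUE, tolerance = 1e-9)
  # collinear points embed on one axis
  line <- as.matrix(stats::dist(cbind(c(0, 1, 3))))
  dimnames(line) <- list(c("a", "b", "c"), c("a", "b", "c"))
  emb2 <- classical_mds(line)
  expect_equal(abs(emb2$eigenvalues[2]), 0, tolerance = 1e-9)
  # NA entries are reported with the offending pair
  bad <- d
  bad[1, 2] <- bad[2, 1] <- NA
  expect_error(classical_mds(bad), "P1-P2")
  # negative entries floored with a warning
  neg <- d
  neg[1, 2] <- neg[2, 1] <- -0.01
  expect_warning(classical_mds(neg), "floored")
})

test_that("fst_matrix + tidy expose the pair table with gene flow", {
  withr::with_seed(47, {
    sim <- simulate_dataset(c(A = 6, B = 6),
                            demographic_model("constant", 3),
                            split_time = 8)
  })
  ds <- sim$dataset
  # add a third population by relabelling (tests matrix shape only)
  ds$population[ds$sample_id %in% c("s1", "s2", "s7", "s8")] <- "C"
  fm <- fst_matrix(ds, n_perm = 50, seed = 48)
  expect_equal(dim(fm$fst), c(3, 3))
  expect_equal(diag(fm$fst), rep(0, 3), ignore_attr = TRUE)
  expect_equal(fm$fst, t(fm$fst))
  td <- tidy(fm)
  expect_equal(nrow(td), 3)
  expect_true(all(c("fst", "p", "M") %in% names(td)))
})
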