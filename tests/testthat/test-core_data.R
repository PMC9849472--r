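test_that("region sets validate bounds and compute lengths from them", {
  rs <- stat_regions()
  expect_equal(rs$total_length, 2450L)
  expect_equal(screened_regions()$total_length, 2669L)
  expect_error(region_set(c(10, 5), c(20, 30)), "non-overlapping")
  expect_error(region_set(10, 5), "start <= end")
  expect_equal(region_set(c(9801, 8001), c(10900, 9000))$regions$start,
               c(8001L, 9801L))
})

test_that("FASTA ingest maps substitutions, reference matches and ambiguity", {
  rs <- stat_regions()
  withr::with_seed(11, {
    ref <- random_reference(rs)
  })
  pos <- region_positions(rs)
  # mutate sample 2 at rCRS 16223, put an N at 8281 in sample 3
  i16223 <- match(16223L, pos)
  i8281 <- match(8281L, pos)
  ref_16223 <- substring(ref, i16223, i16223)
  alt <- setdiff(c("A", "C", "G", "T"), ref_16223)[1]
  s2 <- ref
  substring(s2, i16223, i16223) <- alt
  s3 <- ref
  substring(s3, i8281, i8281) <- "N"
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ident", ref, ">sub", s2, ">amb", s3), fa)
  prof <- read_profiles(fa, rs, ref)
  expect_equal(prof$sample_id, c("ident", "sub", "amb"))
  expect_length(prof$variants[[1]], 0)
  expect_length(prof$missing[[1]], 0)
  expect_equal(prof$variants[[2]],
               stats::setNames(alt, "16223"))
  expect_equal(prof$missing[[3]], 8281L)
  expect_false("8281" %in% names(prof$variants[[3]]))
})

test_that("records with inconsistent length are rejected by id", {
  rs <- stat_regions()
  withr::with_seed(12, ref <- random_reference(rs))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad_record", substring(ref, 1, 100)), fa)
  expect_error(read_profiles(fa, rs, ref), "bad_record")
})

test_that("profiles survive a FASTA round trip", {
  rs <- stat_regions()
  withr::with_seed(13, {
    ref <- random_reference(rs)
    pos <- region_positions(rs)
    sets <- purrr::map(1:6, function(i) {
      p <- sample(pos, sample(0:8, 1))
      v <- purrr::map_chr(p, function(pp) {
        idx <- match(pp, pos)
        sample(setdiff(c("A", "C", "G", "T"),
                       substring(ref, idx, idx)), 1)
      })
      stats::setNames(v, as.character(p))
    })
    miss <- purrr::map(1:6, \(i) {
      m <- sample(setdiff(pos, as.integer(names(sets[[i]]))), sample(0:3, 1))
      sort(m)
    })
  })
  ds <- toy_dataset(sets, rep("P", 6), missing = miss, rs = rs)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_profiles(ds, fa, ref)
  back <- read_profiles(fa, rs, ref)
  expect_equal(back$variants, ds$variants, ignore_attr = TRUE)
  expect_equal(back$missing, ds$missing, ignore_attr = TRUE)
})

test_that("pairwise differences honour pairwise deletion and symmetry", {
  rs <- toy_regions()
  a <- list(variants = c("10" = "A", "20" = "C", "30" = "G"),
            missing = integer(0))
  b <- list(variants = stats::setNames(character(0), character(0)),
            missing = integer(0))
  r <- pairwise_differences(a, b, rs)
  expect_equal(r$differences, 3)
  expect_equal(r$compared_sites, 1000)
  expect_equal(pairwise_differences(a, a, rs),
               list(differences = 0, compared_sites = 1000))
  # variant at a site the partner cannot call is excluded from both counts
  c_ <- list(variants = c("10" = "A", "20" = "C"), missing = 30L)
  r2 <- pairwise_differences(a, c_, rs)
  expect_equal(r2$differences, 0)
  expect_equal(r2$compared_sites, 999)
  # same position, different derived alleles counts once
  d_ <- list(variants = c("10" = "T"), missing = integer(0))
  expect_equal(pairwise_differences(a, d_, rs)$differences, 3)
  # symmetry and bound over random profiles
  withr::with_seed(14, {
    for (i in 1:20) {
      va <- stats::setNames(sample(c("A", "C", "G", "T"), 5, TRUE),
                            sample(1000, 5))
      vb <- stats::setNames(sample(c("A", "C", "G", "T"), 5, TRUE),
                            sample(1000, 5))
      pa <- list(variants = canonical_variants(va),
                 missing = sample(setdiff(1:1000, as.integer(names(va))), 2))
      pb <- list(variants = canonical_variants(vb),
                 missing = sample(setdiff(1:1000, as.integer(names(vb))), 2))
      r_ab <- pairwise_differences(pa, pb, rs)
      r_ba <- pairwise_differences(pb, pa, rs)
      expect_equal(r_ab, r_ba)
      expect_lte(r_ab$differences, r_ab$compared_sites)
    }
  })
})

test_that("haplotype collapsing counts and keys behave", {
  h1 <- c("10" = "A")
  h2 <- c("20" = "C", "10" = "A")
  ds <- toy_dataset(list(h1, h1, h2, h2), rep("P", 4))
  tab <- collapse_haplotypes(ds)
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$n), c(2L, 2L))
  expect_equal(sum(tab$n), 4L)
  # canonical key is position-sorted
  expect_true("10A/20C" %in% tab$haplotype)
  # all distinct -> k = n; reference haplotype key
  ds2 <- toy_dataset(list(character(0), c("5" = "T"), c("6" = "G")),
                     rep("Q", 3))
  tab2 <- collapse_haplotypes(ds2)
  expect_equal(nrow(tab2), 3)
  expect_true("rCRS" %in% tab2$haplotype)
  expect_equal(length(haplotype_counts(ds2)), 3)
})

test_that("dataset construction enforces labels and region membership", {
  expect_error(
    toy_dataset(list(c("2000" = "A")), "P"),
    "outside region"
  )
  profiles <- tibble::tibble(
    sample_id = "s1",
    variants = list(c("10" = "A")),
    missing = list(integer(0))
  )
  expect_error(mt_dataset(profiles, c(other = "P"), toy_regions()),
               "No population label")
  expect_error(
    toy_dataset(list(c("10" = "A")), "P", missing = list(10L)),
    "both variant and missing"
  )
})
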