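test_that("rho is the mean root-to-tip substitution count", {
  two <- ape::read.tree(text = "(A:1,B:0);")
  expect_equal(rho_statistic(two), 0.5)
  star3 <- ape::read.tree(text = "(A:2,B:1,C:1);")
  expect_equal(rho_statistic(star3), 4 / 3)
  zero <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(rho_statistic(zero), 0)
  bad <- ape::read.tree(text = "(A:0.5,B:0);")
  expect_error(rho_statistic(bad), "integer")
})

test_that("Saillard sigma weights branches by squared descendant counts", {
  two <- ape::read.tree(text = "(A:1,B:0);")
  expect_equal(saillard_sigma(two), 0.5)
  # root->A (2), root->internal (1) -> {B, C}: sigma = sqrt(6)/3
  nested <- ape::read.tree(text = "(A:2,(B:0,C:0):1);")
  expect_equal(saillard_sigma(nested), sqrt(6) / 3, tolerance = 1e-12)
  zero <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(saillard_sigma(zero), 0)
  # star trees with singleton substitutions: sigma = sqrt(rho/n)
  withr::with_seed(61, {
    for (i in 1:10) {
      n <- sample(3:12, 1)
      m <- stats::rpois(n, 1.5)
      txt <- paste0("(", paste0("t", seq_len(n), ":", m, collapse = ","),
                    ");")
      phy <- ape::read.tree(text = txt)
      expect_equal(saillard_sigma(phy),
                   sqrt(rho_statistic(phy) / n), tolerance = 1e-12)
    }
  })
})

test_that("the corrected clock reproduces the printed ages", {
  clk <- clock_model()
  expect_equal(corrected_time(0, clk), 0)
  expect_equal(round_half_up(corrected_time(1, clk), 1), 2.6)
  expect_equal(round_half_up(corrected_time(2, clk), 1), 5.2)
  expect_error(corrected_time(-1, clk), "non-negative")
  # strictly increasing, correction factor in (0, 1) tending to 1
  rho <- seq(0, 50, by = 0.5)
  t_ <- corrected_time(rho, clk)
  expect_true(all(diff(t_) > 0))
  fac <- t_[-1] / (clk$m * rho[-1])
  expect_true(all(fac > 0 & fac < 1))
  expect_gt(fac[length(fac)], 0.9)
})

test_that("confidence bounds use the central correction factor", {
  clk <- clock_model()
  ci <- time_ci(0.5, 0.5, clk)
  expect_equal(round_half_up(ci$low, 1), -1.2)
  expect_equal(round_half_up(ci$high, 1), 3.8)
  expect_equal(round_half_up(corrected_time(0.5, clk), 1), 1.3)
  ci0 <- time_ci(1, 0, clk)
  expect_equal(ci0$low, ci0$high)
  expect_equal(ci0$low, corrected_time(1, clk))
  ci1 <- time_ci(1, 0.5, clk)
  expect_equal(round(ci1$low, 2), 0.05, tolerance = 0.01)
  expect_equal(round(ci1$high, 2), 5.12, tolerance = 0.01)
})

test_that("date_clades assembles the report table", {
  clades <- list(
    young = ape::read.tree(text = "(A:1,B:0);"),
    older = ape::read.tree(text = "(A:2,(B:1,C:1):1);")
  )
  tab <- date_clades(clades)
  expect_equal(tab$clade, c("young", "older"))
  expect_equal(tab$n, c(2L, 3L))
  expect_equal(tab$t_kyr, corrected_time(tab$rho))
  expect_true(all(tab$ci_low <= tab$t_kyr & tab$t_kyr <= tab$ci_high))
  expect_equal(tab$t_rounded, round_half_up(tab$t_kyr, 1))
})

test_that("star_rho matches per-sample differences to the root haplotype", {
  ds <- toy_dataset(
    list(c("10" = "A"), c("10" = "A", "20" = "C"), character(0)),
    rep("P", 3)
  )
  sr <- star_rho(ds, root_variants = c("10" = "A"))
  # diffs to root: 0, 1, 1
  expect_equal(sr$rho, 2 / 3, tolerance = 1e-12)
  expect_equal(sr$sigma, sqrt((2 / 3) / 3), tolerance = 1e-12)
})

test_that("rate combination is a length-weighted mean with its interval", {
  one <- combine_rates(1e-7, 1000)
  expect_equal(one$combined_per_site_rate, 1e-7)
  expect_equal(one$per_sequence_interval_years, 10000)
  # the coding-region calibration: one substitution per 13,786 years
  coding <- combine_rates(3.42e-8, 2121)
  expect_equal(coding$per_sequence_interval_years, 13786, tolerance = 1e-3)
  # combining HVS-I and coding windows
  both <- combine_rates(c(1.602e-7, 3.42e-8), c(350, 2121))
  expect_equal(both$combined_per_site_rate, 5.205e-8, tolerance = 1e-3)
  expect_error(combine_rates(c(1e-7, -1), c(10, 10)), "positive")
  expect_equal(glance(both)$total_length, 2471L)
})

test_that("partial-sequence dating converts rho with optional correction", {
  expect_equal(date_clade_partial(1, interval_override = 8940), 8.94)
  expect_equal(date_clade_partial(0, interval_override = 8940), 0)
  calib <- combine_rates(1e-7, 1000)
  expect_equal(date_clade_partial(2, calib), 20)
  corr <- date_clade_partial(2, calib, correct = TRUE)
  expect_lt(corr, 20)
  expect_equal(corr / 20, exp(-exp(-0.0263 * (2 + 40.28))),
               tolerance = 1e-12)
  expect_error(date_clade_partial(1), "calibration or an interval")
})

test_that("simulated star clades recover their true age with ~95% coverage", {
  clk <- clock_model()
  T_star <- 10
  # expected substitutions per lineage consistent with the corrected clock
  rho_star <- stats::uniroot(\(r) corrected_time(r, clk) - T_star,
                             c(0.1, 50))$root
  withr::with_seed(62, {
    res <- purrr::map(1:500, function(i) {
      m <- stats::rpois(50, rho_star)
      rho_hat <- mean(m)
      sigma_hat <- sqrt(sum(m) / 50^2)
      ci <- time_ci(rho_hat, sigma_hat, clk)
      list(t = corrected_time(rho_hat, clk),
           covered = ci$low <= T_star && T_star <= ci$high)
    })
  })
  t_hat <- purrr::map_dbl(res, "t")
  expect_equal(mean(t_hat), T_star, tolerance = 0.05)
  coverage <- mean(purrr::map_lgl(res, "covered"))
  expect_gt(coverage, 0.90)
  expect_lt(coverage, 0.99)
})
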