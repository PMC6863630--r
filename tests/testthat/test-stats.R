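test_that("Fisher's exact test follows the point-probability rule", {
  # the balanced table is the modal table: p = 1
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  # printed responder counts: GP_CPu vs GP_STN under M1 is extreme
  p_m1 <- fisher_exact_2x2(28, 7, 17, 34)$p_value
  expect_lt(p_m1, 2.5e-4)
  expect_equal(p_m1, oracle_fisher_p(28, 7, 17, 34), tolerance = 1e-9)
  # degenerate margins
  expect_warning(r0 <- fisher_exact_2x2(0, 0, 0, 0))
  expect_equal(r0$p_value, 1)
  expect_equal(fisher_exact_2x2(0, 0, 5, 5)$p_value, 1)
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4),
               class = "optopallidum_argument_error")
})

test_that("Fisher p-values are invariant under table symmetries", {
  tabs <- list(c(28, 7, 17, 34), c(3, 9, 6, 2), c(1, 5, 7, 2))
  for (tb in tabs) {
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p_value
    expect_equal(fisher_exact_2x2(tb[3], tb[4], tb[1], tb[2])$p_value, p)
    expect_equal(fisher_exact_2x2(tb[2], tb[1], tb[4], tb[3])$p_value, p)
    expect_equal(fisher_exact_2x2(tb[1], tb[3], tb[2], tb[4])$p_value, p)
  }
})

test_that("exact tests agree with enumeration oracles on all small instances", {
  # Fisher: every 2x2 table with total n <= 12
  for (n_tot in 0:12) {
    for (a in 0:n_tot) for (b in 0:(n_tot - a)) for (cc in 0:(n_tot - a - b)) {
      d <- n_tot - a - b - cc
      if (all(rowSums(matrix(c(a, cc, b, d), 2)) > 0) &&
          all(colSums(matrix(c(a, cc, b, d), 2)) > 0)) {
        expect_equal(fisher_exact_2x2(a, b, cc, d)$p_value,
                     oracle_fisher_p(a, b, cc, d), tolerance = 1e-9)
      }
    }
  }
})

test_that("rank-sum test is exact for small untied samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(7, 8), c(7, 8))$p_value, 1)
  set.seed(31)
  for (rep in 1:5) {
    x <- round(rnorm(4), 3)
    y <- round(rnorm(4, 0.5), 3)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcox_p(x, y),
                 tolerance = 1e-9)
  }
  # uneven sizes
  x <- c(0.1, 2.5, 3.7)
  y <- c(1.1, 1.9, 4.2, 5.5, 0.4)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcox_p(x, y),
               tolerance = 1e-9)
})

test_that("Kruskal-Wallis uses the exact permutation null for tiny samples", {
  # identical constants: H = 0
  res <- suppressWarnings(kruskal_wallis(list(rep(1, 3), rep(1, 3))))
  expect_equal(unname(res$statistic), 0)
  # 3 groups of 2 distinct values: matches the 720-permutation oracle
  g <- list(c(1.2, 3.4), c(2.2, 5.1), c(0.3, 4.4))
  res2 <- kruskal_wallis(g)
  expect_equal(res2$method, "exact_permutation")
  expect_equal(res2$p_value, oracle_kw_p(g), tolerance = 1e-9)
  # larger samples fall back to the chi-square reference
  set.seed(5)
  big <- list(rnorm(8), rnorm(8), rnorm(8))
  resb <- kruskal_wallis(big)
  expect_equal(resb$method, "chi_square")
  expect_equal(resb$p_value,
               stats::kruskal.test(big)$p.value, tolerance = 1e-12)
})

test_that("Tukey-HSD with two equal groups reduces to the pooled t statistic", {
  set.seed(9)
  x <- rnorm(8)
  y <- rnorm(8, 1)
  tk <- tukey_hsd(list(a = x, b = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  # q = t * sqrt(2): Tukey's adjusted p equals the t-test p for 2 groups
  expect_equal(tk$p_value, tt$p.value, tolerance = 1e-9)
  expect_equal(tk$diff, mean(y) - mean(x), tolerance = 1e-12)
})

test_that("KS statistic equals the brute-force CDF gap", {
  x <- rnorm(30)
  set.seed(13)
  x <- rnorm(30)
  y <- rnorm(40, 0.4)
  r <- ks_two_sample(x, y)
  expect_equal(unname(r$statistic), oracle_ks_d(x, y), tolerance = 1e-12)
  # identical samples: D = 0, p = 1
  expect_equal(unname(ks_two_sample(x, x)$statistic), 0)
  expect_equal(ks_two_sample(x, x)$p_value, 1)
  # disjoint supports: D = 1
  expect_equal(unname(ks_two_sample(1:5, 11:15)$statistic), 1)
})

test_that("signed-rank test vs a reference value is exact and drops zeros", {
  # symmetric around the reference: p near 1
  x <- 1 + c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3)
  expect_gt(signed_rank_vs_value(x, 1)$p_value, 0.9)
  # all values above 1, n = 6: matches the 2^6 sign enumeration
  y <- 1 + c(0.05, 0.11, 0.23, 0.31, 0.47, 0.55)
  r <- signed_rank_vs_value(y, 1)
  expect_equal(r$p_value, oracle_signed_rank_p(y, 1), tolerance = 1e-9)
  expect_equal(r$p_value, 2 / 64)
  # zero differences are dropped and n adjusted
  z <- c(1, 1, 1.2, 1.4, 0.9)
  rz <- signed_rank_vs_value(z, 1)
  expect_equal(rz$n, 3)
  expect_equal(rz$p_value, oracle_signed_rank_p(c(1.2, 1.4, 0.9), 1),
               tolerance = 1e-9)
})

test_that("Bonferroni correction reproduces the figure-legend star levels", {
  expect_equal(bonferroni(0.05, 4), 0.0125)
  expect_equal(bonferroni(0.01, 4), 0.0025)
  expect_equal(bonferroni(0.001, 4), 0.00025)
  expect_equal(bonferroni(0.07, 1), 0.07)
  expect_equal(significance_stars(c(1e-5, 1e-3, 5e-3, 0.5)),
               c("***", "**", "*", "ns"))
})

test_that("connection analysis runs the four planned comparisons on printed counts", {
  counts <- tibble::tibble(
    cortical_source = c("M1", "M1", "M2", "M2"),
    projection_class = c("GP_CPu", "GP_STN", "GP_CPu", "GP_STN"),
    n_responsive = c(28, 17, 23, 36),
    n_total = c(35, 51, 27, 75)
  )
  res <- connection_table_analysis(counts)
  expect_equal(nrow(res$comparisons), 4)
  expect_equal(res$comparisons$adjusted_alpha, rep(0.0125, 4))
  # each p reproducible by the enumeration oracle
  oracle_ps <- c(
    oracle_fisher_p(28, 7, 17, 34), oracle_fisher_p(23, 4, 36, 39),
    oracle_fisher_p(28, 7, 23, 4), oracle_fisher_p(17, 34, 36, 39)
  )
  expect_equal(res$comparisons$p_value, oracle_ps, tolerance = 1e-9)
  # both within-source comparisons significant at the corrected level
  expect_true(all(res$comparisons$significant[1:2]))
  # empty class: affected comparisons skipped with warnings
  expect_warning(
    expect_warning(res0 <- connection_table_analysis(counts[-1, ]), "skipped"),
    "skipped"
  )
  expect_equal(nrow(res0$comparisons), 2)
})

test_that("planned-comparison familywise error stays at the corrected level", {
  n_sig <- vapply(1:100, function(s) {
    set.seed(s + 700)
    counts <- tibble::tibble(
      cortical_source = c("M1", "M1", "M2", "M2"),
      projection_class = c("GP_CPu", "GP_STN", "GP_CPu", "GP_STN"),
      n_responsive = rbinom(4, 50, 0.5),
      n_total = 50
    )
    any(connection_table_analysis(counts)$comparisons$significant)
  }, logical(1))
  expect_gte(mean(!n_sig), 0.94)
})

test_that("amplitude comparison mirrors the population analysis", {
  # four identical groups: F ~ 0, all Tukey p ~ 1
  meas0 <- tibble::tibble(
    projection_class = rep(c("MSN", "STN", "GP_STN", "GP_CPu"), each = 5),
    amplitude = rep(c(10, 20, 30, 40, 50), 4)
  )
  r0 <- amplitude_comparison(meas0)
  expect_lt(abs(r0$anova$statistic), 1e-10)
  expect_true(all(r0$tukey$p_value > 0.999))
  # MSN amplitudes 5x the pallidal groups: significant in nearly all seeds
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    meas <- tibble::tibble(
      projection_class = rep(c("MSN", "STN", "GP_STN", "GP_CPu"), each = 15),
      amplitude = c(rlnorm(15, log(250), 0.5), rlnorm(15, log(50), 0.5),
                    rlnorm(15, log(40), 0.5), rlnorm(15, log(90), 0.5))
    )
    r <- amplitude_comparison(meas)
    msn_rows <- grepl("MSN", r$tukey$comparison)
    all(r$tukey$p_value[msn_rows] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # n = 1 group is excluded with a warning
  meas1 <- dplyr::bind_rows(meas0, tibble::tibble(projection_class = "GP_Bi",
                                                  amplitude = 5))
  expect_warning(r1 <- amplitude_comparison(meas1), "excluding")
  expect_false(any(grepl("GP_Bi", r1$tukey$comparison)))
  # GP_Bi vs GP_CPu cumulative distributions via KS when both present
  set.seed(2)
  meas2 <- tibble::tibble(
    projection_class = rep(c("GP_Bi", "GP_CPu"), each = 20),
    amplitude = c(rlnorm(20, log(15), 0.4), rlnorm(20, log(90), 0.4))
  )
  r2 <- suppressWarnings(amplitude_comparison(meas2))
  expect_false(is.null(r2$ks_bi))
  expect_lt(r2$ks_bi$p_value, 0.01)
})
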