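test_that("replication binomial test reproduces the printed 0.034", {
  p <- binom_test_vs_reference(9, 13, 0.90)
  expect_equal(round(p, 3), 0.034)
  expect_equal(binom_test_vs_reference(10, 10, 0.9), 1)
  expect_equal(binom_test_vs_reference(3, 10, 0.5),
               oracle_binom_lower(3, 10, 0.5), tolerance = 1e-12)
})

test_that("exact tails agree with log-factorial summation to 1e-12", {
  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(1:200, 1)
      k <- sample(0:n, 1)
      p0 <- runif(1, 0.05, 0.95)
      expect_equal(binom_test_vs_reference(k, n, p0),
                   oracle_binom_lower(k, n, p0), tolerance = 1e-12)
      if (k >= 1) {
        expect_equal(chance_test(k, n, 1 - p0),
                     oracle_binom_upper(k, n, p0), tolerance = 1e-12)
      }
    }
  })
})

test_that("binomial tails are monotone in the observed count", {
  p_ref <- vapply(0:13, binom_test_vs_reference, numeric(1),
                  n = 13, p0 = 0.9)
  expect_true(all(diff(p_ref) >= 0))
  p_ch <- vapply(0:29, chance_test, numeric(1), n_selected = 29)
  expect_true(all(diff(p_ch) <= 0))
})

test_that("chance tests on the volumetric node counts beat their bars", {
  expect_lt(chance_test(26, 29), 0.01)   # test-cohort node
  expect_lt(chance_test(57, 67), 0.001)  # pooled
  # p0 -> 1 - chance_remission: larger chance remission means a smaller
  # success probability, hence a smaller upper tail
  ps <- vapply(c(0.2, 0.35, 0.5, 0.65), function(cr) chance_test(20, 29, cr),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("chi-square matches the printed melancholia statistic and closed form", {
  res <- chi2_2x2(matrix(c(6, 12, 51, 34), 2))
  expect_equal(round(res$statistic, 2), 4.27)
  expect_equal(round(res$p_value, 3), 0.039)
  expect_equal(chi2_2x2(matrix(c(3, 3, 9, 9), 2))$statistic, 0)
  withr::with_seed(13, {
    for (i in 1:50) {
      tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
      expect_equal(chi2_2x2(tab)$statistic, oracle_chi2(tab),
                   tolerance = 1e-12)
    }
  })
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("Fisher exact p follows the probability-ordering rule", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  tab <- matrix(c(18, 17, 2, 15), 2)
  expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab), tolerance = 1e-9)
  withr::with_seed(29, {
    for (i in 1:50) {
      tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
      expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab),
                   tolerance = 1e-9)
    }
  })
})

test_that("group comparison reproduces the characterization-table row", {
  fx <- make_melancholia_fixture()
  res <- compare_groups(fx, "group", "melancholic")
  expect_equal(res$type, "binary")
  expect_equal(round(res$p_value, 2), 0.04)
  expect_equal(round(res$p_value, 3), 0.039)
})

test_that("identical groups compare as null", {
  d <- tibble::tibble(
    group = rep(c("a", "b"), each = 20),
    x = rep(rnorm(20, 10), 2),
    flag = rep(c(TRUE, FALSE), 20)
  )
  res <- compare_groups(d, "group", c("x", "flag"))
  expect_equal(res$statistic[res$variable == "x"], 0, tolerance = 1e-12)
  expect_equal(res$p_value[res$variable == "x"], 1, tolerance = 1e-12)
  expect_equal(res$p_value[res$variable == "flag"], 1, tolerance = 1e-12)
})

test_that("the continuous comparison holds its nominal type-I error", {
  withr::with_seed(404, {
    reps <- 400
    p <- vapply(seq_len(reps), function(i) {
      d <- tibble::tibble(group = rep(c("a", "b"), each = 15),
                          x = rnorm(30))
      compare_groups(d, "group", "x")$p_value
    }, numeric(1))
    rate <- mean(p < 0.05)
    se <- sqrt(0.05 * 0.95 / reps)
    expect_lt(abs(rate - 0.05), 4 * se)
  })
})

test_that("selection evaluation computes counts, coverage and tests", {
  pooled <- ispotd_pooled_cohort()
  ev <- pooled |>
    apply_rules(ispotd_rules("volumetric")) |>
    evaluate_selection(reference_accuracy = 26 / 29)
  expect_equal(ev$n_selected, 67L)
  expect_equal(ev$n_correct, 57L)
  expect_equal(ev$accuracy, 57 / 67)
  expect_equal(ev$coverage, 57 / 103)
  expect_equal(ev$p_vs_reference,
               oracle_binom_lower(57, 67, 26 / 29), tolerance = 1e-12)
  expect_equal(ev$p_vs_chance,
               oracle_binom_upper(57, 67, 0.65), tolerance = 1e-12)
})
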