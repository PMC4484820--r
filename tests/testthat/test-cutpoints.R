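test_that("candidates appear at all distinct values except the minimum", {
  d <- tibble::tibble(x = c(1, 2, 2, 3),
                      remitted = c(TRUE, TRUE, FALSE, FALSE))
  cand <- enumerate_cutpoints(d, "x")
  expect_equal(cand$threshold, c(2, 3))
  expect_true(all(cand$n_lt_nonremit + cand$n_lt_remit > 0))
  expect_true(all(cand$n_ge_nonremit + cand$n_ge_remit > 0))
})

test_that("a constant feature yields no candidates", {
  d <- tibble::tibble(x = rep(4, 10),
                      remitted = rep(c(TRUE, FALSE), 5))
  expect_equal(nrow(enumerate_cutpoints(d, "x")), 0L)
})

test_that("a feature missing for all subjects is an error", {
  d <- tibble::tibble(x = rep(NA_real_, 5), remitted = rep(TRUE, 5))
  expect_error(enumerate_cutpoints(d, "x"), "missing for all")
  expect_error(enumerate_cutpoints(d, "absent"), "not found")
})

test_that("candidate tables, kappa and p agree with brute force on a toy set", {
  withr::with_seed(5, d <- random_toy_instance())
  cand <- enumerate_cutpoints(d, "f1")
  for (i in seq_len(nrow(cand))) {
    v <- cand$threshold[i]
    ge <- d$f1 >= v
    tab <- rbind(c(sum(ge & !d$remitted), sum(ge & d$remitted)),
                 c(sum(!ge & !d$remitted), sum(!ge & d$remitted)))
    expect_equal(cand$n_ge_nonremit[i], tab[1, 1])
    expect_equal(cand$n_lt_remit[i], tab[2, 2])
    expect_equal(cand$kappa[i],
                 max(oracle_kappa(tab), oracle_kappa(tab[2:1, ])),
                 tolerance = 1e-12)
    expect_equal(cand$p_value[i], oracle_fisher(tab), tolerance = 1e-9)
  }
})

test_that("best_cutpoint equals the exhaustive brute-force maximizer", {
  withr::with_seed(20250901, {
    n_null <- 0
    for (rep in 1:60) {
      d <- random_toy_instance()
      feats <- setdiff(names(d), "remitted")
      got <- best_cutpoint(d, feats, alpha = 0.05)
      want <- oracle_best_cutpoint(d, feats, alpha = 0.05)
      if (is.null(want)) {
        n_null <- n_null + 1
        expect_null(got)
      } else {
        expect_false(is.null(got))
        expect_equal(got$feature, want$feature)
        expect_equal(got$threshold, want$threshold)
        expect_equal(got$direction, want$direction)
        expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
      }
    }
    # the generator must exercise both outcomes of the search
    expect_lt(n_null, 60)
  })
})

test_that("best_cutpoint returns NULL for a single-class subsample", {
  d <- tibble::tibble(x = 1:10, remitted = rep(TRUE, 10))
  expect_null(best_cutpoint(d, "x"))
  expect_error(best_cutpoint(d, character()), "at least one")
})

test_that("noise-free planted single split is recovered exactly", {
  d <- make_separable_cohort(n1 = 30, n2 = 30, n3 = 0)
  cut <- best_cutpoint(d, c("f1", paste0("noise", 1:8)))
  expect_equal(cut$feature, "f1")
  expect_equal(cut$threshold, 14.82)
  expect_equal(cut$kappa, 1)
})
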