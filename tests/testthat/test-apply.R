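test_that("routing follows stored thresholds with >= at the boundary", {
  d <- make_separable_cohort()
  tree <- build_tree(d, c("f1", "f2"))
  new <- tibble::tibble(
    subject_id = c("at", "just-below", "missing"),
    remitted = c(TRUE, FALSE, FALSE),
    f1 = c(14.82, 14.819, NA),
    f2 = c(1, 1, 1)
  )
  routed <- apply_tree(new, tree)
  nodes <- tidy(tree)
  ge_leaf <- nodes$node_id[nodes$side == "ge" & nodes$depth == 1]
  expect_equal(routed$.node_id[1], ge_leaf) # boundary goes to ">="
  expect_false(routed$.node_id[2] %in% ge_leaf)
  expect_true(is.na(routed$.node_id[3])) # unroutable -> unclassified
})

test_that("every routed subject reaches exactly one leaf and counts add up", {
  cohort <- simulate_cohort(ispotd_config(seed = 21))
  test <- cohort[cohort$cohort == "test", ]
  tree <- build_tree(test, "volumes")
  routed <- apply_tree(cohort[cohort$cohort == "validation", ], tree)
  leaf_ids <- tidy(tree)$node_id[tidy(tree)$is_leaf]
  expect_true(all(routed$.node_id %in% leaf_ids))
  expect_equal(sum(table(routed$.node_id)), nrow(routed))
  # idempotence
  routed2 <- apply_tree(cohort[cohort$cohort == "validation", ], tree)
  expect_identical(routed$.node_id, routed2$.node_id)
  # empty cohort
  expect_equal(nrow(apply_tree(cohort[0, ], tree)), 0L)
})

test_that("actionable rules are the >=80% non-remission paths", {
  d <- make_separable_cohort()
  tree <- build_tree(d, c("f1", "f2"))
  rules <- extract_actionable_rules(tree)
  # the only impure-enough node is the pure non-remitter leaf f1< & f2<
  expect_equal(nrow(rules), 1L)
  expect_equal(rules$accuracy, 1)
  cond <- rules$conditions[[1]]
  expect_equal(cond$feature, c("f1", "f2"))
  expect_equal(cond$op, c("<", "<"))
  expect_equal(nrow(extract_actionable_rules(tree, min_accuracy = 1.01)), 0L)
})

test_that("a qualifying ancestor subsumes its descendants' rules", {
  # all-non-remitter cohort at the root: the root rule selects everyone
  d <- make_separable_cohort()
  d$remitted <- FALSE
  tree <- build_tree(d, c("f1", "f2"))
  rules <- extract_actionable_rules(tree)
  expect_equal(nrow(rules), 1L)
  expect_equal(nrow(rules$conditions[[1]]), 0L) # the empty (root) path
  expect_true(all(apply_rules(d, rules)$.selected))
})

test_that("series is the intersection and parallel the union of selections", {
  pooled <- ispotd_pooled_cohort()
  vol <- ispotd_rules("volumetric")
  dti <- ispotd_rules("dti", "replicated")
  a <- apply_rules(pooled, vol)$.selected
  b <- apply_rules(pooled, dti)$.selected
  ser <- combine_series(pooled, vol, dti)$.selected
  par <- combine_parallel(pooled, vol, dti)$.selected
  expect_identical(ser, a & b)
  expect_identical(par, a | b)
  # order invariance
  expect_identical(ser, combine_series(pooled, dti, vol)$.selected)
  # containment and inclusion-exclusion
  expect_true(all(ser <= a) && all(ser <= b))
  expect_true(all(par >= a) && all(par >= b))
  expect_equal(sum(par), sum(a) + sum(b) - sum(ser))
})

test_that("the pooled fixture reproduces the published combination counts", {
  pooled <- ispotd_pooled_cohort()
  vol <- ispotd_rules("volumetric")
  dti <- ispotd_rules("dti", "replicated")
  ser <- evaluate_selection(combine_series(pooled, dti, vol))
  expect_equal(ser$n_selected, 10L)
  expect_equal(ser$n_correct, 10L) # no remitters selected in series
  par <- evaluate_selection(combine_parallel(pooled, dti, vol))
  expect_equal(par$n_selected, 76L)
  expect_equal(par$n_correct, 63L)
  expect_equal(round(100 * par$accuracy), 83)
})

test_that("set identities hold on random cohorts and rule pairs", {
  withr::with_seed(61, {
    for (i in 1:25) {
      n <- 40
      d <- tibble::tibble(
        remitted = as.logical(rbinom(n, 1, 0.4)),
        u = runif(n), v = runif(n)
      )
      ra <- tibble::tibble(rule_id = 1L, conditions = list(
        tibble::tibble(feature = "u", op = ">=", threshold = runif(1))))
      rb <- tibble::tibble(rule_id = 1L, conditions = list(
        tibble::tibble(feature = "v", op = "<", threshold = runif(1))))
      a <- apply_rules(d, ra)$.selected
      b <- apply_rules(d, rb)$.selected
      ser <- combine_series(d, ra, rb)$.selected
      par <- combine_parallel(d, ra, rb)$.selected
      expect_identical(ser, combine_series(d, rb, ra)$.selected)
      expect_equal(sum(par), sum(a) + sum(b) - sum(ser))
      expect_true(all(ser <= par))
    }
  })
})

test_that("disjoint selections combine to an empty series", {
  d <- tibble::tibble(remitted = rep(FALSE, 10), x = 1:10)
  lo <- tibble::tibble(rule_id = 1L, conditions = list(
    tibble::tibble(feature = "x", op = "<", threshold = 4)))
  hi <- tibble::tibble(rule_id = 1L, conditions = list(
    tibble::tibble(feature = "x", op = ">=", threshold = 8)))
  expect_equal(sum(combine_series(d, lo, hi)$.selected), 0L)
  expect_error(combine_series(d, lo, lo[0, ]), "non-empty")
})
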