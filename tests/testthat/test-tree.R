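test_that("a noise-free depth-2 planted tree is recovered identically", {
  d <- make_separable_cohort()
  tree <- build_tree(d, c("f1", "f2", paste0("noise", 1:8)))
  nodes <- tidy(tree)
  root <- nodes[nodes$depth == 0, ]
  expect_equal(root$feature, "f1")
  expect_equal(root$threshold, 14.82)
  second <- nodes[nodes$depth == 1 & !nodes$is_leaf, ]
  expect_equal(nrow(second), 1L)
  expect_equal(second$side, "lt") # the low-volume branch splits again
  expect_equal(second$feature, "f2")
  expect_equal(second$threshold, 6.25)
  # leaves are pure, so nothing splits further
  expect_equal(max(nodes$depth), 2L)
})

test_that("a draconian alpha yields a single leaf", {
  d <- make_separable_cohort(n1 = 10, n2 = 6, n3 = 6)
  tree <- build_tree(d, c("f1", "f2"), alpha = 1e-12)
  expect_equal(nrow(tidy(tree)), 1L)
  expect_true(tidy(tree)$is_leaf)
})

test_that("counts are conserved and stopping is sound at every split", {
  cohort <- simulate_cohort(ispotd_config(seed = 3))
  tree <- build_tree(cohort[cohort$cohort == "test", ], "volumes")
  nodes <- tidy(tree)
  for (i in which(!nodes$is_leaf)) {
    kids <- nodes[!is.na(nodes$parent_id) &
                    nodes$parent_id == nodes$node_id[i], ]
    expect_equal(nrow(kids), 2L)
    expect_equal(sum(kids$n_remit), nodes$n_remit[i])
    expect_equal(sum(kids$n_nonremit), nodes$n_nonremit[i])
    expect_lt(nodes$p_value[i], tree$alpha)
    # strictly decreasing subject counts along every path
    expect_true(all(kids$n_remit + kids$n_nonremit <
                      nodes$n_remit[i] + nodes$n_nonremit[i]))
  }
  expect_equal(nodes$p_remission,
               nodes$n_remit / (nodes$n_remit + nodes$n_nonremit))
})

test_that("fitting is deterministic", {
  d <- make_separable_cohort(seed = 7)
  t1 <- build_tree(d, c("f1", "f2", "noise1", "noise2"))
  t2 <- build_tree(d, c("f1", "f2", "noise1", "noise2"))
  expect_identical(tidy(t1), tidy(t2))
})

test_that("the study-structure simulation recovers the volumetric root", {
  hits <- 0
  runs <- 12
  for (s in seq_len(runs)) {
    cohort <- simulate_cohort(ispotd_config(seed = 1000 + s))
    tree <- build_tree(cohort[cohort$cohort == "test", ], "volumes")
    root <- tidy(tree)[1, ]
    if (!root$is_leaf && root$feature == "Frontal_Mid_L") hits <- hits + 1
  }
  # recovery is stochastic at n = 76 with 116 candidate regions, but the
  # planted signal should dominate in most runs
  expect_gte(hits, ceiling(runs / 2))
})

test_that("high-contrast planted roots are recovered with localized thresholds", {
  # depth-2 planted tree with 0.9 / 0.1 leaf remission rates; the
  # recovered cut-point should identify the planted region and sit
  # close to the planted threshold (exactly flanking it only when the
  # labels are noise-free, which the depth-2 identity test covers)
  cfg <- cohort_config(
    cohorts = list(test = cohort_spec(
      "test", n = 150L,
      planted = list(volumetric = planted_tree(
        tibble::tibble(feature = c("Frontal_Mid_L", "Angular_R"),
                       threshold = c(14.82, 6.25),
                       leaf_side = c("ge", "lt"),
                       leaf_p = c(0.9, 0.1), leaf_n = c(65L, 28L)),
        final_p = 0.1, final_n = 57L
      ))
    )),
    feature_means = c(Frontal_Mid_L = 14.8, Angular_R = 6.3),
    feature_sds = c(Frontal_Mid_L = 2.2, Angular_R = 1.0)
  )
  hits <- 0
  runs <- 25
  for (s in seq_len(runs)) {
    cohort <- simulate_cohort(cfg, seed = 30000 + s)
    root <- tidy(build_tree(cohort, recovery_features()))[1, ]
    if (!root$is_leaf && root$feature == "Frontal_Mid_L") {
      hits <- hits + 1
      expect_lt(abs(root$threshold - 14.82), 1) # well inside the support
    }
  }
  expect_gte(hits, ceiling(0.95 * runs))
})

test_that("tree summaries and plots are well formed", {
  d <- make_separable_cohort()
  tree <- build_tree(d, c("f1", "f2"))
  g <- glance(tree)
  expect_equal(g$n, nrow(d))
  expect_equal(g$n_leaves, g$n_nodes - sum(!tidy(tree)$is_leaf))
  expect_s3_class(autoplot(tree), "ggplot")
  expect_output(print(tree), "ROC recursive-partitioning tree")
})
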