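test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- ispotd_config()
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(
    readr::format_csv(a),
    readr::format_csv(b)
  )
  c <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(readr::format_csv(a), readr::format_csv(c)))
})

test_that("the study configuration reproduces the published structure", {
  cfg <- ispotd_config(seed = 2, label_mode = "exact")
  expect_equal(planted_thresholds(cfg$cohorts$test$planted$volumetric),
               c(14.82, 6.25))
  expect_equal(planted_thresholds(cfg$cohorts$test$planted$dti),
               c(0.63, 0.54, 0.50))
  cohort <- simulate_cohort(cfg)
  test <- cohort[cohort$cohort == "test", ]
  validation <- cohort[cohort$cohort == "validation", ]
  expect_equal(nrow(test), 76L)
  expect_equal(nrow(validation), 83L)
  # two test subjects lack the DTI scan
  expect_equal(sum(!is.na(test$Cingulum_cingulate_gyrus_L)), 74L)
  # exact label mode reproduces the printed remitter totals
  expect_equal(sum(test$remitted), 35L)       # 25 + 7 + 3
  expect_equal(sum(validation$remitted), 20L) # 10 + 3 + 7
  # the planted volumetric leaves have their target compositions
  sel <- test$Frontal_Mid_L < 14.82 & test$Angular_R >= 6.25
  expect_equal(sum(sel), 29L)
  expect_equal(sum(sel & !test$remitted), 26L)
  vsel <- validation$Frontal_Mid_L < 14.82 & validation$Angular_R >= 6.25
  expect_equal(sum(vsel), 38L)
  expect_equal(sum(vsel & !validation$remitted), 31L)
})

test_that("remission labels are marginally unbiased for the configured rate", {
  cfg <- cohort_config(
    cohorts = list(test = cohort_spec("test", n = 74, remission_rate = 0.46))
  )
  reps <- 60
  remitters <- vapply(seq_len(reps), function(s) {
    sum(simulate_cohort(cfg, seed = 5000 + s)$remitted)
  }, numeric(1))
  # mean remitter count within 4 binomial standard errors of 0.46 * 74
  se <- sqrt(74 * 0.46 * 0.54 / reps)
  expect_lt(abs(mean(remitters) - 0.46 * 74), 4 * se)
})

test_that("planted leaf remission rates are honoured at scale", {
  cfg <- cohort_config(
    cohorts = list(test = cohort_spec(
      "test", n = 1000,
      planted = list(volumetric = planted_tree(
        tibble::tibble(feature = "Frontal_Mid_L", threshold = 12,
                       leaf_side = "ge", leaf_p = 0.90, leaf_n = 500L),
        final_p = 0.10, final_n = 500L
      ))
    ))
  )
  cohort <- simulate_cohort(cfg, seed = 31)
  ge <- cohort$Frontal_Mid_L >= 12
  expect_equal(sum(ge), 500L)
  se <- sqrt(0.9 * 0.1 / 500)
  expect_lt(abs(mean(cohort$remitted[ge]) - 0.90), 3 * se)
  expect_lt(abs(mean(cohort$remitted[!ge]) - 0.10), 3 * se)
})

test_that("noise features are independent of the label", {
  cfg <- recovery_config()
  cors <- vapply(1:30, function(s) {
    cohort <- simulate_cohort(cfg, seed = 7000 + s)
    cor(cohort$Precentral_L, as.numeric(cohort$remitted))
  }, numeric(1))
  # point-biserial correlation centred at zero across simulations
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)))
})

test_that("noise-free 0/1 leaves make the planted split perfectly separating", {
  cfg <- cohort_config(
    cohorts = list(test = cohort_spec(
      "test", n = 80,
      planted = list(volumetric = planted_tree(
        tibble::tibble(feature = "Frontal_Mid_L", threshold = 12,
                       leaf_side = "ge", leaf_p = 1, leaf_n = 40L),
        final_p = 0, final_n = 40L
      ))
    ))
  )
  cohort <- simulate_cohort(cfg, seed = 8)
  ge <- cohort$Frontal_Mid_L >= 12
  tab <- rbind(c(sum(ge & !cohort$remitted), sum(ge & cohort$remitted)),
               c(sum(!ge & !cohort$remitted), sum(!ge & cohort$remitted)))
  expect_equal(kappa_2x2(tab[2:1, ]), 1) # lt branch predicts non-remission
})

test_that("labels always satisfy the week-8 remission criterion", {
  cohort <- simulate_cohort(ispotd_config(seed = 55))
  expect_identical(cohort$remitted, cohort$hrsd17_week8 <= 7)
  fa <- as.matrix(cohort[, atlas_labels("jhu46")])
  expect_true(all(is.na(fa) | (fa >= 0 & fa <= 1)))
  vol <- as.matrix(cohort[, atlas_labels("aal116")])
  expect_true(all(is.na(vol) | vol > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_spec("t", n = 10), "remission_rate")
  expect_error(
    cohort_spec("t", n = 10, planted = list(v = planted_tree(
      tibble::tibble(feature = "Frontal_Mid_L", threshold = 12,
                     leaf_side = "ge", leaf_p = 1, leaf_n = 4L),
      final_p = 0, final_n = 4L
    ))),
    "sum to `n`"
  )
  expect_error(
    cohort_config(cohorts = list(t = cohort_spec(
      "t", n = 4,
      planted = list(v = planted_tree(
        tibble::tibble(feature = "NotARegion", threshold = 1,
                       leaf_side = "ge", leaf_p = 1, leaf_n = 2L),
        final_p = 0, final_n = 2L
      ))
    ))),
    "atlas label lists"
  )
})
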