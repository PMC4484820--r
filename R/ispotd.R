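#' Published decision rules of the iSPOT-D structural-MRI study
#'
#' The actionable non-remission rules reported by the study, as rule
#' tables in the [extract_actionable_rules()] layout:
#'
#' * volumetric: left middle frontal gyrus volume < 14.82 mL and right
#'   angular gyrus volume >= 6.25 mL (26/29 non-remitters in the test
#'   cohort);
#' * DTI path 1: left cingulum (cingulate) FA < 0.63 and right superior
#'   fronto-occipital fasciculus FA >= 0.54 (18/20);
#' * DTI path 2: the same plus right superior longitudinal fasciculus
#'   FA < 0.50 (11/13).  Only path 2 replicated in the validation
#'   cohort, so `which = "replicated"` returns path 2 alone — the rule
#'   the pooled-cohort and combination analyses use.
#'
#' @param modality `"volumetric"` or `"dti"`.
#' @param which For `"dti"`: `"all"` (both paths) or `"replicated"`
#'   (path 2 only).  Ignored for `"volumetric"`.
#' @return A rule tibble: `rule_id`, `n_nonremit`, `n_remit`,
#'   `accuracy`, `path`, and a `conditions` list-column of
#'   `(feature, op, threshold)` tables.
#' @examples
#' ispotd_rules("volumetric")$path
#' @export
ispotd_rules <- function(modality = c("volumetric", "dti"),
                         which = c("all", "replicated")) {
  modality <- match.arg(modality)
  which <- match.arg(which)
  cond <- function(feature, op, threshold) {
    tibble::tibble(feature = feature, op = op, threshold = threshold)
  }
  if (modality == "volumetric") {
    rules <- tibble::tibble(
      rule_id = 1L, n_nonremit = 26L, n_remit = 3L, accuracy = 26 / 29,
      path = "Frontal_Mid_L < 14.82 & Angular_R >= 6.25",
      conditions = list(cond(c("Frontal_Mid_L", "Angular_R"),
                             c("<", ">="), c(14.82, 6.25)))
    )
    return(rules)
  }
  rules <- tibble::tibble(
    rule_id = 1:2,
    n_nonremit = c(18L, 11L), n_remit = c(2L, 2L),
    accuracy = c(18 / 20, 11 / 13),
    path = c(
      "Cingulum_cingulate_gyrus_L < 0.63 & Superior_fronto_occipital_fasciculus_R >= 0.54",
      "Cingulum_cingulate_gyrus_L < 0.63 & Superior_fronto_occipital_fasciculus_R < 0.54 & Superior_longitudinal_fasciculus_R < 0.50"
    ),
    conditions = list(
      cond(c("Cingulum_cingulate_gyrus_L",
             "Superior_fronto_occipital_fasciculus_R"),
           c("<", ">="), c(0.63, 0.54)),
      cond(c("Cingulum_cingulate_gyrus_L",
             "Superior_fronto_occipital_fasciculus_R",
             "Superior_longitudinal_fasciculus_R"),
           c("<", "<", "<"), c(0.63, 0.54, 0.50))
    )
  )
  if (which == "replicated") rules[2, ] else rules
}

#' Deterministic pooled cohort reproducing the published selection counts
#'
#' Builds a synthetic pooled cohort (74 test + 83 validation subjects)
#' whose joint membership in the volumetric and DTI rule selections
#' reproduces, by construction, every selection count the study reports:
#' 26/29 (test) and 31/38 (validation) for the volumetric rule, 11/13
#' and 5/6 for the replicated DTI path, their serial intersection (10
#' subjects, all non-remitters) and parallel union (76 subjects, 63
#' non-remitters), and the pooled totals of 103 non-remitters among 157
#' subjects.
#'
#' The union/intersection compositions are implied uniquely by the
#' reported margins; the split of the 10-subject overlap across cohorts
#' (7 test / 3 validation) and all feature values off the decision paths
#' are synthetic choices.  Every subject carries both modalities here
#' (the study's two test-cohort subjects without DTI are represented in
#' [ispotd_config()], not in this fixed table).
#'
#' @return A cohort tibble in the [simulate_cohort()] layout (no
#'   randomness; calling it twice gives identical tables).
#' @examples
#' pooled <- ispotd_pooled_cohort()
#' table(pooled$cohort, pooled$remitted)
#' @export
ispotd_pooled_cohort <- function() {
  # category: both rules / volumetric only / DTI only / neither,
  # by cohort and remission status
  cat_tab <- tibble::tibble(
    cohort = rep(c("test", "validation"), each = 8L),
    group  = rep(rep(c("both", "vol", "dti", "none"), each = 2L), 2L),
    remitted = rep(c(TRUE, FALSE), 8L),
    count = c(
      0L, 7L,  3L, 19L,  2L, 4L,  29L, 10L, # test: 34 R / 40 NR
      0L, 3L,  7L, 28L,  1L, 2L,  12L, 30L  # validation: 20 R / 63 NR
    )
  )
  rows <- cat_tab[rep(seq_len(nrow(cat_tab)), cat_tab$count), ]
  n <- nrow(rows)

  vol_feats <- atlas_labels("aal116")
  fa_feats <- atlas_labels("jhu46")
  feats <- matrix(rep(c(rep(10, length(vol_feats)), rep(0.5, length(fa_feats))),
                      each = n),
                  nrow = n, dimnames = list(NULL, c(vol_feats, fa_feats)))
  in_vol <- rows$group %in% c("both", "vol")
  in_dti <- rows$group %in% c("both", "dti")
  feats[, "Frontal_Mid_L"] <- ifelse(in_vol, 13.0, 16.0)
  feats[, "Angular_R"] <- 7.0
  feats[, "Cingulum_cingulate_gyrus_L"] <- ifelse(in_dti, 0.55, 0.70)
  feats[, "Superior_fronto_occipital_fasciculus_R"] <- 0.45
  feats[, "Superior_longitudinal_fasciculus_R"] <- 0.40

  tibble::tibble(
    subject_id = sprintf("pooled-%03d", seq_len(n)),
    cohort = rows$cohort,
    remitted = rows$remitted,
    tibble::as_tibble(feats),
    age = 35,
    sex = 0L,
    hrsd17_baseline = 21,
    hrsd17_week8 = ifelse(rows$remitted, 5, 13),
    melancholic = FALSE,
    prior_treatment = FALSE,
    arm = "escitalopram",
    dose_mg_day = 13
  )
}
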