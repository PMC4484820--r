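#' Region and tract label lists
#'
#' The feature columns of a cohort table are named after the parcellation
#' they come from: 116 gray-matter regions of the Automated Anatomical
#' Labeling (AAL) atlas for the volumetric measures (mL), and 46 major
#' white-matter tracts of the JHU ICBM-DTI-81 atlas for the mean
#' fractional-anisotropy (FA) measures.  The label lists ship with the
#' package as plain-text files and are the authoritative column schema for
#' [read_cohort()] and [simulate_cohort()].
#'
#' @param atlas `"aal116"` (gray-matter regions) or `"jhu46"` (white-matter
#'   tracts).
#' @return Character vector of feature names, in atlas order.
#' @examples
#' length(atlas_labels("aal116")) # 116
#' head(atlas_labels("jhu46"))
#' @export
atlas_labels <- function(atlas = c("aal116", "jhu46")) {
  atlas <- match.arg(atlas)
  file <- switch(atlas,
    aal116 = "aal116_labels.txt",
    jhu46  = "jhu_icbm_dti81_labels.txt"
  )
  path <- system.file("extdata", file, package = "roctree", mustWork = TRUE)
  readLines(path)
}

#' Clinical and demographic covariate column names
#'
#' The non-imaging candidate predictors carried in a cohort table: age,
#' sex, baseline and week-8 depression severity (17-item Hamilton Rating
#' Scale, HRSD17), melancholic subtype, previous antidepressant treatment,
#' randomized treatment arm and daily dose.
#'
#' @return Character vector of column names.
#' @export
clinical_columns <- function() {
  c("age", "sex", "hrsd17_baseline", "hrsd17_week8",
    "melancholic", "prior_treatment", "arm", "dose_mg_day")
}

# Clinical columns usable as candidate split predictors (numeric or 0/1).
clinical_predictors <- function() {
  c("age", "sex", "hrsd17_baseline", "melancholic", "prior_treatment",
    "dose_mg_day")
}
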