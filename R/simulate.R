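#' Simulate a synthetic study cohort
#'
#' Generates per-subject feature tables with the statistical structure
#' the partitioning analysis assumes: 116 AAL-atlas gray-matter region
#' volumes, 46 JHU ICBM-DTI-81 tract FA values, demographic/clinical
#' covariates and a binary remission label.  When a cohort carries
#' planted decision trees, subjects are first assigned to planted leaves
#' (exactly matching the leaf target counts), the remission label is
#' drawn from the label-driving tree's leaf probabilities, the other
#' modality's leaf membership is drawn conditional on the label, and
#' each split feature is drawn from a normal distribution truncated to
#' the leaf's side of the threshold.  All non-split ("noise") features
#' are drawn independently of the label.  A planted tree whose leaf
#' counts sum to less than the cohort size leaves the remaining subjects
#' with that modality missing (`NA` features), emulating subjects
#' without a usable scan.
#'
#' The remission label always satisfies the clinical definition:
#' `remitted == (hrsd17_week8 <= 7)` (17-item Hamilton depression score
#' at week 8 of treatment).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed overriding `config$seed`.  The whole cohort
#'   is governed by this one seed (Mersenne-Twister); identical
#'   config + seed is bit-identical.
#' @return A tibble with one row per subject: `subject_id`, `cohort`,
#'   `remitted`, the 116 volume columns, the 46 FA columns, and the
#'   clinical covariates ([clinical_columns()]).  The generator
#'   algorithm and seed are recorded in the `"generator"` attribute.
#' @examples
#' cohort <- simulate_cohort(ispotd_config(seed = 42))
#' dplyr::count(cohort, cohort, remitted)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a `cohort_config`.")
  }
  seed <- seed %||% config$seed
  out <- with_rng(seed, {
    dplyr::bind_rows(lapply(config$cohorts, simulate_one_cohort,
                            config = config))
  })
  attr(out, "generator") <- list(
    algorithm = "Mersenne-Twister",
    seed = seed,
    version = as.character(utils::packageVersion("roctree"))
  )
  out
}

simulate_one_cohort <- function(spec, config) {
  n <- spec$n
  vol_feats <- atlas_labels("aal116")
  fa_feats <- atlas_labels("jhu46")

  # -- leaf assignment and labels -------------------------------------
  assign_by <- list() # modality -> integer leaf id per subject (NA = missing)
  if (length(spec$planted) > 0L) {
    lab_tree <- spec$planted[[spec$label_from]]
    lv <- planted_leaves(lab_tree)
    leaf <- sample(rep.int(lv$leaf_id, lv$n))
    assign_by[[spec$label_from]] <- leaf
    p <- lv$p_remission[leaf]
    remitted <- if (config$label_mode == "exact") {
      exact_labels_by_group(leaf, lv$leaf_id, round(lv$p_remission * lv$n))
    } else {
      runif(n) < p
    }
  } else {
    remitted <- if (config$label_mode == "exact") {
      sample(seq_len(n)) <= round(spec$remission_rate * n)
    } else {
      runif(n) < spec$remission_rate
    }
  }
  if (config$label_noise > 0) {
    flip <- runif(n) < config$label_noise
    remitted <- xor(remitted, flip)
  }

  # -- secondary planted trees: leaf membership conditional on label --
  for (modality in setdiff(names(spec$planted), spec$label_from)) {
    tree <- spec$planted[[modality]]
    lv <- planted_leaves(tree)
    exp_r <- lv$p_remission * lv$n
    exp_nr <- (1 - lv$p_remission) * lv$n
    n_missing <- n - sum(lv$n)
    leaf <- rep(NA_integer_, n)
    avail <- seq_len(n)
    if (n_missing > 0L) {
      # drop subjects so the remaining label mix matches the tree's
      # implied composition as closely as possible
      want_r <- max(0L, min(sum(remitted), n_missing,
                            round(sum(remitted) - sum(exp_r))))
      want_nr <- n_missing - want_r
      if (want_nr > sum(!remitted) || want_nr < 0L) {
        want_nr <- max(0L, min(sum(!remitted), n_missing))
        want_r <- n_missing - want_nr
      }
      miss <- c(resample(which(remitted), want_r),
                resample(which(!remitted), want_nr))
      avail <- setdiff(avail, miss)
    }
    for (is_r in c(TRUE, FALSE)) {
      idx <- avail[remitted[avail] == is_r]
      w <- if (is_r) exp_r else exp_nr
      if (sum(w) <= 0) w <- lv$n
      leaf[idx] <- sample(lv$leaf_id, length(idx), replace = TRUE,
                          prob = w / sum(w))
    }
    assign_by[[modality]] <- leaf
  }

  # -- imaging features ------------------------------------------------
  feats <- matrix(NA_real_, nrow = n,
                  ncol = length(vol_feats) + length(fa_feats),
                  dimnames = list(NULL, c(vol_feats, fa_feats)))
  constrained <- constraint_bounds(spec, assign_by, n)
  for (f in c(vol_feats, fa_feats)) {
    is_vol <- f %in% vol_feats
    dom <- if (is_vol) c(0, Inf) else c(0, 1)
    mu <- feature_mean(f, spec, config, is_vol)
    sg <- feature_sd(f, config, is_vol)
    lower <- rep(dom[1], n)
    upper <- rep(dom[2], n)
    present <- rep(TRUE, n)
    modality <- if (is_vol) "volumetric" else "dti"
    if (modality %in% names(assign_by)) {
      present <- !is.na(assign_by[[modality]])
    }
    if (f %in% names(constrained)) {
      b <- constrained[[f]]
      lower <- pmax(lower, b$lower)
      upper <- pmin(upper, b$upper)
    }
    x <- rtnorm(n, mu, sg, lower, upper)
    x[!present] <- NA_real_
    feats[, f] <- x
  }

  # -- clinical covariates --------------------------------------------
  arm <- sample(c("escitalopram", "sertraline", "venlafaxine"), n,
                replace = TRUE)
  dose_mu <- c(escitalopram = 13, sertraline = 61, venlafaxine = 100)
  dose_sd <- c(escitalopram = 5, sertraline = 27, venlafaxine = 35)
  hrsd8 <- numeric(n)
  hrsd8[remitted] <- round(rtnorm(sum(remitted), 4.9, 1.9, 0, 7))
  hrsd8[!remitted] <- round(rtnorm(sum(!remitted), 13.0, 3.6, 8, 40))

  tibble::tibble(
    subject_id = sprintf("%s-%03d", spec$name, seq_len(n)),
    cohort = spec$name,
    remitted = as.logical(remitted),
    tibble::as_tibble(feats),
    age = round(rtnorm(n, 34, 12, 18, 75), 1),
    sex = rbinom(n, 1L, 0.5),
    hrsd17_baseline = round(rtnorm(n, 21.5, 3.5, 16, 34)),
    hrsd17_week8 = hrsd8,
    melancholic = runif(n) < 0.2,
    prior_treatment = runif(n) < 0.45,
    arm = arm,
    dose_mg_day = round(rtnorm(n, dose_mu[arm], dose_sd[arm], 1, Inf))
  )
}

# sample() without the length-1 surprise
resample <- function(x, size) x[sample.int(length(x), size)]

# exactly k_g remitters within each group g, placed at random
exact_labels_by_group <- function(group, group_ids, k) {
  out <- logical(length(group))
  for (i in seq_along(group_ids)) {
    idx <- which(group == group_ids[i])
    out[resample(idx, min(k[i], length(idx)))] <- TRUE
  }
  out
}

# Per-feature truncation bounds implied by planted-leaf membership.
constraint_bounds <- function(spec, assign_by, n) {
  out <- list()
  for (modality in names(spec$planted)) {
    tree <- spec$planted[[modality]]
    lv <- planted_leaves(tree)
    leaf <- assign_by[[modality]]
    for (i in seq_len(nrow(lv))) {
      in_leaf <- !is.na(leaf) & leaf == lv$leaf_id[i]
      if (!any(in_leaf)) next
      for (cond in lv$conditions[[i]]) {
        f <- cond$feature
        if (is.null(out[[f]])) {
          out[[f]] <- list(lower = rep(-Inf, n), upper = rep(Inf, n))
        }
        if (cond$op == ">=") {
          out[[f]]$lower[in_leaf] <- pmax(out[[f]]$lower[in_leaf],
                                          cond$threshold)
        } else {
          # strict "<" realized as an open upper bound; continuous draws
          # hit the boundary with probability 0
          out[[f]]$upper[in_leaf] <- pmin(out[[f]]$upper[in_leaf],
                                          cond$threshold)
        }
      }
    }
  }
  out
}

feature_mean <- function(f, spec, config, is_vol) {
  if (!is.null(config$feature_means) && f %in% names(config$feature_means)) {
    return(unname(config$feature_means[f]))
  }
  # planted split features center on their threshold so both sides of
  # the split are populated
  for (tree in spec$planted) {
    idx <- match(f, planted_features(tree))
    if (!is.na(idx)) return(planted_thresholds(tree)[idx])
  }
  if (is_vol) config$volume_mean else config$fa_mean
}

feature_sd <- function(f, config, is_vol) {
  if (!is.null(config$feature_sds) && f %in% names(config$feature_sds)) {
    return(unname(config$feature_sds[f]))
  }
  if (is_vol) config$volume_sd else config$fa_sd
}
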