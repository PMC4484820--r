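#' Exact binomial replication test against a reference accuracy
#'
#' One-sided lower-tail exact binomial probability
#' `P(X <= successes | n, p0)`: the chance of observing at most the
#' achieved number of correct classifications if the rule truly
#' performed at the reference accuracy `p0`.  Used to ask whether a
#' rule's validation-cohort accuracy is significantly *below* its
#' test-cohort accuracy (e.g. 9 of 13 correct against a 90% reference
#' gives p = 0.034).
#'
#' @param successes Number of correct classifications observed.
#' @param n Number of subjects the rule was applied to.
#' @param p0 Reference accuracy in (0, 1).
#' @return The exact lower-tail probability.
#' @examples
#' binom_test_vs_reference(9, 13, 0.90) # 0.034
#' @export
binom_test_vs_reference <- function(successes, n, p0) {
  check_count(successes, "successes")
  check_count(n, "n")
  if (n < 1L) abort("`n` must be at least 1.")
  if (successes > n) abort("`successes` cannot exceed `n`.")
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) abort("`p0` must lie in (0, 1).")
  pbinom(successes, n, p0)
}

#' Exact binomial test against chance non-remission
#'
#' One-sided upper-tail exact binomial probability
#' `P(X >= n_correct | n_selected, 1 - chance_remission)`: the chance
#' that a rule selecting subjects at random from a population with the
#' given remission rate would classify at least this many non-remitters
#' correctly.  The default chance remission rate of 35% is the
#' prevalence observed across large antidepressant trials.
#'
#' @param n_correct Non-remitters among the selected subjects.
#' @param n_selected Number of subjects selected by the rule.
#' @param chance_remission Population remission rate defining chance
#'   performance (default 0.35).
#' @return The exact upper-tail probability.
#' @examples
#' chance_test(26, 29) # < 0.01
#' @export
chance_test <- function(n_correct, n_selected, chance_remission = 0.35) {
  check_count(n_correct, "n_correct")
  check_count(n_selected, "n_selected")
  if (n_correct > n_selected) abort("`n_correct` cannot exceed `n_selected`.")
  if (chance_remission <= 0 || chance_remission >= 1) {
    abort("`chance_remission` must lie in (0, 1).")
  }
  pbinom(n_correct - 1, n_selected, 1 - chance_remission,
         lower.tail = FALSE)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square with 1 degree of freedom and no continuity
#' correction, as used for the categorical rows of the group
#' characterization table.
#'
#' @param table 2x2 matrix of non-negative counts with all margins
#'   positive.
#' @return A tibble with `statistic` and `p_value`.
#' @examples
#' chi2_2x2(matrix(c(6, 12, 51, 34), 2)) # statistic 4.27
#' @export
chi2_2x2 <- function(table) {
  table <- check_2x2(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("All margins of `table` must be positive.")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric enumeration with the
#' probability-ordering rule (all tables with the observed margins whose
#' probability does not exceed the observed table's contribute).  This
#' is the significance test gating candidate splits during
#' partitioning, and the replication test for individual cut-points.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided exact p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)) # 1/3
#' @export
fisher_exact_2x2 <- function(table) {
  table <- check_2x2(table)
  if (sum(table) == 0) return(1)
  stats::fisher.test(table)$p.value
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != round(x)) {
    abort(paste0("`", name, "` must be a single non-negative integer."))
  }
}

check_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("`table` must be 2x2.")
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    abort("`table` entries must be non-negative integers.")
  }
  table
}

#' Evaluate a rule selection against the remission outcome
#'
#' Summarizes a selection produced by [apply_rules()],
#' [combine_series()] or [combine_parallel()]: how many subjects the
#' non-remission rules selected, how many of them truly failed to remit
#' (`accuracy`, the study's "specificity" of the rule-out test), what
#' fraction of all non-remitters were captured (`coverage`), and exact
#' binomial tests against a reference accuracy and against chance.
#'
#' @param data Data frame carrying a logical `.selected` column and the
#'   outcome column.
#' @param reference_accuracy Optional accuracy to test against with
#'   [binom_test_vs_reference()] (e.g. the test-cohort accuracy of the
#'   same rule).
#' @param chance_remission Chance remission rate for [chance_test()];
#'   `NULL` to skip.
#' @param outcome Name of the logical remission column.
#' @return A one-row tibble: `n`, `n_selected`, `n_correct`,
#'   `accuracy`, `n_nonremitters`, `coverage`, `p_vs_reference`,
#'   `p_vs_chance`.
#' @examples
#' ispotd_pooled_cohort() |>
#'   apply_rules(ispotd_rules("volumetric")) |>
#'   evaluate_selection()
#' @export
evaluate_selection <- function(data, reference_accuracy = NULL,
                               chance_remission = 0.35,
                               outcome = "remitted") {
  if (!".selected" %in% names(data)) {
    abort("`data` must carry a `.selected` column (see `apply_rules()`).")
  }
  sel <- data$.selected
  nr <- !as.logical(data[[outcome]])
  n_selected <- sum(sel)
  n_correct <- sum(sel & nr)
  accuracy <- if (n_selected > 0) n_correct / n_selected else NA_real_
  n_nonrem <- sum(nr)
  coverage <- if (n_nonrem > 0) n_correct / n_nonrem else NA_real_
  p_ref <- if (is.null(reference_accuracy) || n_selected == 0) {
    NA_real_
  } else if (reference_accuracy >= 1) {
    # degenerate reference (a pure node): P(X <= k | p0 = 1) is an
    # indicator of a perfect validation score
    as.numeric(n_correct == n_selected)
  } else if (reference_accuracy <= 0) {
    1
  } else {
    binom_test_vs_reference(n_correct, n_selected, reference_accuracy)
  }
  p_chance <- if (!is.null(chance_remission) && n_selected > 0) {
    chance_test(n_correct, n_selected, chance_remission)
  } else NA_real_
  tibble::tibble(
    n = nrow(data), n_selected = n_selected, n_correct = n_correct,
    accuracy = accuracy, n_nonremitters = n_nonrem, coverage = coverage,
    p_vs_reference = p_ref, p_vs_chance = p_chance
  )
}

#' Compare two subject groups variable by variable
#'
#' Emulates the study's group characterization table: continuous
#' variables are compared with an independent two-sample t-test
#' (pooled-variance by default, era-typical; Welch via
#' `var_equal = FALSE`), binary variables with the Pearson chi-square
#' test ([chi2_2x2()]).  No multiple-testing correction is applied.
#'
#' @param data Data frame of subjects.
#' @param group Name of a column with exactly two distinct values.
#' @param variables Character vector of columns to compare.  Logical
#'   and two-valued columns are treated as binary, numeric columns as
#'   continuous.
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @return A tibble with one row per variable: `variable`, `type`,
#'   per-group summary (`mean_1`, `mean_2` — proportions for binary
#'   variables), `statistic` and `p_value`.
#' @export
compare_groups <- function(data, group, variables, var_equal = TRUE) {
  g <- data[[group]]
  if (is.null(g)) abort(paste0("Column `", group, "` not found."))
  levels <- sort(unique(g[!is.na(g)]))
  if (length(levels) != 2L) abort("`group` must have exactly two levels.")
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    if (is.null(x)) abort(paste0("Column `", v, "` not found."))
    x1 <- x[g == levels[1] & !is.na(x)]
    x2 <- x[g == levels[2] & !is.na(x)]
    binary <- is.logical(x) || is.character(x) || is.factor(x) ||
      length(unique(c(x1, x2))) <= 2L
    if (binary) {
      if (!is.logical(x)) {
        uv <- sort(unique(c(x1, x2)))
        if (length(uv) > 2L) {
          abort(paste0("Column `", v, "` has more than two levels."))
        }
        x1 <- x1 == uv[length(uv)]
        x2 <- x2 == uv[length(uv)]
      }
      tab <- matrix(c(sum(x1), sum(x2), sum(!x1), sum(!x2)), nrow = 2)
      res <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        tibble::tibble(statistic = 0, p_value = 1)
      } else {
        chi2_2x2(tab)
      }
      tibble::tibble(
        variable = v, type = "binary",
        mean_1 = mean(x1), mean_2 = mean(x2),
        statistic = res$statistic, p_value = res$p_value
      )
    } else {
      ht <- t.test(x1, x2, var.equal = var_equal)
      tibble::tibble(
        variable = v, type = "continuous",
        mean_1 = mean(x1), mean_2 = mean(x2),
        statistic = unname(ht$statistic), p_value = ht$p.value
      )
    }
  })
}
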