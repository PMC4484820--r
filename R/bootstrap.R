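#' Subsampling cross-validation of rule specificity
#'
#' The study's bias check for the unequal remission rates of its two
#' cohorts: draw many random subsamples from the pooled cohort, apply a
#' *fixed* non-remission rule set to each, and record per subsample the
#' specificity (proportion of true non-remitters among the selected
#' subjects) and coverage (proportion of the subsample's non-remitters
#' that were selected).  Defaults are 1000 iterations of 100 subjects
#' drawn without replacement, as in the study.
#'
#' Iterations in which the rule selects nobody have undefined
#' specificity; they are recorded as `NA`, excluded from the summaries
#' and counted (`n_undefined_specificity`).  Likewise for coverage when
#' a subsample contains no non-remitter.
#'
#' @param data Pooled cohort data frame.
#' @param rules A rule tibble ([extract_actionable_rules()],
#'   [ispotd_rules()]) or a fitted `roc_tree` (its actionable rules at
#'   the 80% bar are used).
#' @param n_iter Number of subsamples (default 1000).
#' @param m Subsample size (default 100); `m == nrow(data)` without
#'   replacement makes every iteration the full-cohort evaluation.
#' @param seed Integer seed; the whole resampling stream is reproducible
#'   from it.
#' @param replace Draw subsamples with replacement (default `FALSE`:
#'   random subsets, as "randomly chosen" participants).
#' @param outcome Name of the logical remission column.
#' @return An object of class `roc_bootstrap`; see
#'   [tidy()][tidy.roc_bootstrap()] for per-iteration values and
#'   [glance()][glance.roc_bootstrap()] for the mean/sd summary.
#' @examples
#' boot <- bootstrap_cv(ispotd_pooled_cohort(), ispotd_rules("volumetric"),
#'                      n_iter = 200, m = 100, seed = 1)
#' glance(boot)
#' @export
bootstrap_cv <- function(data, rules, n_iter = 1000L, m = 100L, seed = NULL,
                         replace = FALSE, outcome = "remitted") {
  if (inherits(rules, "roc_tree")) rules <- extract_actionable_rules(rules)
  if (nrow(rules) == 0L) {
    abort("`rules` contains no non-remission rule.")
  }
  n <- nrow(data)
  if (!replace && m > n) abort("`m` cannot exceed the pooled size.")
  # the rules are fixed, so each subject's selection status can be
  # computed once and subsampled
  sel <- apply_rules(data, rules)$.selected
  nr <- !as.logical(data[[outcome]])
  spec <- numeric(n_iter)
  cov <- numeric(n_iter)
  with_rng(seed, {
    for (i in seq_len(n_iter)) {
      idx <- sample.int(n, m, replace = replace)
      s <- sel[idx]
      k <- nr[idx]
      n_sel <- sum(s)
      n_nr <- sum(k)
      spec[i] <- if (n_sel > 0) sum(s & k) / n_sel else NA_real_
      cov[i] <- if (n_nr > 0) sum(s & k) / n_nr else NA_real_
    }
  })
  structure(
    list(n_iter = as.integer(n_iter), m = as.integer(m),
         replace = replace, seed = seed,
         specificity = spec, coverage = cov),
    class = "roc_bootstrap"
  )
}

#' Per-iteration bootstrap values
#'
#' @param x A `roc_bootstrap`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `specificity` and `coverage`
#'   (`NA` where undefined).
#' @export
#' @exportS3Method generics::tidy
tidy.roc_bootstrap <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$n_iter),
                 specificity = x$specificity,
                 coverage = x$coverage)
}

#' Summary of a bootstrap cross-validation
#'
#' @param x A `roc_bootstrap`.
#' @param ... Unused.
#' @return A one-row tibble: iteration count, subsample size, mean and
#'   sd of specificity and coverage over defined iterations, and the
#'   counts of undefined iterations.
#' @export
#' @exportS3Method generics::glance
glance.roc_bootstrap <- function(x, ...) {
  tibble::tibble(
    n_iter = x$n_iter, m = x$m,
    mean_specificity = mean(x$specificity, na.rm = TRUE),
    sd_specificity = sd(x$specificity, na.rm = TRUE),
    mean_coverage = mean(x$coverage, na.rm = TRUE),
    sd_coverage = sd(x$coverage, na.rm = TRUE),
    n_undefined_specificity = sum(is.na(x$specificity)),
    n_undefined_coverage = sum(is.na(x$coverage))
  )
}

#' @export
print.roc_bootstrap <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("Bootstrap cross-validation: %d iterations of %d subjects ",
           "(%s replacement)\n  specificity %.1f%% +/- %.1f%%",
           " | coverage %.1f%% +/- %.1f%% | %d undefined\n"),
    g$n_iter, g$m, if (x$replace) "with" else "without",
    100 * g$mean_specificity, 100 * g$sd_specificity,
    100 * g$mean_coverage, 100 * g$sd_coverage,
    g$n_undefined_specificity
  ))
  invisible(x)
}

#' Histogram of the bootstrap specificity distribution
#'
#' @param object A `roc_bootstrap`.
#' @param metric `"specificity"` or `"coverage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.roc_bootstrap <- function(object,
                                   metric = c("specificity", "coverage"),
                                   ...) {
  metric <- match.arg(metric)
  d <- tidy(object)
  m <- mean(d[[metric]], na.rm = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = m, linetype = 2) +
    ggplot2::labs(
      x = paste("per-subsample", metric),
      y = "subsamples",
      title = sprintf("%s over %d subsamples of %d: %.1f%% +/- %.1f%%",
                      metric, object$n_iter, object$m, 100 * m,
                      100 * sd(d[[metric]], na.rm = TRUE))
    ) +
    ggplot2::theme_minimal()
}
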