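#' Run the full test/validate/bootstrap workflow
#'
#' Reproduces the study's analysis plan end to end: fit a decision tree
#' on the test cohort by kappa-maximizing recursive partitioning,
#' extract the actionable non-remission rules, evaluate each rule on
#' the validation cohort with the exact binomial replication test
#' (against the rule's test-cohort accuracy) and the better-than-chance
#' test, and run the pooled-cohort subsampling cross-validation of the
#' rule set.
#'
#' @param data Cohort tibble with a `cohort` column containing
#'   `test_label` and `validation_label` values, or `NULL` to simulate
#'   from `config`.
#' @param config A [cohort_config()] used when `data` is `NULL`.
#' @param modality Candidate feature set for [build_tree()]
#'   (`"volumes"`, `"fa"`, `"all"` or a character vector of columns).
#' @param alpha Stopping significance level for splits.
#' @param min_accuracy Purity bar for actionable rules.
#' @param chance_remission Chance remission rate for [chance_test()].
#' @param n_iter,m Bootstrap iterations and subsample size.
#' @param seed Governs simulation (when `data` is `NULL`) and the
#'   bootstrap resampling.
#' @param test_label,validation_label Values of `cohort` naming the two
#'   cohorts.
#' @return An object of class `roc_report`: a list with the fitted
#'   `tree`, the `rules` table, `validation` (one [evaluate_selection()]
#'   row per rule plus one for the whole rule set), `bootstrap`
#'   (a `roc_bootstrap`, `NULL` when no rule qualified), and a
#'   `manifest` recording inputs, parameters, seed and versions.
#' @examples
#' report <- run_pipeline(config = ispotd_config(), modality = "volumes",
#'                        n_iter = 50, seed = 11)
#' report$validation
#' @export
run_pipeline <- function(data = NULL, config = NULL, modality = "volumes",
                         alpha = 0.01, min_accuracy = 0.80,
                         chance_remission = 0.35,
                         n_iter = 1000L, m = 100L, seed = NULL,
                         test_label = "test",
                         validation_label = "validation") {
  if (is.null(data)) {
    if (is.null(config)) abort("Provide `data` or `config`.")
    data <- simulate_cohort(config, seed = seed)
  }
  if (!"cohort" %in% names(data)) abort("`data` must have a `cohort` column.")
  test <- data[data$cohort == test_label, , drop = FALSE]
  validation <- data[data$cohort == validation_label, , drop = FALSE]
  if (nrow(test) == 0L || nrow(validation) == 0L) {
    abort("Both the test and validation cohorts must be non-empty.")
  }

  tree <- build_tree(test, modality, alpha = alpha, cohort_id = test_label)
  rules <- extract_actionable_rules(tree, min_accuracy = min_accuracy)

  evaluate_rule_rows <- function(rules_subset, label) {
    sel <- apply_rules(validation, rules_subset)
    ref <- sum(rules_subset$n_nonremit) /
      sum(rules_subset$n_nonremit + rules_subset$n_remit)
    dplyr::mutate(
      evaluate_selection(sel, reference_accuracy = ref,
                         chance_remission = chance_remission),
      rule = label, reference_accuracy = ref, .before = 1
    )
  }
  validation_eval <- if (nrow(rules) > 0L) {
    per_rule <- purrr::map_dfr(seq_len(nrow(rules)), function(i) {
      evaluate_rule_rows(rules[i, ], rules$path[i])
    })
    if (nrow(rules) > 1L) {
      dplyr::bind_rows(per_rule, evaluate_rule_rows(rules, "(all rules)"))
    } else {
      per_rule
    }
  } else {
    tibble::tibble()
  }

  boot <- if (nrow(rules) > 0L) {
    pooled <- dplyr::bind_rows(test, validation)
    bootstrap_cv(pooled, rules, n_iter = n_iter,
                 m = min(m, nrow(pooled)), seed = seed)
  }

  manifest <- list(
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    rng = "Mersenne-Twister",
    modality = modality,
    alpha = alpha,
    min_accuracy = min_accuracy,
    chance_remission = chance_remission,
    n_iter = n_iter,
    m = m,
    n_test = nrow(test),
    n_validation = nrow(validation),
    data_hash = rlang::hash(data),
    config = if (!is.null(config)) config_snapshot(config),
    version = as.character(utils::packageVersion("roctree"))
  )
  structure(
    list(tree = tree, rules = rules, validation = validation_eval,
         bootstrap = boot, manifest = manifest),
    class = "roc_report"
  )
}

# JSON-serializable snapshot of a cohort_config (planted trees and
# tibbles flattened to plain lists), mirroring the YAML schema of
# read_config().
config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$cohorts <- lapply(snap$cohorts, function(co) {
    co$planted <- lapply(co$planted, function(pt) {
      list(
        splits = lapply(seq_len(nrow(pt$splits)),
                        function(i) as.list(pt$splits[i, ])),
        final_p = pt$final_p, final_n = pt$final_n
      )
    })
    co
  })
  snap$feature_means <- as.list(snap$feature_means)
  snap$feature_sds <- as.list(snap$feature_sds)
  snap
}

#' @export
print.roc_report <- function(x, ...) {
  cat("== Fitted decision tree (test cohort) ==\n")
  print(x$tree)
  cat(sprintf("\n== Actionable non-remission rules (%d) ==\n", nrow(x$rules)))
  if (nrow(x$rules) > 0L) {
    for (i in seq_len(nrow(x$rules))) {
      cat(sprintf("  %d. %s  [%d/%d non-remitters, accuracy %.0f%%]\n",
                  i, x$rules$path[i], x$rules$n_nonremit[i],
                  x$rules$n_nonremit[i] + x$rules$n_remit[i],
                  100 * x$rules$accuracy[i]))
    }
    cat("\n== Validation-cohort evaluation ==\n")
    print(x$validation)
    if (!is.null(x$bootstrap)) {
      cat("\n== Pooled-cohort cross-validation ==\n")
      print(x$bootstrap)
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the report bundle: the fitted tree as JSON, the validation
#' evaluation and per-iteration bootstrap values as TSV, a text render
#' of the tree, and the run manifest as JSON.
#'
#' @param report A `roc_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "roc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tree(report$tree, file.path(dir, "tree.json"))
  writeLines(utils::capture.output(print(report$tree)),
             file.path(dir, "tree.txt"))
  readr::write_tsv(report$validation, file.path(dir, "validation.tsv"))
  if (!is.null(report$bootstrap)) {
    readr::write_tsv(tidy(report$bootstrap),
                     file.path(dir, "bootstrap_iterations.tsv"))
    readr::write_tsv(glance(report$bootstrap),
                     file.path(dir, "bootstrap_summary.tsv"))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
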