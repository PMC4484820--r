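#' Enumerate candidate cut-points for one predictor
#'
#' Generates one candidate split per distinct observed value `v` of the
#' predictor, dividing the subsample into the `x >= v` and `x < v`
#' branches, and scores each by Cohen's kappa between branch membership
#' and the remission label.  The candidate at the minimum observed value
#' (whose `< v` branch is empty) is dropped.  Subjects with a missing
#' value for the predictor are excluded (complete cases per feature).
#'
#' The candidate's `direction` records which branch is the "positive"
#' (predicted non-remission) side: the branch with the higher
#' non-remission proportion.  With that orientation the reported kappa is
#' always the larger of the two orientations (and is non-negative).
#'
#' @param data Data frame with one row per subject, containing `feature`
#'   and a logical outcome column.
#' @param feature Name of the predictor column.
#' @param outcome Name of the logical remission column (`TRUE` = remitted).
#' @return A tibble with one row per candidate: `feature`, `threshold`,
#'   `direction` (`"ge"` or `"lt"`: the predicted-non-remission branch),
#'   the 2x2 branch-by-outcome counts (`n_ge_nonremit`, `n_ge_remit`,
#'   `n_lt_nonremit`, `n_lt_remit`), `kappa`, `p_value` (two-sided Fisher
#'   exact), `sensitivity` and `specificity` of the positive branch as a
#'   non-remission classifier.
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 2, 3), remitted = c(TRUE, TRUE, FALSE, FALSE))
#' enumerate_cutpoints(d, "x")
#' @export
enumerate_cutpoints <- function(data, feature, outcome = "remitted") {
  cand <- cutpoint_tables(data, feature, outcome)
  if (nrow(cand) == 0L) return(cand_with_p(cand))
  cand$p_value <- purrr::map_dbl(seq_len(nrow(cand)), function(i) {
    fisher_exact_2x2(cand_table(cand[i, ]))
  })
  cand
}

# Vectorized candidate construction: all distinct-value thresholds of one
# feature, with 2x2 counts, oriented kappa and sensitivity/specificity.
# No p-values (those are computed lazily by the callers that need them).
cutpoint_tables <- function(data, feature, outcome = "remitted") {
  if (!feature %in% names(data)) {
    abort(paste0("Feature `", feature, "` not found in `data`."))
  }
  x <- data[[feature]]
  y <- as.logical(data[[outcome]])
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  empty <- tibble::tibble(
    feature = character(), threshold = numeric(), direction = character(),
    n_ge_nonremit = integer(), n_ge_remit = integer(),
    n_lt_nonremit = integer(), n_lt_remit = integer(),
    kappa = numeric(), sensitivity = numeric(), specificity = numeric()
  )
  if (length(x) == 0L) {
    abort(paste0("Feature `", feature, "` is missing for all subjects."))
  }
  ord <- order(x)
  xs <- x[ord]
  nr <- !y[ord] # non-remitter indicator
  n <- length(xs)
  n_nr <- sum(nr)
  n_r <- n - n_nr
  first <- which(!duplicated(xs))
  v <- xs[first]
  n_lt <- first - 1L
  nr_lt <- c(0L, cumsum(nr))[first]
  # drop the minimum (empty "< v" branch)
  keep_v <- n_lt > 0L
  if (!any(keep_v)) return(empty)
  v <- v[keep_v]; n_lt <- n_lt[keep_v]; nr_lt <- nr_lt[keep_v]
  r_lt <- n_lt - nr_lt
  n_ge <- n - n_lt
  nr_ge <- n_nr - nr_lt
  r_ge <- n_ge - nr_ge

  # kappa with the ">= v" branch as predicted non-remission
  po_ge <- (nr_ge + r_lt) / n
  pe_ge <- (n_ge * n_nr + n_lt * n_r) / n^2
  kap_ge <- ifelse(abs(1 - pe_ge) < .Machine$double.eps^0.5, 0,
                   (po_ge - pe_ge) / (1 - pe_ge))
  kap_lt <- ifelse(abs(1 - pe_ge) < .Machine$double.eps^0.5, 0,
                   ((1 - po_ge) - (1 - pe_ge)) / (1 - (1 - pe_ge)))
  ge_is_pos <- nr_ge / n_ge >= nr_lt / n_lt
  direction <- ifelse(ge_is_pos, "ge", "lt")
  kappa <- ifelse(ge_is_pos, kap_ge, kap_lt)
  nr_pos <- ifelse(ge_is_pos, nr_ge, nr_lt)
  r_neg <- ifelse(ge_is_pos, r_lt, r_ge)
  sens <- if (n_nr > 0) nr_pos / n_nr else NA_real_
  spec <- if (n_r > 0) r_neg / n_r else NA_real_

  tibble::tibble(
    feature = feature, threshold = v, direction = direction,
    n_ge_nonremit = as.integer(nr_ge), n_ge_remit = as.integer(r_ge),
    n_lt_nonremit = as.integer(nr_lt), n_lt_remit = as.integer(r_lt),
    kappa = kappa, sensitivity = sens, specificity = spec
  )
}

cand_with_p <- function(cand) {
  cand$p_value <- numeric(nrow(cand))
  cand
}

# 2x2 matrix (branch x outcome) from one candidate row
cand_table <- function(row) {
  matrix(c(row$n_ge_nonremit, row$n_lt_nonremit,
           row$n_ge_remit, row$n_lt_remit), nrow = 2)
}

#' Best significant cut-point across a set of predictors
#'
#' Evaluates every observed value of every listed predictor as a
#' candidate split, and returns the candidate with the largest Cohen's
#' kappa among those whose two-sided Fisher exact p-value is below
#' `alpha`.  Candidates leaving fewer than `min_node` subjects in either
#' branch, and degenerate candidates with kappa 0, are not considered.
#'
#' Ties are broken deterministically: larger kappa, then smaller p-value,
#' then the predictor listed earliest in `features`, then the smaller
#' threshold.
#'
#' @inheritParams enumerate_cutpoints
#' @param features Character vector of predictor column names, in
#'   priority order for tie-breaking.
#' @param alpha Significance level gating candidate splits (default 0.01).
#' @param min_node Minimum subjects required in each branch (default 2).
#' @return A one-row tibble in the [enumerate_cutpoints()] layout, or
#'   `NULL` when no candidate is significant (including when only one
#'   outcome class is present).
#' @export
best_cutpoint <- function(data, features, outcome = "remitted",
                          alpha = 0.01, min_node = 2L) {
  if (length(features) == 0L) abort("`features` must name at least one predictor.")
  y <- as.logical(data[[outcome]])
  y <- y[!is.na(y)]
  if (length(unique(y)) < 2L) return(NULL)

  cand <- purrr::map(features, function(f) cutpoint_tables(data, f, outcome))
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0L) return(NULL)
  cand$feature_idx <- match(cand$feature, features)
  n_ge <- cand$n_ge_nonremit + cand$n_ge_remit
  n_lt <- cand$n_lt_nonremit + cand$n_lt_remit
  cand <- cand[n_ge >= min_node & n_lt >= min_node & cand$kappa > 0, ]
  if (nrow(cand) == 0L) return(NULL)

  # The two-sided Fisher p includes the observed table, so it is bounded
  # below by the table's hypergeometric point probability; candidates
  # whose point probability already reaches alpha can never be
  # significant and are pruned before any exact test is run.
  point_p <- stats::dhyper(cand$n_ge_nonremit,
                           cand$n_ge_nonremit + cand$n_lt_nonremit,
                           cand$n_ge_remit + cand$n_lt_remit,
                           cand$n_ge_nonremit + cand$n_ge_remit)
  cand <- cand[point_p < alpha, ]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$kappa, cand$feature_idx, cand$threshold), ]

  # Exact p-values are computed lazily, one kappa-level at a time, down
  # the sorted candidate list: the winner is the max-kappa significant
  # candidate, so once a level contains a significant candidate no lower
  # level can win.
  i <- 1L
  while (i <= nrow(cand)) {
    j <- i
    while (j < nrow(cand) && cand$kappa[j + 1L] == cand$kappa[i]) j <- j + 1L
    block <- cand[i:j, ]
    block$p_value <- purrr::map_dbl(seq_len(nrow(block)), function(b) {
      fisher_exact_2x2(cand_table(block[b, ]))
    })
    sig <- block[block$p_value < alpha, ]
    if (nrow(sig) > 0L) {
      sig <- sig[order(sig$p_value, sig$feature_idx, sig$threshold), ]
      out <- sig[1, ]
      out$feature_idx <- NULL
      return(out[, c("feature", "threshold", "direction",
                     "n_ge_nonremit", "n_ge_remit",
                     "n_lt_nonremit", "n_lt_remit",
                     "kappa", "sensitivity", "specificity", "p_value")])
    }
    i <- j + 1L
  }
  NULL
}
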