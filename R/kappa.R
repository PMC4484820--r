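#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement between a candidate split's branch
#' assignment (rows: predicted non-remitter / predicted remitter) and the
#' observed outcome (columns: non-remitter / remitter).  This is the score
#' that ranks candidate cut-points during recursive partitioning: the
#' largest kappa corresponds to the cut-point with the best joint
#' sensitivity and specificity.
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement
#' proportion and `p_e` the agreement expected from the row/column
#' margins.  When a margin is degenerate (`p_e = 1`, e.g. all subjects in
#' one branch) kappa is defined as 0: such a split carries no information.
#'
#' @param table 2x2 matrix of non-negative integer counts; rows index the
#'   branch assignment, columns the observed outcome.
#' @return A single number in `[-1, 1]`.
#' @examples
#' kappa_2x2(matrix(c(10, 0, 0, 10), 2)) # 1: perfect agreement
#' kappa_2x2(matrix(c(5, 5, 5, 5), 2))   # 0: independence
#' @export
kappa_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    abort("`table` must be a 2x2 matrix of counts.")
  }
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    abort("`table` entries must be non-negative integers.")
  }
  n <- sum(table)
  if (n < 1) abort("`table` must contain at least one subject.")
  po <- (table[1, 1] + table[2, 2]) / n
  pe <- (sum(table[1, ]) * sum(table[, 1]) +
         sum(table[2, ]) * sum(table[, 2])) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(0)
  (po - pe) / (1 - pe)
}
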