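#' Specify a planted decision tree
#'
#' A planted tree defines the ground truth a synthetic cohort is built
#' around: an ordered chain of splits in which, at each stage, one branch
#' terminates as a leaf with a target subject count and remission
#' probability while the other branch continues to the next split.  This
#' "caterpillar" shape matches the hierarchical trees the partitioning
#' procedure produces on the study data (each significant cut-point
#' closes off one subgroup).
#'
#' @param splits Data frame with one row per split, columns `feature`
#'   (name in the atlas label lists), `threshold`, `leaf_side` (`"ge"` or
#'   `"lt"`: the side that becomes a leaf at this split), `leaf_p`
#'   (remission probability of that leaf) and `leaf_n` (target subject
#'   count of that leaf).
#' @param final_p,final_n Remission probability and target count of the
#'   residual leaf left after the last split.
#' @return An object of class `planted_tree`.
#' @examples
#' planted_tree(
#'   tibble::tibble(feature = "Frontal_Mid_L", threshold = 14.82,
#'                  leaf_side = "ge", leaf_p = 0.9, leaf_n = 40),
#'   final_p = 0.1, final_n = 60
#' )
#' @export
planted_tree <- function(splits, final_p, final_n) {
  splits <- tibble::as_tibble(splits)
  need <- c("feature", "threshold", "leaf_side", "leaf_p", "leaf_n")
  if (!all(need %in% names(splits))) {
    abort(paste0("`splits` must have columns: ", paste(need, collapse = ", ")))
  }
  if (!all(splits$leaf_side %in% c("ge", "lt"))) {
    abort('`leaf_side` must be "ge" or "lt".')
  }
  probs <- c(splits$leaf_p, final_p)
  if (any(probs < 0 | probs > 1)) abort("Leaf probabilities must lie in [0, 1].")
  if (any(c(splits$leaf_n, final_n) < 0)) abort("Leaf counts must be non-negative.")
  structure(
    list(splits = splits, final_p = final_p, final_n = as.integer(final_n)),
    class = "planted_tree"
  )
}

#' @export
print.planted_tree <- function(x, ...) {
  cat("Planted decision tree:\n")
  for (i in seq_len(nrow(x$splits))) {
    s <- x$splits[i, ]
    cat(sprintf("  split %d: %s %s %s -> leaf (n = %d, P(remit) = %.3f)\n",
                i, s$feature, if (s$leaf_side == "ge") ">=" else "<",
                format(s$threshold), s$leaf_n, s$leaf_p))
  }
  cat(sprintf("  residual leaf: n = %d, P(remit) = %.3f\n",
              x$final_n, x$final_p))
  invisible(x)
}

# Leaf table of a planted tree: one row per leaf with target count,
# remission probability and the list of (feature, op, threshold)
# conditions defining it. Leaf k (k <= n splits) satisfies the continue
# side of splits 1..k-1 and the leaf side of split k; the residual leaf
# satisfies the continue side of every split.
planted_leaves <- function(tree) {
  stopifnot(inherits(tree, "planted_tree"))
  s <- tree$splits
  k <- nrow(s)
  op_of <- function(side) if (side == "ge") ">=" else "<"
  flip <- function(side) if (side == "ge") "lt" else "ge"
  conds <- vector("list", k + 1L)
  for (i in seq_len(k)) {
    cc <- list()
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        cc[[j]] <- list(feature = s$feature[j],
                        op = op_of(flip(s$leaf_side[j])),
                        threshold = s$threshold[j])
      }
    }
    cc[[i]] <- list(feature = s$feature[i], op = op_of(s$leaf_side[i]),
                    threshold = s$threshold[i])
    conds[[i]] <- cc
  }
  conds[[k + 1L]] <- lapply(seq_len(k), function(j) {
    list(feature = s$feature[j], op = op_of(flip(s$leaf_side[j])),
         threshold = s$threshold[j])
  })
  tibble::tibble(
    leaf_id = seq_len(k + 1L),
    n = c(s$leaf_n, tree$final_n),
    p_remission = c(s$leaf_p, tree$final_p),
    conditions = conds
  )
}

# Total size and expected label composition implied by a planted tree.
planted_composition <- function(tree) {
  lv <- planted_leaves(tree)
  list(
    n = sum(lv$n),
    n_remit = sum(lv$n * lv$p_remission),
    n_nonremit = sum(lv$n * (1 - lv$p_remission))
  )
}

#' Thresholds and features of a planted tree
#'
#' Accessors for the split chain of a [planted_tree()]: the ordered
#' cut-point thresholds (root first) and the features they apply to.
#'
#' @param tree A `planted_tree`.
#' @return Numeric or character vector, one element per split.
#' @export
planted_thresholds <- function(tree) tree$splits$threshold

#' @rdname planted_thresholds
#' @export
planted_features <- function(tree) tree$splits$feature
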