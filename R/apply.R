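#' Route subjects through a fitted tree
#'
#' Applies a fitted `roc_tree` to new subjects using its stored
#' thresholds and directions.  A subject exactly at a threshold follows
#' the `>=` branch.  A subject missing a feature needed on its path
#' cannot be routed and is reported as unclassified (`NA` node).
#'
#' @param data Data frame of subjects (one per row).
#' @param tree A fitted [build_tree()] object.
#' @return `data` with three columns added: `.node_id` (terminal node
#'   reached, `NA` if unclassified), `.node_path` (conjunction of split
#'   conditions) and `.p_remission` (the terminal node's fitted remission
#'   probability).
#' @examples
#' cohort <- simulate_cohort(ispotd_config(seed = 7))
#' tree <- build_tree(dplyr::filter(cohort, cohort == "test"), "volumes")
#' apply_tree(dplyr::filter(cohort, cohort == "validation"), tree) |>
#'   dplyr::count(.node_path, remitted)
#' @export
apply_tree <- function(data, tree) {
  stopifnot(inherits(tree, "roc_tree"))
  n <- nrow(data)
  node_id <- rep(NA_integer_, n)
  route <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (is.null(node$split)) {
      node_id[idx] <<- node$id
      return()
    }
    x <- data[[node$split$feature]][idx]
    route(node$children$ge, idx[!is.na(x) & x >= node$split$threshold])
    route(node$children$lt, idx[!is.na(x) & x < node$split$threshold])
    # idx with is.na(x) stay unclassified
  }
  if (n > 0L) route(tree$root, seq_len(n))
  nodes <- tidy(tree)
  at <- match(node_id, nodes$node_id)
  dplyr::mutate(
    tibble::as_tibble(data),
    .node_id = node_id,
    .node_path = nodes$path[at],
    .p_remission = nodes$p_remission[at]
  )
}

#' Extract actionable non-remission rules from a fitted tree
#'
#' A root-to-node path is clinically actionable when the subjects
#' reaching that node are non-remitters with sufficient purity (the
#' study's bar: more than 80%), so the rule can support ruling out the
#' treatment.  All nodes at or above the purity bar qualify; a node
#' whose ancestor already qualifies is dropped (its rule is subsumed).
#'
#' @param tree A fitted `roc_tree`.
#' @param min_accuracy Minimum non-remission proportion of the node
#'   (default 0.80).
#' @return A rule tibble: `rule_id`, `node_id`, `n_nonremit`,
#'   `n_remit`, `accuracy` (the node's non-remission proportion),
#'   `path`, and a `conditions` list-column of `(feature, op,
#'   threshold)` tables with conjunction semantics.
#' @export
extract_actionable_rules <- function(tree, min_accuracy = 0.80) {
  stopifnot(inherits(tree, "roc_tree"))
  nodes <- tidy(tree)
  nodes$accuracy <- 1 - nodes$p_remission
  conds <- node_conditions(tree)
  qualifies <- nodes$accuracy >= min_accuracy &
    (nodes$n_remit + nodes$n_nonremit) > 0
  # drop nodes with a qualifying ancestor
  keep <- qualifies
  for (i in which(qualifies)) {
    p <- nodes$parent_id[i]
    while (!is.na(p)) {
      j <- match(p, nodes$node_id)
      if (qualifies[j]) { keep[i] <- FALSE; break }
      p <- nodes$parent_id[j]
    }
  }
  # the root, if it qualifies, is a degenerate "select everyone" rule
  sel <- nodes[keep, ]
  tibble::tibble(
    rule_id = seq_len(nrow(sel)),
    node_id = sel$node_id,
    n_nonremit = sel$n_nonremit,
    n_remit = sel$n_remit,
    accuracy = sel$accuracy,
    path = sel$path,
    conditions = conds[match(sel$node_id, nodes$node_id)]
  )
}

# Conditions defining each node, aligned with tidy() row order.
node_conditions <- function(tree) {
  out <- list()
  rec <- function(node, conds) {
    out[[length(out) + 1L]] <<- conds
    if (is.null(node$split)) return()
    s <- node$split
    rec(node$children$ge,
        dplyr::bind_rows(conds, tibble::tibble(
          feature = s$feature, op = ">=", threshold = s$threshold)))
    rec(node$children$lt,
        dplyr::bind_rows(conds, tibble::tibble(
          feature = s$feature, op = "<", threshold = s$threshold)))
  }
  empty <- tibble::tibble(feature = character(), op = character(),
                          threshold = numeric())
  rec(tree$root, empty) # same preorder as walk_nodes/tidy
  out
}

#' Select subjects matching a set of non-remission rules
#'
#' Marks every subject matching at least one rule (each rule is the
#' conjunction of its conditions; a missing feature value fails the
#' condition).  Rules come from [extract_actionable_rules()] or
#' [ispotd_rules()].
#'
#' @param data Data frame of subjects.
#' @param rules A rule tibble with a `conditions` list-column.
#' @return `data` with `.selected` (logical) and `.rule_id` (first
#'   matching rule, `NA` if none) columns added.
#' @export
apply_rules <- function(data, rules) {
  if (nrow(rules) == 0L) {
    return(dplyr::mutate(tibble::as_tibble(data),
                         .selected = FALSE, .rule_id = NA_integer_))
  }
  n <- nrow(data)
  sel <- rep(FALSE, n)
  rule_id <- rep(NA_integer_, n)
  for (i in rev(seq_len(nrow(rules)))) {
    m <- rule_matches(data, rules$conditions[[i]])
    rule_id[m] <- rules$rule_id[i]
    sel <- sel | m
  }
  dplyr::mutate(tibble::as_tibble(data),
                .selected = sel, .rule_id = rule_id)
}

rule_matches <- function(data, conditions) {
  m <- rep(TRUE, nrow(data))
  for (j in seq_len(nrow(conditions))) {
    x <- data[[conditions$feature[j]]]
    if (is.null(x)) {
      abort(paste0("Rule feature `", conditions$feature[j],
                   "` not found in `data`."))
    }
    ok <- if (conditions$op[j] == ">=") x >= conditions$threshold[j]
          else x < conditions$threshold[j]
    ok[is.na(ok)] <- FALSE
    m <- m & ok
  }
  m
}

#' Combine two rule sets in series or in parallel
#'
#' Serial application selects the subjects selected by *both* rule sets
#' (set intersection — order of application is irrelevant); parallel
#' application selects subjects selected by *either* (set union).  These
#' mirror combining the DTI and volumetric decision trees as a two-stage
#' versus an either-or clinical test.
#'
#' @param data Data frame of subjects.
#' @param rules_a,rules_b Rule tibbles (see [apply_rules()]).
#' @return `data` with a logical `.selected` column added.
#' @examples
#' pooled <- ispotd_pooled_cohort()
#' serial <- combine_series(pooled,
#'                          ispotd_rules("dti", "replicated"),
#'                          ispotd_rules("volumetric"))
#' sum(serial$.selected) # 10
#' @export
combine_series <- function(data, rules_a, rules_b) {
  if (nrow(rules_a) == 0L || nrow(rules_b) == 0L) {
    abort("Both rule sets must be non-empty.")
  }
  a <- apply_rules(data, rules_a)$.selected
  b <- apply_rules(data, rules_b)$.selected
  dplyr::mutate(tibble::as_tibble(data), .selected = a & b)
}

#' @rdname combine_series
#' @export
combine_parallel <- function(data, rules_a, rules_b) {
  if (nrow(rules_a) == 0L || nrow(rules_b) == 0L) {
    abort("Both rule sets must be non-empty.")
  }
  a <- apply_rules(data, rules_a)$.selected
  b <- apply_rules(data, rules_b)$.selected
  dplyr::mutate(tibble::as_tibble(data), .selected = a | b)
}
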