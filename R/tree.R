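#' Fit a decision tree by kappa-maximizing recursive partitioning
#'
#' The ROC signal-detection partitioning procedure: at each node the best
#' significant cut-point across all candidate predictors (largest Cohen's
#' kappa with two-sided Fisher exact p below `alpha`, see
#' [best_cutpoint()]) splits the subsample into its `>= v` and `< v`
#' branches, and the same search is repeated within each branch.
#' Partitioning stops in a branch when no candidate cut-point reaches
#' significance, when a branch holds a single outcome class, or when
#' `max_depth` is reached.  Every node records its remitter /
#' non-remitter counts and remission probability.
#'
#' Fitting is fully deterministic: identical input yields an identical
#' tree (ties among candidates are broken by the documented ordering).
#'
#' @param data Data frame with one row per subject: predictor columns, a
#'   logical `outcome` column, and (optionally) `subject_id`.
#' @param features Character vector of candidate predictor columns, or
#'   one of the shortcuts `"volumes"` (AAL-116 regions), `"fa"` (JHU-46
#'   tracts), `"all"` (volumes, FA and numeric clinical covariates);
#'   shortcut columns absent from `data` are ignored.
#' @param alpha Stopping rule: a split must have Fisher exact p `< alpha`
#'   (default 0.01).
#' @param min_node Minimum subjects per branch for a candidate split.
#' @param max_depth Safety cap on tree depth (default 10).
#' @param outcome Name of the logical remission column.
#' @param cohort_id Optional label for the cohort the tree was fitted on,
#'   stored in the tree metadata.
#' @return An object of class `roc_tree`.  Inspect with `print()`,
#'   [tidy()][tidy.roc_tree()], [glance()][glance.roc_tree()] or
#'   [autoplot()][autoplot.roc_tree()]; apply to new subjects with
#'   [apply_tree()]; turn into clinical rules with
#'   [extract_actionable_rules()].
#' @examples
#' cohort <- simulate_cohort(ispotd_config(seed = 1))
#' tree <- build_tree(dplyr::filter(cohort, cohort == "test"), "volumes")
#' tree
#' @export
build_tree <- function(data, features, alpha = 0.01, min_node = 2L,
                       max_depth = 10L, outcome = "remitted",
                       cohort_id = NULL) {
  if (nrow(data) == 0L) abort("`data` must contain at least one subject.")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  features <- resolve_features(data, features)
  y <- as.logical(data[[outcome]])
  if (anyNA(y)) abort("`outcome` must not contain missing values.")

  counter <- new.env(parent = emptyenv())
  counter$next_id <- 1L
  root <- grow_node(data, features, alpha, min_node, max_depth, outcome,
                    depth = 0L, counter = counter)
  structure(
    list(
      root = root,
      features = features,
      alpha = alpha,
      min_node = as.integer(min_node),
      n = nrow(data),
      cohort_id = cohort_id,
      meta = list(
        significance_test = "fisher_exact_two_sided",
        tie_break = "kappa_desc,p_asc,feature_order,threshold_asc",
        threshold_semantics = "ge_vs_lt",
        missing_policy = "complete_case_per_feature",
        version = as.character(utils::packageVersion("roctree"))
      )
    ),
    class = "roc_tree"
  )
}

resolve_features <- function(data, features) {
  if (length(features) == 1L && features %in% c("volumes", "fa", "all")) {
    features <- switch(features,
      volumes = atlas_labels("aal116"),
      fa      = atlas_labels("jhu46"),
      all     = c(atlas_labels("aal116"), atlas_labels("jhu46"),
                  clinical_predictors())
    )
    features <- intersect(features, names(data))
  }
  missing <- setdiff(features, names(data))
  if (length(missing) > 0L) {
    abort(paste0("Features not in `data`: ", paste(missing, collapse = ", ")))
  }
  if (length(features) == 0L) abort("No candidate features available.")
  features
}

grow_node <- function(data, features, alpha, min_node, max_depth, outcome,
                      depth, counter) {
  id <- counter$next_id
  counter$next_id <- id + 1L
  y <- as.logical(data[[outcome]])
  n_remit <- sum(y)
  n_nonremit <- sum(!y)
  node <- list(
    id = id, depth = depth,
    n_remit = n_remit, n_nonremit = n_nonremit,
    p_remission = n_remit / (n_remit + n_nonremit),
    split = NULL, children = NULL, n_unrouted = 0L
  )
  if (depth >= max_depth) return(node)
  cut <- best_cutpoint(data, features, outcome = outcome,
                       alpha = alpha, min_node = min_node)
  if (is.null(cut)) return(node)

  x <- data[[cut$feature]]
  ge <- !is.na(x) & x >= cut$threshold
  lt <- !is.na(x) & x < cut$threshold
  node$split <- list(
    feature = cut$feature, threshold = cut$threshold,
    direction = cut$direction, kappa = cut$kappa, p_value = cut$p_value,
    sensitivity = cut$sensitivity, specificity = cut$specificity
  )
  node$n_unrouted <- as.integer(sum(is.na(x)))
  node$children <- list(
    ge = grow_node(data[ge, , drop = FALSE], features, alpha, min_node,
                   max_depth, outcome, depth + 1L, counter),
    lt = grow_node(data[lt, , drop = FALSE], features, alpha, min_node,
                   max_depth, outcome, depth + 1L, counter)
  )
  node
}

walk_nodes <- function(node, parent_id = NA_integer_, side = "root",
                       path = character()) {
  here <- tibble::tibble(
    node_id = node$id, parent_id = parent_id, depth = node$depth,
    side = side,
    feature = if (is.null(node$split)) NA_character_ else node$split$feature,
    threshold = if (is.null(node$split)) NA_real_ else node$split$threshold,
    direction = if (is.null(node$split)) NA_character_ else node$split$direction,
    kappa = if (is.null(node$split)) NA_real_ else node$split$kappa,
    p_value = if (is.null(node$split)) NA_real_ else node$split$p_value,
    n_remit = node$n_remit, n_nonremit = node$n_nonremit,
    p_remission = node$p_remission,
    is_leaf = is.null(node$split),
    path = if (length(path) == 0L) "(root)" else paste(path, collapse = " & ")
  )
  if (is.null(node$children)) return(here)
  f <- node$split$feature
  v <- node$split$threshold
  dplyr::bind_rows(
    here,
    walk_nodes(node$children$ge, node$id, "ge",
               c(path, paste0(f, " >= ", format(v)))),
    walk_nodes(node$children$lt, node$id, "lt",
               c(path, paste0(f, " < ", format(v))))
  )
}

#' Tidy a fitted tree into a node table
#'
#' @param x A `roc_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: identifiers, split
#'   description (`feature`, `threshold`, `direction`, `kappa`,
#'   `p_value`; `NA` for leaves), subject counts, remission probability
#'   and the conjunction `path` from the root.
#' @export
#' @exportS3Method generics::tidy
tidy.roc_tree <- function(x, ...) {
  walk_nodes(x$root)
}

#' One-row summary of a fitted tree
#'
#' @param x A `roc_tree`.
#' @param ... Unused.
#' @return A tibble with `n`, node/leaf counts, depth, `alpha`, and the
#'   number of actionable non-remission rules at the 80% purity bar.
#' @export
#' @exportS3Method generics::glance
glance.roc_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(
    n = x$n,
    n_nodes = nrow(nodes),
    n_leaves = sum(nodes$is_leaf),
    depth = max(nodes$depth),
    alpha = x$alpha,
    n_actionable = nrow(extract_actionable_rules(x))
  )
}

#' @export
print.roc_tree <- function(x, ...) {
  cat(sprintf(
    "ROC recursive-partitioning tree (n = %d, alpha = %g%s)\n",
    x$n, x$alpha,
    if (is.null(x$cohort_id)) "" else paste0(", cohort = ", x$cohort_id)
  ))
  print_node <- function(node, prefix, label) {
    cat(sprintf("%s%s[n = %d | %d R / %d NR | P(remit) = %.2f]\n",
                prefix, label,
                node$n_remit + node$n_nonremit,
                node$n_remit, node$n_nonremit, node$p_remission))
    if (!is.null(node$split)) {
      s <- node$split
      child_prefix <- paste0(sub("[├└]─ $", "|  ", prefix))
      print_node(node$children$ge, paste0(child_prefix, "├─ "),
                 sprintf("%s >= %s (kappa = %.2f, p = %.3g) ",
                         s$feature, format(s$threshold), s$kappa, s$p_value))
      print_node(node$children$lt, paste0(child_prefix, "└─ "),
                 sprintf("%s < %s ", s$feature, format(s$threshold)))
    }
  }
  print_node(x$root, "", "")
  invisible(x)
}

#' Plot a fitted tree
#'
#' Draws the hierarchical partition as a node-and-edge diagram: each box
#' shows the subject counts and remission probability of a node, edges
#' are labelled with the split condition.
#'
#' @param object A `roc_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.roc_tree <- function(object, ...) {
  nodes <- tidy(object)
  # x position: order leaves left to right, parents midway over children
  pos <- rep(NA_real_, nrow(nodes))
  leaf_ids <- nodes$node_id[nodes$is_leaf]
  pos[match(leaf_ids, nodes$node_id)] <- seq_along(leaf_ids)
  for (d in sort(unique(nodes$depth), decreasing = TRUE)) {
    for (i in which(nodes$depth == d & !nodes$is_leaf)) {
      kids <- which(nodes$parent_id == nodes$node_id[i])
      pos[i] <- mean(pos[kids])
    }
  }
  nodes$x <- pos
  nodes$y <- -nodes$depth
  nodes$label <- sprintf("%d R / %d NR\nP(remit) = %.2f",
                         nodes$n_remit, nodes$n_nonremit, nodes$p_remission)
  edges <- dplyr::inner_join(
    dplyr::select(nodes, "node_id", "x", "y"),
    dplyr::select(nodes, "parent_id", xend = "x", yend = "y",
                  child = "node_id", "side"),
    by = c("node_id" = "parent_id")
  )
  parent <- nodes[match(edges$node_id, nodes$node_id), ]
  edges$cond <- ifelse(
    edges$side == "ge",
    sprintf("%s >= %s", parent$feature, format(parent$threshold)),
    sprintf("%s < %s", parent$feature, format(parent$threshold))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50"
    ) +
    ggplot2::geom_label(
      data = edges,
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2, label = .data$cond),
      size = 2.8
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                   fill = .data$p_remission),
      size = 3, colour = "black"
    ) +
    ggplot2::scale_fill_gradient(low = "#d7301f", high = "#2b8cbe",
                                 limits = c(0, 1), name = "P(remit)") +
    ggplot2::theme_void()
}
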