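#' Read and write cohort tables
#'
#' Cohort tables are CSV or TSV files with one row per subject and the
#' column schema produced by [simulate_cohort()]: `subject_id`,
#' `cohort`, `remitted`, the atlas-named volumetric and FA feature
#' columns, and clinical covariates.  Reading validates the domain
#' invariants — FA in `[0, 1]`, volumes strictly positive, and
#' `remitted == (hrsd17_week8 <= 7)` where the week-8 score is present —
#' and reports violations with row numbers.  Missing cells stay
#' missing (`NA`), never zero.
#'
#' @param path File path; `.tsv` is read tab-separated, anything else
#'   comma-separated.
#' @param strict If `TRUE` (default) any invariant violation or unknown
#'   feature-like column is an error; if `FALSE`, offending rows are
#'   dropped with a warning and unknown columns are kept.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, strict = TRUE) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  data <- reader(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "cohort", "remitted")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Cohort file lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  data$remitted <- as.logical(data$remitted)

  known <- c(required, atlas_labels("aal116"), atlas_labels("jhu46"),
             clinical_columns())
  unknown <- setdiff(names(data), known)
  if (length(unknown) > 0L) {
    msg <- paste0("Unknown columns: ", paste(unknown, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }

  problems <- character()
  bad_rows <- integer()
  for (f in intersect(atlas_labels("jhu46"), names(data))) {
    bad <- which(!is.na(data[[f]]) & (data[[f]] < 0 | data[[f]] > 1))
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf(
        "row %d, column %s: FA value %g outside [0, 1]",
        bad, f, data[[f]][bad]))
      bad_rows <- c(bad_rows, bad)
    }
  }
  for (f in intersect(atlas_labels("aal116"), names(data))) {
    bad <- which(!is.na(data[[f]]) & data[[f]] <= 0)
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf(
        "row %d, column %s: volume %g not strictly positive",
        bad, f, data[[f]][bad]))
      bad_rows <- c(bad_rows, bad)
    }
  }
  if ("hrsd17_week8" %in% names(data)) {
    bad <- which(!is.na(data$hrsd17_week8) & !is.na(data$remitted) &
                   data$remitted != (data$hrsd17_week8 <= 7))
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf(
        "row %d: remitted label inconsistent with hrsd17_week8 = %g",
        bad, data$hrsd17_week8[bad]))
      bad_rows <- c(bad_rows, bad)
    }
  }
  if (length(problems) > 0L) {
    msg <- paste0("Cohort validation failed:\n  ",
                  paste(problems, collapse = "\n  "))
    if (strict) abort(msg)
    warn(paste0(msg, "\n  (offending rows dropped)"))
    data <- data[-unique(bad_rows), , drop = FALSE]
  }
  data
}

#' @rdname read_cohort
#' @param data A cohort tibble.
#' @export
write_cohort <- function(data, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}

#' Serialize a fitted tree to JSON and back
#'
#' Trees round-trip losslessly: every node's split (`feature`,
#' `threshold`, `direction`, `kappa`, `p_value`), counts and children
#' are written at full precision.
#'
#' @param tree A `roc_tree`.
#' @param path JSON file path.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "roc_tree"))
  ser <- unclass(tree)
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @return `read_tree()` returns the reconstructed `roc_tree`.
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix_node <- function(node) {
    node$id <- as.integer(node$id)
    node$depth <- as.integer(node$depth)
    node$n_remit <- as.integer(node$n_remit)
    node$n_nonremit <- as.integer(node$n_nonremit)
    node$p_remission <- as.numeric(node$p_remission)
    node$n_unrouted <- as.integer(node$n_unrouted %||% 0L)
    if (is.null(node$split)) {
      node["split"] <- list(NULL)
      node["children"] <- list(NULL)
    } else {
      node$split$threshold <- as.numeric(node$split$threshold)
      node$split$kappa <- as.numeric(node$split$kappa)
      node$split$p_value <- as.numeric(node$split$p_value)
      node$children$ge <- fix_node(node$children$ge)
      node$children$lt <- fix_node(node$children$lt)
    }
    node
  }
  obj$root <- fix_node(obj$root)
  obj$features <- as.character(unlist(obj$features))
  obj$alpha <- as.numeric(obj$alpha)
  obj$min_node <- as.integer(obj$min_node)
  obj$n <- as.integer(obj$n)
  structure(obj, class = "roc_tree")
}

#' Read a cohort-simulation configuration from YAML
#'
#' The YAML mirrors [cohort_config()]: top-level `label_mode`,
#' `label_noise`, `seed`, feature-distribution defaults and overrides,
#' and a named `cohorts` map whose entries give `n`, optionally
#' `remission_rate`, and optionally `planted` trees per modality, each
#' with a `splits` list (`feature`, `threshold`, `leaf_side`, `leaf_p`,
#' `leaf_n`) and `final_p` / `final_n`.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  parse_planted <- function(p) {
    planted_tree(
      splits = dplyr::bind_rows(lapply(p$splits, tibble::as_tibble)),
      final_p = p$final_p, final_n = p$final_n
    )
  }
  cohorts <- lapply(names(y$cohorts), function(nm) {
    co <- y$cohorts[[nm]]
    planted <- lapply(co$planted %||% list(), parse_planted)
    cohort_spec(
      name = nm,
      # YAML 1.1 resolves a bare `n` key to boolean FALSE
      n = co[["n"]] %||% co[["FALSE"]],
      remission_rate = co$remission_rate,
      planted = planted,
      label_from = co$label_from
    )
  })
  names(cohorts) <- names(y$cohorts)
  cohort_config(
    cohorts = cohorts,
    label_mode = y$label_mode %||% "binomial",
    label_noise = y$label_noise %||% 0,
    volume_mean = y$volume_mean %||% 10,
    volume_sd = y$volume_sd %||% 2,
    fa_mean = y$fa_mean %||% 0.5,
    fa_sd = y$fa_sd %||% 0.06,
    feature_means = unlist(y$feature_means),
    feature_sds = unlist(y$feature_sds),
    seed = y$seed
  )
}
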