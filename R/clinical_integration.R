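#' Encode clinical covariates as a numeric feature matrix
#'
#' Binary covariates (logical, 0/1 numeric, or two-level factor/character)
#' become 0/1 columns; quantitative covariates pass through unchanged
#' (standardization happens inside the SVM fit). Samples with a missing
#' value in any selected variable are excluded listwise, with the excluded
#' IDs reported via a message and the `"excluded_samples"` attribute.
#'
#' @param table clinical data.frame, first column `sample_id`.
#' @param variables names of the covariates to encode.
#' @return numeric samples x variables matrix, rows named by sample ID,
#'   with attribute `excluded_samples`.
#' @export
encode_clinical <- function(table, variables) {
  if (!is.data.frame(table) || names(table)[1] != "sample_id")
    .thrombo_error("format", "clinical table must have first column sample_id")
  available <- setdiff(names(table), "sample_id")
  if (length(variables) == 0)
    .thrombo_error("config", "no clinical variables selected")
  unknown <- setdiff(variables, available)
  if (length(unknown) > 0)
    .thrombo_error("config", "unknown variable(s): %s. Available: %s",
                   paste(unknown, collapse = ", "),
                   paste(available, collapse = ", "))

  cols <- lapply(variables, function(v) .encode_column(table[[v]], v))
  m <- do.call(cbind, cols)
  dimnames(m) <- list(table$sample_id, variables)

  complete <- rowSums(is.na(m)) == 0
  excluded <- table$sample_id[!complete]
  if (length(excluded) > 0)
    message(sprintf("encode_clinical: excluded %d sample(s) with missing values: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  m <- m[complete, , drop = FALSE]
  attr(m, "excluded_samples") <- excluded
  m
}

.encode_column <- function(v, name) {
  if (is.logical(v)) return(as.numeric(v))
  if (is.numeric(v)) return(as.numeric(v))
  vals <- sort(unique(v[!is.na(v)]))
  if (length(vals) > 2)
    .thrombo_error("format",
                   "variable '%s' is non-numeric with %d levels; cannot encode",
                   name, length(vals))
  # two-level categorical: 'yes'/'no' map to 1/0, otherwise sorted order
  if (all(tolower(vals) %in% c("no", "yes")))
    return(as.numeric(tolower(v) == "yes"))
  as.numeric(match(v, vals) - 1)
}

#' Exhaustive SVM search over clinical variable subsets
#'
#' Scores every subset of 1 to `max_k` clinical variables with the same
#' linear-SVM resubstitution criterion as the protein panel search, and
#' reports the best subsets per size — so "adding a variable did not
#' improve the score" is directly checkable. Variables named in
#' `exclusions` are removed before enumeration and can never appear in a
#' reported subset. Listwise missing-value exclusion is applied per subset.
#'
#' @param table clinical data.frame, first column `sample_id`.
#' @param groups group labels (`A`/`C`) named by sample ID (e.g.
#'   `x$groups` of the matching [lfq_matrix]).
#' @param max_k largest subset size (default 3).
#' @param exclusions variable names to remove before the search.
#' @param cost SVM regularization C.
#' @return a `clinical_search_summary`: per-size best subsets (all ties)
#'   with accuracies and excluded-sample counts, overall best, and the
#'   total number of subsets tested.
#' @export
clinical_variable_search <- function(table, groups, max_k = 3,
                                     exclusions = character(), cost = 1) {
  vars <- setdiff(names(table), "sample_id")
  vars <- setdiff(vars, exclusions)
  if (length(vars) < 1)
    .thrombo_error("precondition", "no usable clinical variables after exclusions")
  max_k <- min(max_k, length(vars))

  per_size <- list()
  n_tested <- 0
  for (k in seq_len(max_k)) {
    subsets <- combn(vars, k, simplify = FALSE)
    n_tested <- n_tested + length(subsets)
    scored <- lapply(subsets, function(vs)
      .score_clinical_subset(table, groups, vs, cost))
    acc <- vapply(scored, function(s) s$accuracy_percent, numeric(1))
    best <- max(acc)
    tied <- which(acc == best)
    per_size[[k]] <- list(
      k = k, n_subsets = length(subsets), best_accuracy = best,
      top_subsets = lapply(tied, function(i)
        list(variables = subsets[[i]],
             accuracy_percent = scored[[i]]$accuracy_percent,
             n_samples = scored[[i]]$n,
             n_excluded = scored[[i]]$n_excluded,
             misclassified_ids = scored[[i]]$misclassified_ids)))
  }
  best_acc <- vapply(per_size, function(s) s$best_accuracy, numeric(1))
  structure(
    list(per_size = per_size, n_combinations_tested = n_tested,
         best_accuracy = max(best_acc),
         best_k = which.max(best_acc),
         exclusions = exclusions),
    class = "clinical_search_summary")
}

.score_clinical_subset <- function(table, groups, vs, cost) {
  m <- suppressMessages(encode_clinical(table, vs))
  ids <- rownames(m)
  labels <- as.character(groups[ids])
  if (anyNA(labels))
    .thrombo_error("alignment", "no group label for sample(s): %s",
                   paste(ids[is.na(labels)], collapse = ", "))
  if (length(unique(labels)) < 2)
    .thrombo_error("precondition",
                   "one group empty after missing-value exclusion for subset [%s]",
                   paste(vs, collapse = ", "))
  score <- .panel_score(m, labels, cost = cost)
  score$n_excluded <- length(attr(m, "excluded_samples"))
  score
}

#' @export
print.clinical_search_summary <- function(x, ...) {
  cat(sprintf("clinical_search_summary: %d subsets tested%s\n",
              x$n_combinations_tested,
              if (length(x$exclusions))
                sprintf(" (excluding %s)", paste(x$exclusions, collapse = ", "))
              else ""))
  for (s in x$per_size) {
    top <- s$top_subsets[[1]]
    cat(sprintf("  k = %d: best %.2f%% [%s]%s\n", s$k, s$best_accuracy,
                paste(top$variables, collapse = ", "),
                if (length(s$top_subsets) > 1)
                  sprintf(" (+%d tied)", length(s$top_subsets) - 1) else ""))
  }
  invisible(x)
}

#' Score a combined protein + clinical feature panel
#'
#' Concatenates the log2 LFQ columns of the named proteins with the encoded
#' clinical variables into one feature block and scores it with the linear
#' SVM and resubstitution accuracy. With an empty clinical list this
#' degenerates exactly to the protein-panel scoring; with an empty protein
#' list, to the clinical scoring. Samples excluded for missing clinical
#' values are dropped from the protein block too (the count is reported).
#'
#' @param x an [lfq_matrix]; the named proteins must be fully quantified
#'   (apply [filter_common()] first).
#' @param table clinical data.frame (only needed when clinical variables
#'   are requested).
#' @param protein_ids proteins to include (possibly empty).
#' @param clinical_variables covariates to include (possibly empty).
#' @param cost SVM regularization C.
#' @return a `classification_result` with attribute `n_excluded`.
#' @export
combined_panel_accuracy <- function(x, table = NULL,
                                    protein_ids = character(),
                                    clinical_variables = character(),
                                    cost = 1) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (length(protein_ids) == 0 && length(clinical_variables) == 0)
    .thrombo_error("config", "no features selected")

  keep_ids <- sample_ids(x)
  clin <- NULL
  if (length(clinical_variables) > 0) {
    if (is.null(table))
      .thrombo_error("config", "clinical variables requested but no clinical table given")
    clin <- encode_clinical(table, clinical_variables)
    keep_ids <- intersect(keep_ids, rownames(clin))
    if (length(keep_ids) == 0)
      .thrombo_error("alignment", "no samples shared between matrix and clinical table")
  }

  blocks <- list()
  if (length(protein_ids) > 0) {
    missing <- setdiff(protein_ids, rownames(x$intensities))
    if (length(missing) > 0)
      .thrombo_error("alignment", "protein(s) not in matrix: %s",
                     paste(missing, collapse = ", "))
    xs <- x[protein_ids, keep_ids]
    if (!all(xs$valid_mask))
      .thrombo_error("precondition",
                     "selected proteins have missing values; apply filter_common() first")
    if (!xs$log2) xs <- log2_transform(xs)
    blocks$proteins <- t(xs$intensities)
  }
  if (!is.null(clin)) blocks$clinical <- clin[keep_ids, , drop = FALSE]

  feats <- do.call(cbind, blocks)
  labels <- as.character(x$groups[keep_ids])
  if (length(unique(labels)) < 2)
    .thrombo_error("precondition", "one group empty after sample alignment")
  n_excluded <- length(sample_ids(x)) - length(keep_ids)
  if (n_excluded > 0)
    message(sprintf("combined_panel_accuracy: %d sample(s) excluded for missing clinical values",
                    n_excluded))
  res <- .panel_score(feats, labels, cost = cost)
  attr(res, "n_excluded") <- n_excluded
  res
}
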