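#' Run the end-to-end two-group LFQ analysis pipeline
#'
#' Read the LFQ table and annotation, select leading proteins, keep the
#' commonly detected proteins, run the exhaustive SVM panel search, compute
#' per-protein Wilcoxon statistics for the top-panel members, run the
#' minimum-valid-fraction filter plus t-test volcano analysis, and — when a
#' clinical table is supplied — the clinical-variable SVM search and an
#' optional combined protein + clinical scoring. Returns (and optionally
#' writes) a single results envelope embedding the fully resolved
#' configuration, so a rerun from the same inputs reproduces it exactly.
#'
#' @param lfq_path tab-delimited LFQ protein table (see [read_lfq_table()]).
#' @param annotation_path sample annotation CSV (`sample_id`, `group`).
#' @param clinical_path optional clinical covariate CSV.
#' @param out_dir optional directory: writes `envelope.json`,
#'   `volcano.tsv` and `top_panels.tsv`.
#' @param k panel size of the protein search (default 3).
#' @param cost SVM regularization C.
#' @param min_valid_fraction valid-fraction threshold of the volcano branch.
#' @param var_equal pooled-variance Student t instead of Welch.
#' @param alpha significance threshold of the volcano flags.
#' @param clinical_max_k largest clinical subset size.
#' @param clinical_exclusions clinical variables excluded from the search.
#' @param combined optional list with elements `protein_ids` and/or
#'   `clinical_variables` for a combined panel score.
#' @param chunk_size,checkpoint passed to [search_panels()].
#' @return the results envelope (list), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(lfq_path, annotation_path, clinical_path = NULL,
                         out_dir = NULL, k = 3, cost = 1,
                         min_valid_fraction = 0.5, var_equal = FALSE,
                         alpha = 0.05, clinical_max_k = 3,
                         clinical_exclusions = character(),
                         combined = NULL, chunk_size = NULL,
                         checkpoint = NULL) {
  config <- list(
    lfq_path = lfq_path, annotation_path = annotation_path,
    clinical_path = clinical_path, k = k, cost = cost,
    min_valid_fraction = min_valid_fraction, var_equal = var_equal,
    alpha = alpha, clinical_max_k = clinical_max_k,
    clinical_exclusions = clinical_exclusions, combined = combined)

  lfq <- read_lfq_table(lfq_path, annotation_path)
  common <- filter_common(lfq)
  message(sprintf("pipeline: %d proteins read, %d common to all %d samples",
                  nrow(lfq$intensities), common$report$n_retained,
                  ncol(lfq$intensities)))

  search <- search_panels(common$matrix, k = k, cost = cost,
                          chunk_size = chunk_size, checkpoint = checkpoint)
  message(sprintf("pipeline: %s combinations tested, best accuracy %.1f%%",
                  format(search$n_combinations_tested, big.mark = ","),
                  search$best_accuracy))

  log2_common <- log2_transform(common$matrix)
  panel_proteins <- unique(unlist(lapply(search$top_panels, `[[`, "protein_ids")))
  wilcoxon <- lapply(panel_proteins, function(pid) {
    vals <- log2_common$intensities[pid, ]
    wilcoxon_rank_sum(vals[log2_common$groups == "C"],
                      vals[log2_common$groups == "A"], protein_id = pid)
  })

  half <- filter_min_valid(lfq, min_valid_fraction)
  volcano <- welch_t_volcano(log2_transform(half$matrix),
                             var_equal = var_equal, alpha = alpha)

  clinical <- NULL
  combined_res <- NULL
  if (!is.null(clinical_path)) {
    clin_tab <- read_clinical_table(clinical_path, lfq)
    clinical <- clinical_variable_search(clin_tab, lfq$groups,
                                         max_k = clinical_max_k,
                                         exclusions = clinical_exclusions,
                                         cost = cost)
    if (!is.null(combined)) {
      combined_res <- combined_panel_accuracy(
        common$matrix, clin_tab,
        protein_ids = combined$protein_ids %||% character(),
        clinical_variables = combined$clinical_variables %||% character(),
        cost = cost)
    }
  }

  envelope <- list(
    package_version = as.character(utils::packageVersion("thromboSVM")),
    config = config,
    input = list(n_proteins = nrow(lfq$intensities),
                 n_samples = ncol(lfq$intensities),
                 n_group_c = sum(lfq$groups == "C"),
                 n_group_a = sum(lfq$groups == "A")),
    filter_common = common$report[c("n_input", "n_retained", "rule")],
    search = .search_to_list(search),
    wilcoxon_top_panel = lapply(wilcoxon, unclass),
    filter_min_valid = half$report[c("n_input", "n_retained", "rule")],
    volcano = list(n_tested = sum(!volcano$untestable),
                   n_significant = sum(volcano$significant),
                   significant = volcano[volcano$significant,
                                         c("protein_id", "difference",
                                           "p_value", "neg_log10_p")]),
    clinical = if (!is.null(clinical)) .clinical_to_list(clinical),
    combined = if (!is.null(combined_res))
      list(accuracy_percent = combined_res$accuracy_percent,
           n = combined_res$n,
           n_excluded = attr(combined_res, "n_excluded"),
           misclassified_ids = combined_res$misclassified_ids))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(envelope, file.path(out_dir, "envelope.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    write.table(volcano, file.path(out_dir, "volcano.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    panels_df <- data.frame(
      panel = vapply(search$top_panels, function(p)
        paste(p$protein_ids, collapse = ";"), character(1)),
      accuracy_percent = vapply(search$top_panels, function(p)
        p$accuracy_percent, numeric(1)))
    write.table(panels_df, file.path(out_dir, "top_panels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(envelope))
  }
  envelope
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.search_to_list <- function(s) {
  list(n_combinations_tested = s$n_combinations_tested, k = s$k,
       best_accuracy = s$best_accuracy,
       top_panels = lapply(s$top_panels, function(p)
         list(protein_ids = p$protein_ids,
              accuracy_percent = p$accuracy_percent,
              misclassified_ids = p$misclassified_ids)),
       core_proteins = s$core_proteins)
}

.clinical_to_list <- function(cs) {
  list(n_combinations_tested = cs$n_combinations_tested,
       best_accuracy = cs$best_accuracy, best_k = cs$best_k,
       exclusions = cs$exclusions,
       per_size = lapply(cs$per_size, function(s)
         list(k = s$k, n_subsets = s$n_subsets,
              best_accuracy = s$best_accuracy,
              top_subsets = lapply(s$top_subsets, function(t)
                list(variables = t$variables,
                     accuracy_percent = t$accuracy_percent,
                     n_samples = t$n_samples,
                     n_excluded = t$n_excluded)))))
}

#' Write a ready-made synthetic fixture cohort to disk
#'
#' Wraps [simulate_cohort()] + [write_cohort()] with three presets:
#' `"tiny"` (6 + 6 samples, 40 proteins, 2 planted; completes in well under
#' a second), `"cohort-like"` (32 cardioembolic-like + 28
#' atherothrombotic-like samples, 2,455 proteins with intensity-dependent
#' missingness, 3 planted), and `"null"` (as tiny but with no planted
#' proteins and no group effect anywhere).
#'
#' @param preset one of `"tiny"`, `"cohort-like"`, `"null"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the list of file paths from [write_cohort()], with
#'   the simulation attached as attribute `"sim"`.
#' @export
make_fixture <- function(preset = c("tiny", "cohort-like", "null"),
                         seed = 1, dir) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    "tiny" = simulation_config(
      n_group_c = 6, n_group_a = 6, n_proteins = 40, n_planted = 2,
      effect_size = 2.5, missing_rate = 0.1, missing_intensity_slope = 3,
      seed = seed,
      clinical_spec = list(clin_binary("atrial_fibrillation", 0.625, 0.036),
                           clin_quant("age", 79.5, 67.5, 9))),
    "cohort-like" = simulation_config(seed = seed),
    "null" = simulation_config(
      n_group_c = 6, n_group_a = 6, n_proteins = 40, n_planted = 0,
      effect_size = 0, missing_rate = 0.1, missing_intensity_slope = 3,
      seed = seed,
      clinical_spec = list(clin_binary("atrial_fibrillation", 0.5, 0.5),
                           clin_quant("age", 72, 72, 9))))
  sim <- simulate_cohort(cfg)
  paths <- write_cohort(sim, dir)
  attr(paths, "sim") <- sim
  invisible(paths)
}
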