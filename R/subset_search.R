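#' Count or enumerate k-combinations of n features
#'
#' `count_combinations()` is the closed-form binomial coefficient;
#' `stream_count_combinations()` counts by actually iterating the
#' lexicographic enumeration (the same loop the panel search walks), which
#' lets the two be cross-checked; `enumerate_combinations()` materializes
#' all strictly increasing k-tuples in lexicographic order.
#'
#' @param n number of features (>= 1).
#' @param k combination size, `1 <= k <= n` (panel search uses `k <= 3`).
#' @return `count_combinations` / `stream_count_combinations`: the count as
#'   a numeric scalar. `enumerate_combinations`: an integer `k x count`
#'   matrix, columns in lexicographic order.
#' @export
count_combinations <- function(n, k) {
  .check_nk(n, k)
  round(choose(n, k))
}

#' @rdname count_combinations
#' @export
stream_count_combinations <- function(n, k) {
  .check_nk(n, k)
  .count_combinations_stream_cpp(as.integer(n), as.integer(k))
}

#' @rdname count_combinations
#' @export
enumerate_combinations <- function(n, k) {
  .check_nk(n, k)
  if (count_combinations(n, k) > 2e6)
    .thrombo_error("config",
                   "refusing to materialize > 2e6 combinations; use search_panels/stream_count_combinations")
  combn(n, k)
}

.check_nk <- function(n, k) {
  if (!is.numeric(n) || !is.numeric(k) || length(n) != 1 || length(k) != 1 ||
      is.na(n) || is.na(k) || k < 1 || n < 1 ||
      n != floor(n) || k != floor(k))
    .thrombo_error("config", "n and k must be positive integers")
  if (k > n)
    .thrombo_error("config", "k (%d) must not exceed n (%d)", k, n)
  invisible(TRUE)
}

#' Exhaustive SVM panel search over protein combinations
#'
#' Scores every combination of `k` proteins (default trios) of a fully
#' quantified LFQ matrix with a linear soft-margin SVM and resubstitution
#' accuracy, and reports all panels tied at the maximum accuracy plus the
#' proteins common to every top panel. Accuracy ties are exact (they are
#' integer counts of correctly classified samples), so all panels at the
#' maximum are retained rather than one arbitrary winner.
#'
#' Features are the log2 LFQ intensities (the matrix is log2-transformed on
#' the fly when still on the raw scale), z-scored per protein inside each
#' fit. The enumeration is lexicographic and can be split into chunks of
#' combination ranks; the reduction over chunks is order-independent, so
#' chunked and serial runs return identical summaries, and an optional
#' checkpoint file makes long searches restartable.
#'
#' @param x an [lfq_matrix] with no invalid cells (apply [filter_common()]
#'   first).
#' @param k panel size, 1-3 (default 3).
#' @param cost SVM regularization parameter C.
#' @param chunk_size combinations per chunk; `NULL` (default) runs one chunk.
#' @param top_margin also retain panels within this many accuracy percentage
#'   points of the best (default 0: ties only).
#' @param checkpoint optional path to a JSON checkpoint updated after every
#'   chunk; an existing checkpoint resumes the search.
#' @param tol,max_iter SMO solver settings (see [fit_svm()]).
#' @param max_store cap on retained panels per chunk (a warning reports
#'   overflow).
#' @return a `search_summary`: `n_combinations_tested`, `best_accuracy`
#'   (percent, full precision), `top_panels` (list of `panel_result`:
#'   sorted `protein_ids`, `accuracy_percent`, geometric `margin`,
#'   `misclassified_ids` — ordered by decreasing margin, the SVM's own
#'   secondary criterion, so the first entry is a deterministic
#'   representative of the tie), `core_proteins` (intersection of all top
#'   panels), and `panels_within_margin` (data.frame, only when
#'   `top_margin > 0`).
#' @export
search_panels <- function(x, k = 3, cost = 1, chunk_size = NULL,
                          top_margin = 0, checkpoint = NULL,
                          tol = 1e-6, max_iter = 20000L,
                          max_store = 200000L) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (!all(x$valid_mask))
    .thrombo_error("precondition",
                   "matrix contains missing cells; apply filter_common() first")
  if (!x$log2) x <- log2_transform(x)
  p <- nrow(x$intensities)
  .check_nk(p, k)
  if (k > 3)
    .thrombo_error("config", "panel size k must be 1, 2 or 3")

  feats <- t(x$intensities)                       # samples x proteins
  y <- ifelse(as.character(x$groups) == "C", 1L, -1L)
  n <- length(y)
  total <- count_combinations(p, k)
  slack <- as.integer(floor(top_margin * n / 100 + 1e-9))

  state <- list(next_rank = 0, n_tested = 0, best_correct = -1L,
                panels = matrix(integer(0), 0, k),
                panel_correct = integer(0), panel_margin = numeric(0))
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    st <- jsonlite::read_json(checkpoint, simplifyVector = TRUE)
    state$next_rank <- st$next_rank
    state$n_tested <- st$n_tested
    state$best_correct <- as.integer(st$best_correct)
    state$panel_correct <- as.integer(st$panel_correct)
    state$panel_margin <- as.numeric(st$panel_margin)
    state$panels <- matrix(as.integer(st$panels), ncol = k)
  }

  step <- if (is.null(chunk_size)) total else as.numeric(chunk_size)
  while (state$next_rank < total) {
    end <- min(state$next_rank + step, total)
    res <- .svm_search_cpp(feats, y, as.integer(k), cost, tol,
                           as.integer(max_iter), state$next_rank, end,
                           slack, as.integer(max_store))
    if (isTRUE(res$overflow))
      warning("panel store overflowed max_store; reported tied panels may be incomplete")
    state <- .reduce_search(state, res, end, slack, k)
    if (!is.null(checkpoint))
      jsonlite::write_json(
        list(next_rank = state$next_rank, n_tested = state$n_tested,
             best_correct = state$best_correct,
             panels = as.integer(state$panels),
             panel_correct = state$panel_correct,
             panel_margin = state$panel_margin),
        checkpoint, auto_unbox = TRUE, digits = NA)
  }

  .summarize_search(state, x, feats, cost, tol, max_iter, k, n,
                    top_margin, slack)
}

.reduce_search <- function(state, res, end, slack, k) {
  best <- max(state$best_correct, res$best_correct)
  keep_old <- state$panel_correct >= best - slack
  keep_new <- res$panel_correct >= best - slack
  state$panels <- rbind(state$panels[keep_old, , drop = FALSE],
                        res$panels[keep_new, , drop = FALSE])
  state$panel_correct <- c(state$panel_correct[keep_old],
                           res$panel_correct[keep_new])
  state$panel_margin <- c(state$panel_margin[keep_old],
                          res$panel_margin[keep_new])
  state$best_correct <- best
  state$n_tested <- state$n_tested + res$n_tested
  state$next_rank <- end
  state
}

.summarize_search <- function(state, x, feats, cost, tol, max_iter, k, n,
                              top_margin, slack) {
  ids <- protein_ids(x)
  labels <- as.character(x$groups)

  is_top <- state$panel_correct == state$best_correct
  top_idx <- which(is_top)
  panel_ids <- lapply(top_idx, function(r) sort(ids[state$panels[r, ]]))
  # exact accuracy ties are ordered by decreasing geometric margin (the
  # SVM's own secondary criterion), then canonically by protein IDs, so the
  # first top panel is a deterministic, permutation-invariant representative
  ord <- order(-state$panel_margin[top_idx],
               vapply(panel_ids, paste, character(1), collapse = "\r"))
  top_idx <- top_idx[ord]
  panel_ids <- panel_ids[ord]

  top_panels <- lapply(seq_along(top_idx), function(ii) {
    r <- top_idx[ii]
    cols <- state$panels[r, ]
    score <- .panel_score(feats[, cols, drop = FALSE], labels,
                          cost = cost, tol = tol, max_iter = max_iter)
    structure(list(protein_ids = panel_ids[[ii]],
                   accuracy_percent = score$accuracy_percent,
                   margin = state$panel_margin[r],
                   misclassified_ids = score$misclassified_ids),
              class = "panel_result")
  })

  within <- NULL
  if (top_margin > 0 && length(state$panel_correct) > 0) {
    keep <- state$panel_correct >= state$best_correct - slack
    within <- data.frame(
      panel = vapply(which(keep), function(r)
        paste(sort(ids[state$panels[r, ]]), collapse = ";"), character(1)),
      accuracy_percent = 100 * state$panel_correct[keep] / n,
      stringsAsFactors = FALSE)
    within <- within[order(-within$accuracy_percent, within$panel), ]
    rownames(within) <- NULL
  }

  structure(
    list(n_combinations_tested = state$n_tested,
         k = k, n_samples = n, cost = cost,
         best_accuracy = 100 * state$best_correct / n,
         top_panels = top_panels,
         core_proteins = core_protein_summary(top_panels),
         panels_within_margin = within),
    class = "search_summary")
}

#' Proteins present in every top-ranked panel
#'
#' The exact set intersection of the protein memberships of the tied best
#' panels; recurring members (a protein present in all top trios) are the
#' search's most robust signal.
#'
#' @param top_panels non-empty list of `panel_result` objects (or of
#'   character vectors of protein IDs).
#' @return character vector of the common protein IDs (possibly empty).
#' @export
core_protein_summary <- function(top_panels) {
  if (length(top_panels) == 0)
    .thrombo_error("precondition", "top_panels must be non-empty")
  sets <- lapply(top_panels, function(p)
    if (inherits(p, "panel_result")) p$protein_ids else as.character(p))
  sort(Reduce(intersect, sets))
}

#' @export
print.search_summary <- function(x, ...) {
  cat(sprintf("search_summary: %s combinations tested (k = %d, %d samples)\n",
              format(x$n_combinations_tested, big.mark = ","),
              x$k, x$n_samples))
  cat(sprintf("  best resubstitution accuracy: %.1f%% (%d tied panel(s))\n",
              x$best_accuracy, length(x$top_panels)))
  show <- utils::head(x$top_panels, 5)
  for (p in show)
    cat(sprintf("    [%s]  margin %.3f\n",
                paste(p$protein_ids, collapse = ", "), p$margin))
  if (length(x$top_panels) > length(show))
    cat(sprintf("    ... and %d more\n", length(x$top_panels) - length(show)))
  cat(sprintf("  core proteins: %s\n",
              if (length(x$core_proteins)) paste(x$core_proteins, collapse = ", ")
              else "(none)"))
  invisible(x)
}
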