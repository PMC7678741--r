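#' LFQ intensity matrix with explicit missingness and group labels
#'
#' The central container of the package: a protein-by-sample matrix of
#' label-free quantification (LFQ) intensities, an explicit validity mask
#' (MaxQuant writes 0 for proteins not quantified in a sample; zeros and
#' blanks are treated as missing, never as measured values), and a two-level
#' group factor over the samples (levels `"A"` for atherothrombotic-like and
#' `"C"` for cardioembolic-like samples).
#'
#' Invalid cells are stored as `NA` in `intensities` and `FALSE` in
#' `valid_mask`; downstream operations only ever consume valid cells.
#'
#' @param intensities numeric protein x sample matrix with protein row names
#'   and sample column names. Cells that are `NA`, zero or negative are
#'   treated as missing unless an explicit `valid_mask` is supplied.
#' @param groups group label per sample: a character or factor vector with
#'   values in `{"A", "C"}`, either named by sample or in column order.
#' @param valid_mask optional logical matrix of the same shape; `TRUE` marks
#'   a quantified cell.
#' @param log2 logical; `TRUE` if `intensities` are already on the log2
#'   scale (in which case zeros are legitimate values and only `NA` cells
#'   are invalid by default).
#'
#' @return an object of class `lfq_matrix`: a list with elements
#'   `intensities` (invalid cells `NA`), `valid_mask`, `groups` (factor with
#'   levels `A`, `C`, named by sample) and `log2`.
#' @export
lfq_matrix <- function(intensities, groups, valid_mask = NULL, log2 = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    .thrombo_error("format", "intensities must be a numeric matrix")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("P%04d", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    .thrombo_error("format", "intensity matrix must have sample column names")

  if (is.null(valid_mask)) {
    valid_mask <- if (log2) !is.na(intensities)
                  else !is.na(intensities) & intensities > 0
  }
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), dim(intensities)))
    .thrombo_error("format", "valid_mask must be a logical matrix of the same shape")
  dimnames(valid_mask) <- dimnames(intensities)
  intensities[!valid_mask] <- NA_real_

  groups <- .resolve_groups(groups, colnames(intensities))

  structure(
    list(intensities = intensities, valid_mask = valid_mask,
         groups = groups, log2 = isTRUE(log2)),
    class = "lfq_matrix"
  )
}

.resolve_groups <- function(groups, sample_ids) {
  if (!is.null(names(groups))) {
    missing <- setdiff(sample_ids, names(groups))
    if (length(missing) > 0)
      .thrombo_error("alignment", "no group label for sample(s): %s",
                     paste(missing, collapse = ", "))
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    .thrombo_error("alignment",
                   "groups has length %d but there are %d samples",
                   length(groups), length(sample_ids))
  }
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("A", "C"))
  if (length(bad) > 0)
    .thrombo_error("format", "group labels must be 'A' or 'C' (found: %s)",
                   paste(bad, collapse = ", "))
  groups <- factor(groups, levels = c("A", "C"))
  if (any(table(groups) == 0))
    .thrombo_error("config", "both groups A and C must be non-empty")
  names(groups) <- sample_ids
  groups
}

#' @export
dim.lfq_matrix <- function(x) dim(x$intensities)

#' Protein and sample identifiers of an LFQ matrix
#' @param x an [lfq_matrix]
#' @return character vector of identifiers.
#' @export
protein_ids <- function(x) rownames(x$intensities)

#' @rdname protein_ids
#' @export
sample_ids <- function(x) colnames(x$intensities)

#' @export
print.lfq_matrix <- function(x, ...) {
  d <- dim(x)
  tab <- table(x$groups)
  cat(sprintf(
    "lfq_matrix: %d proteins x %d samples (%d C, %d A), %s scale\n",
    d[1], d[2], tab[["C"]], tab[["A"]], if (x$log2) "log2" else "raw"))
  cat(sprintf("  valid cells: %d/%d (%.1f%%)\n",
              sum(x$valid_mask), length(x$valid_mask),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' @export
`[.lfq_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  lfq_matrix(x$intensities[i, j, drop = FALSE],
             groups = x$groups[j],
             valid_mask = x$valid_mask[i, j, drop = FALSE],
             log2 = x$log2)
}
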