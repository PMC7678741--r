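#' Keep only proteins quantified in every sample
#'
#' The "commonly detected" filter: an SVM over a protein panel cannot handle
#' missing feature values, so the panel search operates on the subset of
#' proteins with a valid LFQ value in all samples.
#'
#' @param x an [lfq_matrix].
#' @return list with `matrix` (the filtered [lfq_matrix], no invalid cells)
#'   and `report` (a `filter_report`: `n_input`, `n_retained`, `rule`,
#'   `per_protein_valid_fraction`).
#' @export
filter_common <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  frac <- rowMeans(x$valid_mask)
  keep <- frac == 1
  if (!any(keep))
    warning("filter_common: no protein is quantified in every sample")
  report <- structure(
    list(n_input = nrow(x$intensities), n_retained = sum(keep),
         rule = "valid in all samples",
         per_protein_valid_fraction = setNames(frac, protein_ids(x))),
    class = "filter_report")
  list(matrix = x[keep, ], report = report)
}

#' Keep proteins with at least a minimum fraction of valid values
#'
#' Retains proteins whose fraction of valid LFQ values is at least
#' `min_fraction` (inclusive boundary). By default the fraction is counted
#' over all samples; `per_group = TRUE` switches to the per-group variant
#' that keeps a protein if it reaches the fraction in at least one group.
#'
#' @param x an [lfq_matrix].
#' @param min_fraction required valid fraction, in `(0, 1]`; default 0.5.
#' @param per_group logical; count the fraction within each group and
#'   require it in at least one group.
#' @return as [filter_common()].
#' @export
filter_min_valid <- function(x, min_fraction = 0.5, per_group = FALSE) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      is.na(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    .thrombo_error("config", "min_fraction must be in (0, 1]")
  frac <- rowMeans(x$valid_mask)
  if (per_group) {
    keep <- rep(FALSE, nrow(x$intensities))
    for (g in levels(x$groups)) {
      cols <- x$groups == g
      keep <- keep | rowMeans(x$valid_mask[, cols, drop = FALSE]) >= min_fraction
    }
    rule <- sprintf("valid fraction >= %g in at least one group", min_fraction)
  } else {
    keep <- frac >= min_fraction
    rule <- sprintf("valid fraction >= %g over all samples", min_fraction)
  }
  report <- structure(
    list(n_input = nrow(x$intensities), n_retained = sum(keep), rule = rule,
         per_protein_valid_fraction = setNames(frac, protein_ids(x))),
    class = "filter_report")
  list(matrix = x[keep, ], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d / %d proteins retained (%s)\n",
              x$n_retained, x$n_input, x$rule))
  invisible(x)
}

#' Log2-transform the valid intensities of an LFQ matrix
#'
#' Valid cells are replaced by `log2(intensity)`; the validity mask is
#' unchanged. Valid cells must be strictly positive (zeros denote missing
#' values and must already be masked).
#'
#' @param x an [lfq_matrix] on the raw intensity scale.
#' @return the [lfq_matrix] on the log2 scale.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$log2)
    .thrombo_error("precondition", "matrix is already log2-transformed")
  v <- x$intensities[x$valid_mask]
  if (any(v <= 0))
    .thrombo_error("precondition",
                   "valid intensities must be > 0 (zeros should be masked as missing)")
  intens <- x$intensities
  intens[x$valid_mask] <- log2(v)
  lfq_matrix(intens, groups = x$groups, valid_mask = x$valid_mask, log2 = TRUE)
}
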