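#' A MaxQuant-style protein group record
#'
#' One row of a proteinGroups table: the candidate protein identifiers that
#' share the identified peptide evidence, with per-candidate peptide counts
#' and annotation-quality metadata used to pick a single representative
#' ("leading") protein.
#'
#' @param candidate_ids character vector of candidate protein IDs (non-empty).
#' @param peptide_counts integer vector, one count per candidate (>= 0).
#' @param reviewed optional logical per candidate: curated (reviewed)
#'   database entry.
#' @param evidence optional integer per candidate: protein-existence
#'   evidence level, lower = stronger.
#' @param go_count optional integer per candidate: number of Gene Ontology
#'   annotations.
#' @param is_contaminant logical flag for the whole group.
#' @return a `protein_group_record`.
#' @export
protein_group_record <- function(candidate_ids, peptide_counts,
                                 reviewed = NULL, evidence = NULL,
                                 go_count = NULL, is_contaminant = FALSE) {
  if (length(candidate_ids) == 0)
    .thrombo_error("format", "candidate_ids must be non-empty")
  if (length(peptide_counts) != length(candidate_ids))
    .thrombo_error("format", "peptide_counts must match candidate_ids in length")
  if (any(is.na(peptide_counts)) || any(peptide_counts < 0))
    .thrombo_error("format", "peptide_counts must be non-negative")
  structure(
    list(candidate_ids = as.character(candidate_ids),
         peptide_counts = as.numeric(peptide_counts),
         reviewed = reviewed, evidence = evidence, go_count = go_count,
         is_contaminant = isTRUE(is_contaminant)),
    class = "protein_group_record"
  )
}

#' Select the leading protein of a protein group
#'
#' Two-step rule: candidates with the maximal identified-peptide count form
#' the "match group"; among those, the best-annotated candidate wins —
#' reviewed (curated) entries first, then strongest protein-existence
#' evidence (lowest ordinal), then the most Gene Ontology annotations.
#' A final lexicographic tiebreak on the identifier guarantees determinism
#' even when all annotation metadata tie.
#'
#' @param record a [protein_group_record()].
#' @return the selected protein identifier (character scalar).
#' @export
select_leading_protein <- function(record) {
  stopifnot(inherits(record, "protein_group_record"))
  n <- length(record$candidate_ids)
  idx <- which(record$peptide_counts == max(record$peptide_counts))
  if (length(idx) == 1) return(record$candidate_ids[idx])

  rev_key <- if (is.null(record$reviewed)) rep(0, n) else -as.numeric(record$reviewed)
  evi_key <- if (is.null(record$evidence)) rep(0, n) else as.numeric(record$evidence)
  go_key  <- if (is.null(record$go_count)) rep(0, n) else -as.numeric(record$go_count)
  ord <- order(rev_key[idx], evi_key[idx], go_key[idx],
               record$candidate_ids[idx], method = "radix")
  record$candidate_ids[idx[ord[1]]]
}

#' Read a tab-delimited LFQ protein table with sample annotation
#'
#' Parses a MaxQuant-proteinGroups-style table: a `Protein IDs` column
#' (semicolon-separated candidates), an optional `Peptide counts` column
#' (semicolon-separated, used with the optional `Reviewed` / `Evidence` /
#' `GO count` columns to select the leading protein per group), an optional
#' `Contaminant` flag column, and one `LFQ intensity <sample>` column per
#' sample. Zeros and empty cells are recorded as missing (invalid mask);
#' contaminant and reversed-decoy rows (flag column marked `+`, or IDs
#' prefixed `CON__` / `REV__`) are dropped with a message reporting the
#' count.
#'
#' @param path path to the tab-delimited protein table.
#' @param annotation path to a CSV with columns `sample_id` and
#'   `group` (`A` or `C`) covering every LFQ sample column.
#' @return an [lfq_matrix] on the raw intensity scale, rows named by
#'   leading protein.
#' @export
read_lfq_table <- function(path, annotation) {
  if (!file.exists(path))
    .thrombo_error("format", "LFQ table not found: %s", path)
  if (!file.exists(annotation))
    .thrombo_error("alignment", "annotation file not found: %s", annotation)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  if (!"Protein IDs" %in% names(tab))
    .thrombo_error("format", "missing 'Protein IDs' column")
  lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  if (length(lfq_cols) == 0)
    .thrombo_error("format", "no 'LFQ intensity <sample>' columns found")
  samples <- sub("^LFQ intensity ", "", lfq_cols)

  ann <- read.csv(annotation, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ann)))
    .thrombo_error("format", "annotation needs columns sample_id, group")
  unknown <- setdiff(samples, ann$sample_id)
  if (length(unknown) > 0)
    .thrombo_error("alignment", "sample(s) missing from annotation: %s",
                   paste(unknown, collapse = ", "))
  groups <- setNames(ann$group, ann$sample_id)[samples]

  # contaminant / decoy removal
  flag_col <- intersect(c("Contaminant", "Potential contaminant", "Reverse"),
                        names(tab))
  flagged <- rep(FALSE, nrow(tab))
  for (fc in flag_col)
    flagged <- flagged | (!is.na(tab[[fc]]) & tab[[fc]] == "+")
  flagged <- flagged | grepl("^(CON__|REV__)", tab[["Protein IDs"]])
  if (any(flagged)) {
    message(sprintf("read_lfq_table: removed %d contaminant/decoy row(s)",
                    sum(flagged)))
    tab <- tab[!flagged, , drop = FALSE]
  }
  if (nrow(tab) == 0)
    .thrombo_error("format", "no protein rows left after contaminant removal")

  ids <- .leading_ids(tab)
  intens <- as.matrix(tab[, lfq_cols, drop = FALSE])
  storage.mode(intens) <- "double"
  intens[is.na(intens)] <- 0
  dimnames(intens) <- list(make.unique(ids), samples)
  lfq_matrix(intens, groups = groups, log2 = FALSE)
}

.leading_ids <- function(tab) {
  ids_split <- strsplit(tab[["Protein IDs"]], ";", fixed = TRUE)
  if (!"Peptide counts" %in% names(tab))
    return(vapply(ids_split, `[[`, character(1), 1))
  cnt_split <- strsplit(as.character(tab[["Peptide counts"]]), ";", fixed = TRUE)
  split_col <- function(col, cast) {
    if (!col %in% names(tab)) return(NULL)
    lapply(strsplit(as.character(tab[[col]]), ";", fixed = TRUE), cast)
  }
  rev_split <- split_col("Reviewed", function(v) v %in% c("1", "TRUE", "yes", "+"))
  evi_split <- split_col("Evidence", as.numeric)
  go_split  <- split_col("GO count", as.numeric)
  vapply(seq_along(ids_split), function(r) {
    rec <- protein_group_record(
      ids_split[[r]], as.numeric(cnt_split[[r]]),
      reviewed = if (is.null(rev_split)) NULL else rev_split[[r]],
      evidence = if (is.null(evi_split)) NULL else evi_split[[r]],
      go_count = if (is.null(go_split)) NULL else go_split[[r]])
    select_leading_protein(rec)
  }, character(1))
}

#' Write an LFQ matrix in the tab-delimited dialect [read_lfq_table()] reads
#'
#' Missing (masked) cells are written as 0, the MaxQuant convention.
#'
#' @param x an [lfq_matrix] on the raw intensity scale.
#' @param path output path.
#' @param peptide_counts optional integer vector per protein (defaults to 1).
#' @return invisibly, `path`.
#' @export
write_lfq_table <- function(x, path, peptide_counts = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (x$log2)
    .thrombo_error("precondition", "write_lfq_table expects raw-scale intensities")
  intens <- x$intensities
  intens[!x$valid_mask] <- 0
  if (is.null(peptide_counts)) peptide_counts <- rep(1L, nrow(intens))
  out <- data.frame(`Protein IDs` = rownames(intens),
                    `Peptide counts` = peptide_counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  ic <- as.data.frame(intens)
  names(ic) <- paste0("LFQ intensity ", colnames(intens))
  out <- cbind(out, ic)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfq_table
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "lfq_matrix"))
  write.csv(data.frame(sample_id = sample_ids(x),
                       group = as.character(x$groups)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' CSV with first column `sample_id`; remaining columns are binary or
#' quantitative covariates with per-cell missingness allowed.
#'
#' @param path CSV path.
#' @param lfq optional [lfq_matrix]; when given, the table must cover all
#'   its samples and is reordered to match.
#' @return data.frame with first column `sample_id`.
#' @export
read_clinical_table <- function(path, lfq = NULL) {
  if (!file.exists(path))
    .thrombo_error("format", "clinical table not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    .thrombo_error("format", "first column of the clinical table must be sample_id")
  if (!is.null(lfq)) {
    missing <- setdiff(sample_ids(lfq), tab$sample_id)
    if (length(missing) > 0)
      .thrombo_error("alignment", "clinical table lacks sample(s): %s",
                     paste(missing, collapse = ", "))
    tab <- tab[match(sample_ids(lfq), tab$sample_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
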