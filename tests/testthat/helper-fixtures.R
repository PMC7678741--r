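# Shared fixture builders and independent oracles for the test suite.

# small lfq_matrix from an intensity matrix (zeros/NAs -> missing)
toy_lfq <- function(intens, groups, log2 = FALSE) {
  if (is.null(rownames(intens)))
    rownames(intens) <- sprintf("P%02d", seq_len(nrow(intens)))
  if (is.null(colnames(intens)))
    colnames(intens) <- sprintf("S%02d", seq_len(ncol(intens)))
  lfq_matrix(intens, groups = groups, log2 = log2)
}

# MaxQuant-proteinGroups-style TSV on disk; returns list(lfq=, annotation=)
write_maxquant_fixture <- function(dir, intens, groups,
                                   protein_ids = NULL, peptide_counts = NULL,
                                   contaminant = NULL, extra_cols = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(intens)
  if (is.null(protein_ids)) protein_ids <- sprintf("P%02d", seq_len(n))
  if (is.null(peptide_counts)) peptide_counts <- rep(1, n)
  if (is.null(colnames(intens)))
    colnames(intens) <- sprintf("S%02d", seq_len(ncol(intens)))
  tab <- data.frame(`Protein IDs` = protein_ids,
                    `Peptide counts` = peptide_counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(contaminant)) tab[["Contaminant"]] <- contaminant
  for (nm in names(extra_cols)) tab[[nm]] <- extra_cols[[nm]]
  ic <- as.data.frame(intens)
  names(ic) <- paste0("LFQ intensity ", colnames(intens))
  tab <- cbind(tab, ic)
  lfq_path <- file.path(dir, "lfq.tsv")
  write.table(tab, lfq_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann_path <- file.path(dir, "annotation.csv")
  write.csv(data.frame(sample_id = colnames(intens), group = groups),
            ann_path, row.names = FALSE)
  list(lfq = lfq_path, annotation = ann_path)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n, n_a) assignments of the observed ranks to group A (no ties assumed).
# The rank-sum null is symmetric, so the symmetric-tail p equals the
# doubled one-tail p used by the exact test.
perm_wilcoxon_p <- function(values_c, values_a) {
  all_v <- c(values_a, values_c)
  n <- length(all_v)
  n_a <- length(values_a)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n_a)])
  ew <- n_a * (n + 1) / 2
  assignments <- utils::combn(n, n_a)
  w_all <- apply(assignments, 2, function(ix) sum(r[ix]))
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

# nested-loop enumeration of strictly increasing k-tuples (k <= 3)
combos_nested_loop <- function(n, k) {
  out <- list()
  if (k == 1) {
    for (i in seq_len(n)) out[[length(out) + 1]] <- i
  } else if (k == 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      out[[length(out) + 1]] <- c(i, j)
  } else if (k == 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (l in (j + 1):n)
      out[[length(out) + 1]] <- c(i, j, l)
  } else stop("k <= 3 only")
  do.call(cbind, out)
}

# best achievable training accuracy of ANY line on a tiny 2-D point set,
# by brute force over all boundaries through point pairs plus axis sweeps
best_linear_accuracy_2d <- function(X, y01) {
  n <- nrow(X)
  best <- 0
  cand_w <- rbind(c(1, 0), c(0, 1))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- X[j, ] - X[i, ]
    if (sum(abs(d)) > 0) cand_w <- rbind(cand_w, c(-d[2], d[1]))
  }
  for (r in seq_len(nrow(cand_w))) {
    s <- as.numeric(X %*% cand_w[r, ])
    cuts <- c(min(s) - 1, (sort(unique(s))[-1] + sort(unique(s))[-length(unique(s))]) / 2,
              max(s) + 1)
    for (b in cuts) {
      acc <- max(mean((s > b) == y01), mean((s < b) == y01))
      best <- max(best, acc)
    }
  }
  best
}
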