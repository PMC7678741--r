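#' Configure a synthetic two-group LFQ cohort
#'
#' Describes a simulated cohort of cardioembolic-like (group C) and
#' atherothrombotic-like (group A) samples with log-normal protein
#' intensities, a configurable set of "planted" discriminative proteins, and
#' intensity-dependent missingness. The defaults emulate the structure of a
#' thrombectomy cohort: 32 C and 28 A samples, ~2,455 identified proteins of
#' which a few hundred are quantified in every sample, and three planted
#' proteins at a large standardized effect.
#'
#' Protein mean abundances are drawn from
#' `Normal(base_log2_mean, protein_log2_sd)`; within a protein, per-sample
#' log2 intensities are `Normal(mean_i, base_log2_sd)`. A planted protein
#' additionally shifts group C by `effect_size * base_log2_sd` on the log2
#' scale (so `effect_size` is Cohen's d against the within-group SD; the
#' shift sign is configurable per protein via `planted_sign`). Each cell is
#' independently set missing with probability
#' `plogis(qlogis(missing_rate) - missing_intensity_slope * z)` where `z` is
#' the cell's log2 intensity standardized by the overall intensity spread,
#' so low-abundance measurements are missing more often — the dominant
#' missingness mechanism in label-free proteomics.
#'
#' @param n_group_c,n_group_a sample counts per group (both >= 1).
#' @param n_proteins number of simulated proteins.
#' @param n_planted number of discriminative proteins (<= `n_proteins`).
#' @param effect_size standardized group-mean difference (Cohen's d) of
#'   planted proteins on the log2 scale.
#' @param base_log2_mean,base_log2_sd location of the log2 intensity
#'   distribution and within-protein (per-sample) SD.
#' @param protein_log2_sd between-protein spread of mean log2 abundance.
#' @param missing_rate missingness probability at the central log2
#'   intensity, in `[0, 1]` (0 = fully observed). With a positive slope the
#'   realized overall missing fraction is larger, because low-abundance
#'   cells dominate the missingness.
#' @param missing_intensity_slope strength (>= 0) of intensity-dependent
#'   missingness; 0 gives missingness completely at random. The defaults
#'   (rate 0.08, slope 5) are calibrated so that roughly 18% of simulated
#'   proteins are quantified in all 60 samples of the default cohort, the
#'   commonly-detected fraction seen in thrombectomy proteomes.
#' @param seed integer random seed; identical seeds give bit-identical
#'   cohorts.
#' @param clinical_spec list of covariate descriptors from [clin_binary()] /
#'   [clin_quant()]; see [default_clinical_spec()].
#' @param planted_sign optional vector of `+1`/`-1` per planted protein
#'   (direction of the group-C shift); default all `+1`.
#'
#' @return a `simulation_config` list, validated.
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_group_c = 32, n_group_a = 28,
                              n_proteins = 2455, n_planted = 3,
                              effect_size = 2.5,
                              base_log2_mean = 25, base_log2_sd = 1,
                              protein_log2_sd = 2,
                              missing_rate = 0.08,
                              missing_intensity_slope = 5,
                              seed = 1,
                              clinical_spec = default_clinical_spec(),
                              planted_sign = NULL) {
  cfg <- list(n_group_c = n_group_c, n_group_a = n_group_a,
              n_proteins = n_proteins, n_planted = n_planted,
              effect_size = effect_size,
              base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
              protein_log2_sd = protein_log2_sd,
              missing_rate = missing_rate,
              missing_intensity_slope = missing_intensity_slope,
              seed = seed, clinical_spec = clinical_spec,
              planted_sign = planted_sign)
  .validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

.check_count <- function(cfg, field, min = 1) {
  v <- cfg[[field]]
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min || v != floor(v))
    .thrombo_error("config", "invalid field '%s': must be an integer >= %d",
                   field, min)
}

.validate_config <- function(cfg) {
  for (f in c("n_group_c", "n_group_a", "n_proteins")) .check_count(cfg, f)
  .check_count(cfg, "n_planted", min = 0)
  .check_count(cfg, "seed", min = 0)
  if (cfg$n_planted > cfg$n_proteins)
    .thrombo_error("config", "invalid field 'n_planted': exceeds n_proteins")
  if (!is.finite(cfg$effect_size))
    .thrombo_error("config", "invalid field 'effect_size': must be finite")
  if (!is.numeric(cfg$missing_rate) || is.na(cfg$missing_rate) ||
      cfg$missing_rate < 0 || cfg$missing_rate > 1)
    .thrombo_error("config", "invalid field 'missing_rate': must be in [0, 1]")
  if (!is.numeric(cfg$missing_intensity_slope) ||
      cfg$missing_intensity_slope < 0)
    .thrombo_error("config", "invalid field 'missing_intensity_slope': must be >= 0")
  for (f in c("base_log2_sd", "protein_log2_sd"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      .thrombo_error("config", "invalid field '%s': must be > 0", f)
  if (!is.null(cfg$planted_sign)) {
    if (length(cfg$planted_sign) != cfg$n_planted ||
        !all(cfg$planted_sign %in% c(-1, 1)))
      .thrombo_error("config",
                     "invalid field 'planted_sign': need %d values in {-1, +1}",
                     cfg$n_planted)
  }
  for (cv in cfg$clinical_spec) .validate_covariate(cv)
  invisible(cfg)
}

.validate_covariate <- function(cv) {
  if (!is.list(cv) || is.null(cv$name) || is.null(cv$type))
    .thrombo_error("config", "clinical covariate descriptors need 'name' and 'type'")
  if (cv$type == "binary") {
    for (f in c("prev_c", "prev_a")) {
      v <- cv[[f]]
      if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
        .thrombo_error("config",
                       "invalid field '%s' of covariate '%s': prevalence must be in [0, 1]",
                       f, cv$name)
    }
  } else if (cv$type == "quantitative") {
    for (f in c("mean_c", "mean_a", "sd"))
      if (!is.numeric(cv[[f]]) || is.na(cv[[f]]))
        .thrombo_error("config", "invalid field '%s' of covariate '%s'", f, cv$name)
    if (cv$sd < 0)
      .thrombo_error("config", "invalid field 'sd' of covariate '%s': must be >= 0",
                     cv$name)
  } else {
    .thrombo_error("config", "unknown covariate type '%s'", cv$type)
  }
}

#' Clinical covariate descriptors for the simulator
#'
#' @param name covariate name.
#' @param prev_c,prev_a prevalence of the binary covariate in group C / A.
#' @return a covariate descriptor list.
#' @export
clin_binary <- function(name, prev_c, prev_a) {
  list(name = name, type = "binary", prev_c = prev_c, prev_a = prev_a)
}

#' @rdname clin_binary
#' @param mean_c,mean_a group means of the quantitative covariate.
#' @param sd common within-group SD.
#' @export
clin_quant <- function(name, mean_c, mean_a, sd) {
  list(name = name, type = "quantitative",
       mean_c = mean_c, mean_a = mean_a, sd = sd)
}

#' Default clinical covariates of the simulated cohort
#'
#' Prevalences and group means chosen to resemble a stroke-thrombectomy
#' cohort: atrial fibrillation and cardiac failure strongly associated with
#' the cardioembolic group, older cardioembolic patients, and largely
#' uninformative anthropometric and blood-count variables.
#'
#' @return list of covariate descriptors.
#' @export
default_clinical_spec <- function() {
  list(
    clin_binary("atrial_fibrillation", 0.625, 0.036),
    clin_binary("cardiac_failure", 0.188, 0.0),
    clin_binary("antithrombotic_medication", 0.625, 0.393),
    clin_binary("male_sex", 0.563, 0.714),
    clin_quant("age", 79.5, 67.5, 9),
    clin_quant("weight_kg", 71, 79, 14),
    clin_quant("bmi", 24.4, 26.0, 3.5),
    clin_quant("glycemia", 6.8, 6.8, 1.2),
    clin_quant("hemoglobin", 13.5, 13.8, 1.5),
    clin_quant("platelets", 203, 250, 55),
    clin_quant("white_cells", 8.9, 10.3, 2.8),
    clin_quant("thrombus_weight_mg", 31.2, 36.0, 25),
    clin_quant("protein_concentration", 11.2, 11.1, 4)
  )
}

#' Simulate a two-group LFQ cohort with known ground truth
#'
#' Generates a protein-by-sample LFQ matrix, a clinical covariate table and
#' the ground truth (planted proteins, per-protein effect, group
#' assignment) under the model described in [simulation_config()].
#'
#' Randomness is keyed entirely by `config$seed`: the planted-protein set is
#' drawn from a master stream, and each protein then uses its own
#' deterministic sub-stream, so a protein's simulated values do not depend
#' on how many other proteins are generated.
#'
#' @param config a [simulation_config()].
#' @return list with elements `lfq` (an [lfq_matrix], raw intensity scale,
#'   missing cells masked), `clinical` (data.frame, first column
#'   `sample_id`), and `truth` (list: `planted_protein_ids`,
#'   `per_protein_effect` — signed log2 shift of group C, named by planted
#'   protein — and `group_assignment`).
#' @export
simulate_cohort <- function(config) {
  .validate_config(config)
  cfg <- config
  n_samples <- cfg$n_group_c + cfg$n_group_a
  samp <- c(sprintf("C%02d", seq_len(cfg$n_group_c)),
            sprintf("A%02d", seq_len(cfg$n_group_a)))
  groups <- setNames(rep(c("C", "A"), c(cfg$n_group_c, cfg$n_group_a)), samp)
  prot <- sprintf("P%04d", seq_len(cfg$n_proteins))

  set.seed(cfg$seed)
  planted_idx <- if (cfg$n_planted > 0)
    sort(sample.int(cfg$n_proteins, cfg$n_planted)) else integer(0)
  sign <- if (is.null(cfg$planted_sign)) rep(1, cfg$n_planted) else cfg$planted_sign
  effect <- setNames(sign * cfg$effect_size * cfg$base_log2_sd,
                     prot[planted_idx])

  is_c <- groups == "C"
  total_sd <- sqrt(cfg$protein_log2_sd^2 + cfg$base_log2_sd^2)
  logit0 <- if (cfg$missing_rate <= 0) -Inf
            else if (cfg$missing_rate >= 1) Inf
            else qlogis(cfg$missing_rate)

  log2_int <- matrix(NA_real_, cfg$n_proteins, n_samples,
                     dimnames = list(prot, samp))
  mask <- matrix(TRUE, cfg$n_proteins, n_samples, dimnames = list(prot, samp))

  for (i in seq_len(cfg$n_proteins)) {
    set.seed(.sub_seed(cfg$seed, i))
    m_i <- rnorm(1, cfg$base_log2_mean, cfg$protein_log2_sd)
    x <- rnorm(n_samples, m_i, cfg$base_log2_sd)
    pos <- match(i, planted_idx)
    if (!is.na(pos)) x[is_c] <- x[is_c] + effect[[pos]]
    if (is.finite(logit0)) {
      z <- (x - cfg$base_log2_mean) / total_sd
      p_miss <- plogis(logit0 - cfg$missing_intensity_slope * z)
      mask[i, ] <- runif(n_samples) >= p_miss
    } else if (logit0 == Inf) {
      mask[i, ] <- FALSE
    }
    log2_int[i, ] <- x
  }

  intens <- 2^log2_int
  intens[!mask] <- NA_real_
  lfq <- lfq_matrix(intens, groups = groups, valid_mask = mask, log2 = FALSE)

  truth <- list(planted_protein_ids = prot[planted_idx],
                per_protein_effect = effect,
                group_assignment = groups)
  clinical <- simulate_clinical(cfg, truth)
  list(lfq = lfq, clinical = clinical, truth = truth)
}

#' Simulate clinical covariates for a cohort
#'
#' Draws the covariates described by `config$clinical_spec` for the samples
#' in `truth$group_assignment`: binary covariates as per-group Bernoulli
#' draws, quantitative covariates as per-group normals.
#'
#' @param config a [simulation_config()].
#' @param truth ground-truth list with `group_assignment` (named group
#'   vector), as produced by [simulate_cohort()].
#' @return data.frame with first column `sample_id` and one column per
#'   covariate (binary covariates as 0/1 integers).
#' @export
simulate_clinical <- function(config, truth) {
  .validate_config(config)
  ga <- truth$group_assignment
  if (is.null(names(ga)) || anyNA(ga))
    .thrombo_error("config", "group_assignment must cover all samples, named by sample")
  out <- data.frame(sample_id = names(ga), stringsAsFactors = FALSE)
  is_c <- as.character(ga) == "C"
  for (ci in seq_along(config$clinical_spec)) {
    cv <- config$clinical_spec[[ci]]
    set.seed(.sub_seed(config$seed + 500000, ci))
    if (cv$type == "binary") {
      p <- ifelse(is_c, cv$prev_c, cv$prev_a)
      out[[cv$name]] <- rbinom(length(ga), 1, p)
    } else {
      mu <- ifelse(is_c, cv$mean_c, cv$mean_a)
      out[[cv$name]] <- rnorm(length(ga), mu, cv$sd)
    }
  }
  out
}

#' Write a simulated cohort to disk in the formats the readers consume
#'
#' Writes the LFQ matrix as a tab-delimited MaxQuant-proteinGroups-style
#' table (missing cells written as 0), the sample annotation and clinical
#' tables as CSV, and the ground truth as JSON.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths written
#'   (`lfq`, `annotation`, `clinical`, `truth`).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(lfq = file.path(dir, "lfq.tsv"),
                annotation = file.path(dir, "annotation.csv"),
                clinical = file.path(dir, "clinical.csv"),
                truth = file.path(dir, "truth.json"))
  write_lfq_table(sim$lfq, paths$lfq)
  write_annotation(sim$lfq, paths$annotation)
  write.csv(sim$clinical, paths$clinical, row.names = FALSE)
  jsonlite::write_json(
    list(planted_protein_ids = sim$truth$planted_protein_ids,
         per_protein_effect = as.list(sim$truth$per_protein_effect),
         group_assignment = setNames(
           as.list(as.character(sim$truth$group_assignment)),
           names(sim$truth$group_assignment))),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
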