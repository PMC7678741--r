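test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_group_c = 0), "n_group_c")
  expect_error(simulation_config(n_planted = 10, n_proteins = 5), "n_planted")
  expect_error(simulation_config(missing_rate = 1.2), "missing_rate")
  expect_error(simulation_config(effect_size = Inf), "effect_size")
  expect_error(simulation_config(missing_intensity_slope = -1),
               "missing_intensity_slope")
  expect_error(
    simulation_config(clinical_spec = list(clin_binary("af", 1.5, 0.1))),
    "prevalence")
})

test_that("a no-missingness, no-effect cohort has the stated shape and empty truth", {
  cfg <- simulation_config(n_group_c = 2, n_group_a = 2, n_proteins = 5,
                           n_planted = 0, effect_size = 0, missing_rate = 0,
                           seed = 1, clinical_spec = list())
  sim <- simulate_cohort(cfg)
  expect_equal(dim(sim$lfq), c(5L, 4L))
  expect_true(all(sim$lfq$valid_mask))
  expect_length(sim$truth$planted_protein_ids, 0)
  expect_equal(as.character(sim$truth$group_assignment),
               c("C", "C", "A", "A"))
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- simulation_config(n_group_c = 5, n_group_a = 4, n_proteins = 50,
                           n_planted = 2, missing_rate = 0.2, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(simulation_config(n_group_c = 5, n_group_a = 4,
                                          n_proteins = 50, n_planted = 2,
                                          missing_rate = 0.2, seed = 100))
  expect_false(identical(s1$lfq$intensities, s3$lfq$intensities))
})

test_that("a protein's values do not depend on how many proteins are simulated", {
  base <- list(n_group_c = 4, n_group_a = 4, n_planted = 0, effect_size = 0,
               missing_rate = 0, seed = 5, clinical_spec = list())
  small <- simulate_cohort(do.call(simulation_config, c(base, n_proteins = 10)))
  large <- simulate_cohort(do.call(simulation_config, c(base, n_proteins = 40)))
  expect_identical(small$lfq$intensities[1:10, ],
                   large$lfq$intensities[1:10, ])
})

test_that("planted proteins shift group C by effect_size * base_log2_sd on log2 scale", {
  cfg <- simulation_config(n_group_c = 400, n_group_a = 400, n_proteins = 6,
                           n_planted = 3, effect_size = 2.5,
                           base_log2_sd = 1, missing_rate = 0, seed = 21,
                           clinical_spec = list())
  sim <- simulate_cohort(cfg)
  lg <- log2_transform(sim$lfq)
  in_c <- lg$groups == "C"
  diff <- rowMeans(lg$intensities[, in_c]) - rowMeans(lg$intensities[, !in_c])
  planted <- protein_ids(lg) %in% sim$truth$planted_protein_ids
  # SE of a mean difference at n=400/400, sd 1 is ~0.07
  expect_true(all(abs(diff[planted] - 2.5) < 0.3))
  expect_true(all(abs(diff[!planted]) < 0.3))
  expect_equal(unname(sim$truth$per_protein_effect),
               rep(2.5, 3))
})

test_that("with no planted effect, group-mean differences shrink within sampling error", {
  cfg <- simulation_config(n_group_c = 100, n_group_a = 100, n_proteins = 300,
                           n_planted = 0, effect_size = 0, missing_rate = 0,
                           seed = 31, clinical_spec = list())
  sim <- simulate_cohort(cfg)
  lg <- log2_transform(sim$lfq)
  in_c <- lg$groups == "C"
  diff <- rowMeans(lg$intensities[, in_c]) - rowMeans(lg$intensities[, !in_c])
  se <- cfg$base_log2_sd * sqrt(1 / 100 + 1 / 100)
  expect_gte(mean(abs(diff) < 4 * se), 0.99)
})

test_that("null Wilcoxon p-values are approximately uniform across proteins", {
  cfg <- simulation_config(n_group_c = 15, n_group_a = 15, n_proteins = 1000,
                           n_planted = 0, effect_size = 0, missing_rate = 0,
                           seed = 41, clinical_spec = list())
  sim <- simulate_cohort(cfg)
  lg <- log2_transform(sim$lfq)
  in_c <- lg$groups == "C"
  pvals <- apply(lg$intensities, 1, function(v)
    wilcoxon_rank_sum(v[in_c], v[!in_c])$p_value)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("missingness is intensity-dependent: lowest quartile misses most", {
  cfg <- simulation_config(n_group_c = 30, n_group_a = 30, n_proteins = 400,
                           n_planted = 0, effect_size = 0,
                           missing_rate = 0.3, missing_intensity_slope = 2,
                           seed = 51, clinical_spec = list())
  sim <- simulate_cohort(cfg)
  # underlying complete log2 intensities, reconstructed from the same seeds
  cfg0 <- cfg; cfg0$missing_rate <- 0
  full <- log2_transform(simulate_cohort(cfg0)$lfq)
  x <- as.numeric(full$intensities)
  miss <- as.numeric(!sim$lfq$valid_mask)
  qs <- stats::quantile(x, c(0.25, 0.75))
  expect_gt(mean(miss[x <= qs[1]]), mean(miss[x >= qs[2]]))
  # overall rate in the vicinity of the configured rate
  expect_lt(abs(mean(miss) - 0.3), 0.1)
})

test_that("binary clinical covariates reproduce their configured prevalences", {
  spec <- list(clin_binary("af", 1.0, 0.0))
  cfg <- simulation_config(n_group_c = 10, n_group_a = 8, n_proteins = 2,
                           n_planted = 0, missing_rate = 0, seed = 61,
                           clinical_spec = spec)
  sim <- simulate_cohort(cfg)
  ind <- as.numeric(sim$truth$group_assignment[sim$clinical$sample_id] == "C")
  expect_equal(sim$clinical$af, ind)

  # cohort-sized prevalences: mean counts over replicates match the binomial
  # expectations 32 * 0.625 = 20 and 28 * 0.036 ~ 1
  spec2 <- list(clin_binary("af", 0.625, 0.036))
  counts <- vapply(1:300, function(s) {
    cfg2 <- simulation_config(n_group_c = 32, n_group_a = 28, n_proteins = 2,
                              n_planted = 0, missing_rate = 0, seed = s,
                              clinical_spec = spec2)
    sim2 <- simulate_cohort(cfg2)
    g <- sim2$truth$group_assignment[sim2$clinical$sample_id]
    c(sum(sim2$clinical$af[g == "C"]), sum(sim2$clinical$af[g == "A"]))
  }, numeric(2))
  # SE of the mean count over 300 replicates is ~0.16 (C) and ~0.06 (A)
  expect_lt(abs(mean(counts[1, ]) - 32 * 0.625), 0.8)
  expect_lt(abs(mean(counts[2, ]) - 28 * 0.036), 0.3)
})

test_that("an empty clinical spec yields a table of sample IDs only", {
  cfg <- simulation_config(n_group_c = 3, n_group_a = 3, n_proteins = 2,
                           n_planted = 0, missing_rate = 0, seed = 1,
                           clinical_spec = list())
  sim <- simulate_cohort(cfg)
  expect_identical(names(sim$clinical), "sample_id")
  expect_equal(nrow(sim$clinical), 6)
})

test_that("written cohorts round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_group_c = 4, n_group_a = 4, n_proteins = 30,
                           n_planted = 1, missing_rate = 0.2, seed = 71)
  sim <- simulate_cohort(cfg)
  paths <- write_cohort(sim, dir)
  back <- read_lfq_table(paths$lfq, paths$annotation)
  expect_equal(back$valid_mask, sim$lfq$valid_mask)
  expect_equal(back$intensities, sim$lfq$intensities, tolerance = 1e-6)
  expect_identical(back$groups, sim$lfq$groups)
  clin <- read_clinical_table(paths$clinical, back)
  expect_identical(clin$sample_id, sample_ids(back))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_identical(truth$planted_protein_ids, sim$truth$planted_protein_ids)
})
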