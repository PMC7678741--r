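clin_fixture <- function(seed = 3) {
  cfg <- simulation_config(
    n_group_c = 12, n_group_a = 12, n_proteins = 20, n_planted = 2,
    effect_size = 2.5, missing_rate = 0, seed = seed,
    clinical_spec = list(clin_binary("af", 1.0, 0.0),
                         clin_binary("smoking", 0.4, 0.5),
                         clin_quant("age", 79, 68, 8),
                         clin_quant("glycemia", 6.8, 6.8, 1.2)))
  simulate_cohort(cfg)
}

test_that("binary covariates encode to 0/1 and quantitative ones pass through", {
  tab <- data.frame(sample_id = c("s1", "s2", "s3"),
                    af = c("yes", "no", "yes"),
                    age = c(70.5, 80.2, 65.0),
                    stringsAsFactors = FALSE)
  m <- encode_clinical(tab, c("af", "age"))
  expect_equal(unname(m[, "af"]), c(1, 0, 1))
  expect_equal(unname(m[, "age"]), tab$age)
})

test_that("samples with missing selected covariates are excluded and reported", {
  sim <- clin_fixture()
  tab <- sim$clinical
  tab$glycemia[5] <- NA
  expect_message(m <- encode_clinical(tab, c("af", "glycemia")), "excluded 1")
  expect_equal(nrow(m), 23)
  expect_identical(attr(m, "excluded_samples"), tab$sample_id[5])
  # variables without missing values keep every sample
  m2 <- encode_clinical(tab, "af")
  expect_equal(nrow(m2), 24)
})

test_that("unknown or empty variable selections raise config errors", {
  sim <- clin_fixture()
  expect_error(encode_clinical(sim$clinical, "no_such_var"),
               class = "thrombo_config_error")
  err <- tryCatch(encode_clinical(sim$clinical, "no_such_var"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "af")   # error lists the available variables
  expect_error(encode_clinical(sim$clinical, character()),
               class = "thrombo_config_error")
})

test_that("a covariate equal to the group label wins the clinical search at 100%", {
  sim <- clin_fixture()
  cs <- clinical_variable_search(sim$clinical, sim$lfq$groups, max_k = 2)
  expect_equal(cs$best_accuracy, 100)
  expect_true(all(vapply(cs$per_size[[1]]$top_subsets,
                         function(s) identical(s$variables, "af"),
                         logical(1))))
  # subset count: 4 singletons + 6 pairs
  expect_equal(cs$n_combinations_tested, 10)
})

test_that("excluding the informative covariate lowers the best accuracy", {
  sim <- clin_fixture()
  cs_all <- clinical_variable_search(sim$clinical, sim$lfq$groups, max_k = 2)
  cs_excl <- clinical_variable_search(sim$clinical, sim$lfq$groups, max_k = 2,
                                      exclusions = "af")
  expect_lt(cs_excl$best_accuracy, cs_all$best_accuracy)
  # excluded variables never appear in any reported subset
  vars_seen <- unlist(lapply(cs_excl$per_size, function(s)
    lapply(s$top_subsets, `[[`, "variables")))
  expect_false("af" %in% vars_seen)
})

test_that("subset counts follow the binomial sums", {
  tab <- data.frame(sample_id = sprintf("s%02d", 1:20))
  for (v in paste0("v", 1:12)) tab[[v]] <- rnorm(20)
  groups <- setNames(rep(c("A", "C"), 10), tab$sample_id)
  cs <- clinical_variable_search(tab, groups, max_k = 2)
  expect_equal(cs$n_combinations_tested, 12 + 66)
})

test_that("combined scoring degenerates exactly to the pure paths", {
  sim <- clin_fixture()
  common <- filter_common(sim$lfq)$matrix
  trio <- protein_ids(common)[1:3]

  # proteins only == subset-search scoring of that panel
  res_p <- combined_panel_accuracy(common, protein_ids = trio)
  lg <- log2_transform(common)
  direct <- resubstitution_accuracy(
    fit_svm(t(lg$intensities[trio, ]), lg$groups),
    t(lg$intensities[trio, ]), lg$groups)
  expect_equal(res_p$accuracy_percent, direct$accuracy_percent)

  # clinical only == clinical-search scoring of that subset
  res_c <- combined_panel_accuracy(common, sim$clinical,
                                   clinical_variables = c("age", "smoking"))
  m <- encode_clinical(sim$clinical, c("age", "smoking"))
  direct_c <- resubstitution_accuracy(
    fit_svm(m, sim$lfq$groups[rownames(m)]),
    m, sim$lfq$groups[rownames(m)])
  expect_equal(res_c$accuracy_percent, direct_c$accuracy_percent)
})

test_that("combining a strong trio with an informative covariate rarely hurts", {
  better <- 0
  for (seed in 1:10) {
    sim <- clin_fixture(seed = 800 + seed)
    common <- filter_common(sim$lfq)$matrix
    s <- search_panels(common, k = 2)
    trio <- s$top_panels[[1]]$protein_ids
    prot_only <- combined_panel_accuracy(common, protein_ids = trio)
    clin_only <- combined_panel_accuracy(common, sim$clinical,
                                         clinical_variables = "age")
    both <- combined_panel_accuracy(common, sim$clinical,
                                    protein_ids = trio,
                                    clinical_variables = "age")
    if (both$accuracy_percent >=
        max(prot_only$accuracy_percent, clin_only$accuracy_percent) - 1e-9)
      better <- better + 1
  }
  expect_gte(better, 8)
})

test_that("combined scoring validates its inputs", {
  sim <- clin_fixture()
  common <- filter_common(sim$lfq)$matrix
  expect_error(combined_panel_accuracy(common),
               class = "thrombo_config_error")
  expect_error(combined_panel_accuracy(common, protein_ids = "NOPE"),
               class = "thrombo_alignment_error")
  # unfiltered matrix with missing values among selected proteins
  cfg <- simulation_config(n_group_c = 6, n_group_a = 6, n_proteins = 10,
                           n_planted = 0, missing_rate = 0.5,
                           missing_intensity_slope = 0, seed = 9,
                           clinical_spec = list())
  holey <- simulate_cohort(cfg)$lfq
  with_na <- protein_ids(holey)[rowSums(!holey$valid_mask) > 0][1]
  expect_error(combined_panel_accuracy(holey, protein_ids = with_na),
               class = "thrombo_precondition_error")
})
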