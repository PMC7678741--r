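test_that("combination counting matches the closed form and the streamed loop", {
  expect_equal(count_combinations(3, 3), 1)
  expect_equal(count_combinations(5, 2), 10)
  expect_equal(count_combinations(30, 3), 4060)
  for (n in c(3, 10, 25, 50)) {
    for (k in 1:3) {
      expect_equal(stream_count_combinations(n, k), count_combinations(n, k))
    }
  }
  expect_error(count_combinations(3, 4), class = "thrombo_config_error")
  expect_error(enumerate_combinations(0, 1), class = "thrombo_config_error")
})

test_that("enumeration yields every strictly increasing tuple once, in lexicographic order", {
  for (nk in list(c(5, 2), c(7, 3), c(6, 1), c(3, 3))) {
    got <- enumerate_combinations(nk[1], nk[2])
    oracle <- combos_nested_loop(nk[1], nk[2])
    expect_identical(unname(got), unname(oracle))
  }
})

test_that("a perfect single-protein group indicator wins the k = 1 search at 100%", {
  set.seed(23)
  intens <- 2^matrix(rnorm(10 * 12, 25, 1), 10, 12)
  groups <- rep(c("C", "A"), each = 6)
  intens[4, ] <- 2^ifelse(groups == "C", 30, 20)
  x <- toy_lfq(intens, groups = groups)
  s <- search_panels(x, k = 1)
  expect_equal(s$best_accuracy, 100)
  expect_true(all(vapply(s$top_panels, function(p) "P04" %in% p$protein_ids,
                         logical(1))))
  expect_equal(s$n_combinations_tested, 10)
})

test_that("the trio search recovers planted proteins from a synthetic cohort", {
  cfg <- simulation_config(n_group_c = 20, n_group_a = 20, n_proteins = 30,
                           n_planted = 3, effect_size = 2.5, missing_rate = 0,
                           seed = 7, clinical_spec = list())
  sim <- simulate_cohort(cfg)
  s <- search_panels(filter_common(sim$lfq)$matrix, k = 3)
  expect_equal(s$n_combinations_tested, 4060)
  n_planted_in_top <- sum(s$top_panels[[1]]$protein_ids %in%
                            sim$truth$planted_protein_ids)
  expect_gte(n_planted_in_top, 2)
  # panel accuracies reported by the summary match an independent refit
  p1 <- s$top_panels[[1]]
  refit <- resubstitution_accuracy(
    fit_svm(t(log2_transform(sim$lfq)$intensities[p1$protein_ids, ]),
            sim$lfq$groups),
    t(log2_transform(sim$lfq)$intensities[p1$protein_ids, ]),
    sim$lfq$groups)
  expect_equal(p1$accuracy_percent, refit$accuracy_percent)
})

test_that("search results are invariant to protein row order", {
  cfg <- simulation_config(n_group_c = 8, n_group_a = 8, n_proteins = 15,
                           n_planted = 2, effect_size = 1.5, missing_rate = 0,
                           seed = 29, clinical_spec = list())
  x <- filter_common(simulate_cohort(cfg)$lfq)$matrix
  s1 <- search_panels(x, k = 2)
  perm <- c(8, 3, 15, 1, 12, 5, 9, 2, 14, 6, 11, 4, 13, 7, 10)
  s2 <- search_panels(x[perm, ], k = 2)
  expect_equal(s1$best_accuracy, s2$best_accuracy)
  expect_identical(lapply(s1$top_panels, `[[`, "protein_ids"),
                   lapply(s2$top_panels, `[[`, "protein_ids"))
  expect_identical(s1$core_proteins, s2$core_proteins)
})

test_that("chunked execution reproduces the serial search exactly", {
  cfg <- simulation_config(n_group_c = 10, n_group_a = 10, n_proteins = 25,
                           n_planted = 2, effect_size = 1, missing_rate = 0,
                           seed = 37, clinical_spec = list())
  x <- filter_common(simulate_cohort(cfg)$lfq)$matrix
  serial <- search_panels(x, k = 3)
  chunked <- search_panels(x, k = 3, chunk_size = 123)
  expect_equal(serial$n_combinations_tested, chunked$n_combinations_tested)
  expect_equal(serial$best_accuracy, chunked$best_accuracy)
  expect_identical(lapply(serial$top_panels, `[[`, "protein_ids"),
                   lapply(chunked$top_panels, `[[`, "protein_ids"))
})

test_that("an interrupted search resumes from its checkpoint", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_group_c = 8, n_group_a = 8, n_proteins = 20,
                           n_planted = 2, effect_size = 1.5, missing_rate = 0,
                           seed = 41, clinical_spec = list())
  x <- filter_common(simulate_cohort(cfg)$lfq)$matrix
  full <- search_panels(x, k = 3)
  ck <- file.path(dir, "ck.json")
  # simulate an interruption: run only the first chunks, then resume
  jsonlite::write_json(list(next_rank = 0, n_tested = 0, best_correct = -1,
                            panels = integer(0), panel_correct = integer(0)),
                       ck, auto_unbox = TRUE, digits = NA)
  partial <- search_panels(x, k = 3, chunk_size = 200, checkpoint = ck)
  expect_equal(partial$best_accuracy, full$best_accuracy)
  # checkpoint now records completion; re-running reuses it and reports the
  # same cumulative state
  resumed <- search_panels(x, k = 3, chunk_size = 200, checkpoint = ck)
  expect_equal(resumed$n_combinations_tested, full$n_combinations_tested)
  expect_identical(lapply(resumed$top_panels, `[[`, "protein_ids"),
                   lapply(full$top_panels, `[[`, "protein_ids"))
})

test_that("planted-protein recovery does not degrade as effect size grows", {
  hits <- vapply(c(0, 1, 2.5), function(d) {
    n_hit <- 0
    for (seed in 1:5) {
      cfg <- simulation_config(n_group_c = 10, n_group_a = 10,
                               n_proteins = 20, n_planted = 2,
                               effect_size = d, missing_rate = 0,
                               seed = 100 + seed, clinical_spec = list())
      sim <- simulate_cohort(cfg)
      s <- search_panels(filter_common(sim$lfq)$matrix, k = 2)
      if (any(s$top_panels[[1]]$protein_ids %in%
              sim$truth$planted_protein_ids))
        n_hit <- n_hit + 1
    }
    n_hit
  }, numeric(1))
  expect_true(hits[3] >= hits[1])
  expect_gte(hits[3], 4)
})

test_that("searching a matrix with missing cells is a precondition error", {
  intens <- matrix(1e6, 4, 6)
  intens[2, 3] <- 0
  x <- toy_lfq(intens, groups = rep(c("C", "A"), each = 3))
  expect_error(search_panels(x, k = 2), class = "thrombo_precondition_error")
})

test_that("core_protein_summary is the exact intersection of panel memberships", {
  panels <- list(c("X", "Y", "Z"), c("U", "V", "X"), c("P", "Q", "X"))
  expect_identical(core_protein_summary(panels), "X")
  expect_identical(core_protein_summary(list(c("A", "B"))), c("A", "B"))
  expect_identical(core_protein_summary(list(c("A", "B"), c("C", "D"))),
                   character(0))
  expect_error(core_protein_summary(list()),
               class = "thrombo_precondition_error")
})
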