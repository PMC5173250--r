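test_that("cohorts are bit-reproducible under a fixed seed", {
  a <- quick_cohort(n_samples = 50, n_targets = 5, n_decoy_genes = 5, seed = 3)
  b <- quick_cohort(n_samples = 50, n_targets = 5, n_decoy_genes = 5, seed = 3)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth$regulons, b$truth$regulons)
})

test_that("planted modulators are independent of the TF by construction", {
  rhos <- vapply(1:10, function(s) {
    sim <- quick_cohort(n_samples = 300, n_targets = 5, n_decoy_genes = 0,
                        gamma = 1, seed = s)
    abs(cor(sim$expr["M1", ], sim$expr["TF1", ], method = "spearman"))
  }, numeric(1))
  expect_gte(mean(rhos < 0.15), 0.9)
})

test_that("positive gamma strengthens coupling in the modulator-high tertile", {
  hits <- vapply(1:10, function(s) {
    sim <- quick_cohort(n_samples = 300, n_targets = 10, n_decoy_genes = 0,
                        gamma = 1, beta_range = c(0.5, 0.5),
                        prop_repressed = 0, seed = s)
    st <- stratify(sim$expr, "M1")
    hi <- cor(sim$expr["TF1", st$high], sim$expr["T1.001", st$high],
              method = "spearman")
    lo <- cor(sim$expr["TF1", st$low], sim$expr["T1.001", st$low],
              method = "spearman")
    hi > lo
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("negative gamma yields negative median dMI over planted targets", {
  hits <- vapply(1:10, function(s) {
    sim <- quick_cohort(n_samples = 300, n_targets = 20, n_decoy_genes = 0,
                        gamma = -1, seed = s)
    reg <- attach_regulons(sim$truth$regulon_sets, sim$expr)
    st <- stratify(sim$expr, "M1")
    rec <- conditional_profile(sim$expr, reg, st, n_perm = 100, n_boot = 20,
                               seed = s)
    median(rec$dmi) < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a null modulator leaves dMI small on average", {
  dbar <- vapply(1:20, function(s) {
    sim <- quick_cohort(n_samples = 300, n_targets = 10, n_decoy_genes = 0,
                        gamma = 0, seed = s)
    reg <- attach_regulons(sim$truth$regulon_sets, sim$expr)
    st <- stratify(sim$expr, "M1")
    x <- sim$expr["TF1", ]
    Y <- t(sim$expr[reg$target, , drop = FALSE])
    ids <- colnames(sim$expr)
    d <- mindyr:::dmi_for_strata(x, Y, match(st$high, ids), match(st$low, ids),
                                 "copula_gaussian")$dmi
    mean(abs(d))
  }, numeric(1))
  expect_lt(mean(dbar), 0.35)  # null dMI fluctuates but carries no signal
})

test_that("the in-modulator cohort wires M1 downstream of TF2", {
  sim <- simulate_in_modulator_cohort(sim_config(n_tfs = 2, n_targets = 10,
                                                 n_decoy_genes = 5, seed = 9))
  expect_true("M1" %in% sim$truth$regulon_sets$TF2)
  expect_identical(sim$truth$expected_calls$upstream_tf, "TF1")
  expect_identical(sim$truth$expected_calls$downstream_tf, "TF2")
  expect_gt(abs(cor(sim$expr["M1", ], sim$expr["TF2", ])), 0.3)
  expect_error(simulate_in_modulator_cohort(sim_config(n_tfs = 1)), "n_tfs")
})

test_that("saturated designs and invalid configs are rejected", {
  expect_error(sim_config(gamma = 2, beta_range = c(0.8, 0.9), noise_sd = 0.05),
               "saturated")
  expect_error(sim_config(n_samples = 10), "n_samples")
  expect_error(sim_config(gamma = 3), "gamma")
})

test_that("recovery scoring handles perfect, empty, and noisy calls", {
  sim <- quick_cohort(n_samples = 50, n_targets = 5, n_decoy_genes = 10,
                      gamma = 1, seed = 1)
  truth <- sim$truth
  perfect <- tibble::tibble(tf = "TF1", modulator = "M1", sign = "positive",
                            p_adj = 1e-6)
  s <- score_recovery(truth, perfect)
  expect_identical(c(s$sensitivity, s$specificity, s$sign_accuracy), c(1, 1, 1))

  none <- perfect[0, ]
  s0 <- score_recovery(truth, none)
  expect_identical(s0$sensitivity, 0)
  expect_identical(s0$specificity, 1)
  expect_true(is.na(s0$sign_accuracy))

  all_called <- tibble::tibble(tf = "TF1", modulator = truth$candidates,
                               sign = "negative", p_adj = 1e-6)
  sa <- score_recovery(truth, all_called)
  expect_identical(sa$specificity, 0)
  expect_identical(sa$sign_accuracy, 0)  # planted sign is positive
})
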