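test_that("tertile stratification follows the floor rule with deterministic ties", {
  m <- tiny_expr(2, 9)
  s <- stratify(m, "G1")
  expect_identical(length(s$high), 3L)
  expect_identical(length(s$low), 3L)
  expect_length(intersect(s$high, s$low), 0)
  expect_true(min(m["G1", s$high]) >= max(m["G1", s$low]))

  m10 <- tiny_expr(2, 10)
  s10 <- stratify(m10, "G1")
  expect_identical(length(s10$high), 3L)  # floor(10/3)

  # ties broken by sample id, so strata are reproducible
  mt <- tiny_expr(2, 12)
  mt["G1", ] <- rep(c(1, 2), 6)
  s1 <- stratify(mt, "G1")
  s2 <- stratify(mt, "G1")
  expect_identical(s1$high, s2$high)
  expect_identical(s1$low, sort(colnames(mt)[mt["G1", ] == 1])[1:4])

  mc <- tiny_expr(2, 9)
  mc["G2", ] <- 5
  expect_error(stratify(mc, "G2"), "constant modulator")
})

test_that("independence constraint excludes TF-correlated candidates", {
  set.seed(5)
  n <- 300
  tf <- rnorm(n)
  m <- matrix(rbind(tf, tf, -tf, rnorm(n)), nrow = 4,
              dimnames = list(c("TF", "COPY", "NEG", "NOISE"),
                              sprintf("S%03d", 1:n)))
  expect_false(independence_filter(m, "TF", "COPY")$pass)
  expect_identical(independence_filter(m, "TF", "COPY")$rho, 1)
  expect_false(independence_filter(m, "TF", "NEG")$pass)   # |rho| symmetric
  expect_true(independence_filter(m, "TF", "NOISE")$pass)
  expect_false(independence_filter(m, "TF", "TF")$pass)    # never own candidate
})

test_that("dMI follows the normalised-difference formula over a dense grid", {
  expect_equal(mindyr:::compute_dmi(0.6, 0.2), 0.5)
  expect_identical(mindyr:::compute_dmi(0.4, 0.4), 0)
  expect_identical(mindyr:::compute_dmi(0, 0), 0)
  g <- expand.grid(top = seq(0, 2, length.out = 100),
                   bottom = seq(0, 2, length.out = 100))
  d <- mindyr:::compute_dmi(g$top, g$bottom)
  pos <- g$top + g$bottom > 0
  expect_equal(d[pos], ((g$top - g$bottom) / (g$top + g$bottom))[pos])
  expect_true(all(d >= -1 & d <= 1))
  expect_identical(mindyr:::compute_dmi(g$bottom, g$top), -d)  # swap negates
})

test_that("planted modulation is detected and swapping strata flips everything", {
  sim <- quick_cohort(n_samples = 300, n_targets = 50, n_decoy_genes = 0,
                      gamma = 1, seed = 17)
  reg <- attach_regulons(sim$truth$regulon_sets, sim$expr)
  s <- stratify(sim$expr, "M1")
  rec <- conditional_profile(sim$expr, reg, s, n_perm = 500, seed = 17)
  expect_gte(mean(rec$modulated), 0.9)
  expect_identical(classify_sign(rec), "positive")
  expect_true(all(rec$dmi >= -1 & rec$dmi <= 1))
  expect_equal(rec$mi_shift, rec$mi_original * (1 + rec$dmi), tolerance = 1e-12)

  swapped <- s
  swapped$high <- s$low
  swapped$low <- s$high
  rec2 <- conditional_profile(sim$expr, reg, swapped, n_perm = 500, seed = 17)
  expect_equal(rec2$dmi, -rec$dmi, tolerance = 1e-12)
  expect_identical(classify_sign(rec2), "negative")
})

test_that("conditional profile works with the binned estimator too", {
  sim <- quick_cohort(n_samples = 120, n_targets = 12, n_decoy_genes = 0,
                      gamma = 1, seed = 2)
  reg <- attach_regulons(sim$truth$regulon_sets, sim$expr,
                         estimator = "binned_plugin")
  s <- stratify(sim$expr, "M1")
  rec <- conditional_profile(sim$expr, reg, s, n_perm = 100, n_boot = 20,
                             seed = 2, estimator = "binned_plugin")
  expect_identical(nrow(rec), 12L)
  expect_true(all(rec$mi_top >= 0 & rec$mi_bottom >= 0))
})

test_that("FET matches the exact hypergeometric tail on a fixed 2x2", {
  # regulon of 50 edges with 8 modulated; universe adds 950 edges with 10
  reg_rec <- make_records(50, modulated_idx = 1:8)
  rest <- make_records(950, modulated_idx = 1:10, tf = "TF2")
  univ <- rbind(reg_rec, rest)
  out <- regulon_tests(reg_rec, universe = univ)
  # exact one-sided tail, enumerated independently: sum over >= 8 of
  # dhyper(j, 50, 950, 18)
  expect_equal(out$fet_p, sum(dhyper(8:18, 50, 950, 18)), tolerance = 1e-10)
  expect_equal(out$fet_p, 6.633408e-07, tolerance = 1e-4)
  expect_identical(out$n_modulated, 8L)
})

test_that("KS rewards modulation of the strongest interactions only", {
  top <- make_records(40, modulated_idx = 1:10)     # strongest-MI targets
  bottom <- make_records(40, modulated_idx = 31:40) # weakest-MI targets
  expect_lt(regulon_tests(top)$ks_p, 0.01)
  expect_gt(regulon_tests(bottom)$ks_p, 0.5)
})

test_that("zero modulated targets short-circuit to unit p-values", {
  none <- make_records(20, modulated_idx = integer())
  out <- regulon_tests(none)
  expect_identical(out, tibble::tibble(fet_p = 1, ks_p = 1, n_modulated = 0L))
})

test_that("single-TF runs fall back to the exact binomial test", {
  rec <- make_records(50, modulated_idx = 1:8)
  out <- regulon_tests(rec, universe = rec, alpha_target = 0.01)
  expect_equal(out$fet_p,
               binom.test(8, 50, 0.01, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("sign classification is the sign of the median dMI", {
  r <- function(d) {
    n <- length(d)
    rec <- make_records(n, modulated_idx = seq_len(n))
    rec$dmi <- d
    rec
  }
  expect_identical(classify_sign(r(c(0.4, 0.3, 0.5))), "positive")
  expect_identical(classify_sign(r(c(-0.4, -0.2))), "negative")
  expect_identical(classify_sign(r(c(-0.3, 0.3))), "unclassified")
  expect_identical(classify_sign(make_records(5, integer())), "unclassified")
})

test_that("BH adjustment is per TF on the FET p-values", {
  s <- tibble::tibble(
    tf = "TF1", modulator = paste0("M", 1:4),
    fet_p = c(0.0001, 0.001, 0.01, 0.05), ks_p = 1,
    excluded_by_independence = FALSE
  )
  out <- adjust_modulators(s, alpha_adj = 0.01)
  full <- mindyr:::add_p_adj(s)
  expect_equal(full$p_adj, c(0.0004, 0.002, 0.0133333, 0.05), tolerance = 1e-5)
  expect_identical(out$modulator, c("M1", "M2"))

  one <- adjust_modulators(s[1, ], alpha_adj = 0.01)
  expect_identical(one$p_adj, one$fet_p)

  s$fet_p <- 1
  expect_identical(nrow(adjust_modulators(s, 0.001)), 0L)
})

test_that("consensus keeps same-sign pairs significant in both cohorts", {
  a <- tibble::tibble(tf = "TF1", modulator = c("M1", "M2", "M3"),
                      sign = c("positive", "positive", "positive"),
                      p_adj = 1e-4)
  b <- tibble::tibble(tf = "TF1", modulator = c("M1", "M2"),
                      sign = c("positive", "negative"), p_adj = 1e-4)
  out <- consensus(a, b)
  expect_identical(out$modulator, "M1")  # M2 sign conflict, M3 only in A
})

test_that("in-modulator calls enumerate cross-TF wiring only", {
  reg <- tibble::tibble(tf = c("TF1", "TF2", "TF3"),
                        target = c("M1", "M1", "M1"))
  sig <- tibble::tibble(tf = "TF1", modulator = "M1", sign = "positive",
                        p_adj = 1e-5)
  out <- find_in_modulators(reg, sig)
  # modulator of TF1, target of TF2 and TF3 -> two calls; self-loop dropped
  expect_identical(nrow(out), 2L)
  expect_identical(out$downstream_tf, c("TF2", "TF3"))
  expect_true(all(out$upstream_tf == "TF1"))

  own <- find_in_modulators(reg[1, ], sig)
  expect_identical(nrow(own), 0L)
})
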