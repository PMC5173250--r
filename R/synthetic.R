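# Synthetic cohorts with planted, modulator-dependent TF-target couplings
# and ground truth, so every pipeline stage is testable without external
# data.

#' Simulation configuration
#'
#' Parameters of the generative model used by [simulate_cohort()] and
#' [simulate_in_modulator_cohort()]. Defaults describe the standard
#' validation cohort: 300 samples, one TF with 50 targets, 200 decoy
#' genes, base couplings drawn from \[0.3, 0.8\] with 20% repressed
#' (negative) targets, unit residual noise.
#'
#' @param n_samples Cohort size (>= 30).
#' @param n_targets Targets per TF.
#' @param n_decoy_genes Independent-noise decoy genes.
#' @param n_tfs Number of TFs.
#' @param gamma Modulator effect size; 0 plants a null modulator;
#'   `|gamma| <= 2`. Positive gamma strengthens TF-target coupling at high
#'   modulator expression.
#' @param beta_range Interval for base coupling magnitudes.
#' @param prop_repressed Fraction of targets with negative coupling.
#' @param noise_sd Residual standard deviation (> 0).
#' @param seed Integer seed; the cohort is bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_targets = 50L,
                       n_decoy_genes = 200L, n_tfs = 1L, gamma = 1,
                       beta_range = c(0.3, 0.8), prop_repressed = 0.2,
                       noise_sd = 1, seed = 1L) {
  stopifnot(n_samples >= 30, n_targets >= 1, n_decoy_genes >= 0,
            n_tfs >= 1, abs(gamma) <= 2, noise_sd > 0,
            length(beta_range) == 2, all(beta_range > 0),
            beta_range[1] <= beta_range[2],
            prop_repressed >= 0, prop_repressed <= 1)
  c_max <- beta_range[2] * (1 + abs(gamma))
  if (c_max / sqrt(c_max^2 + noise_sd^2) > 0.99) {
    stop("saturated design: effective coupling too close to 1", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_targets = as.integer(n_targets),
                 n_decoy_genes = as.integer(n_decoy_genes),
                 n_tfs = as.integer(n_tfs), gamma = gamma,
                 beta_range = beta_range, prop_repressed = prop_repressed,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# Within-cohort rank of M scaled to [-1, 1]; bounds the effective coupling
# and keeps the design noise-stable regardless of M's marginal scale.
rank_scaled <- function(m) {
  n <- length(m)
  2 * (rank(m, ties.method = "average") - 1) / (n - 1) - 1
}

#' Simulate a cohort with a planted modulator
#'
#' Generative model: each TF is standard normal across samples; the
#' candidate modulator `M1` is standard normal and independent of every TF
#' (so it satisfies the independence constraint by construction); each
#' target of TF1 is
#' \deqn{t_i = \beta_i (1 + \gamma \, s(M)) \, TF_1 + \varepsilon,}
#' where \eqn{s(M)} is the within-cohort rank of M scaled to \[-1, 1\] and
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. The interaction is multiplicative
#' on the coupling coefficient, not the mean, so the modulator alters
#' TF-target MI without shifting target mean expression — exactly the
#' phenomenon the conditional analysis detects. Additional TFs (if any)
#' get unmodulated targets; decoys are independent noise. With
#' `gamma = 0`, `M1` is a pure null candidate and the truth records no
#' planted modulator.
#'
#' Gene ids are systematic: `TF1..`, `M1`, targets `T<k>.001..`, decoys
#' `D001..`; samples `S001..`.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (genes x samples matrix) and `truth` (list:
#'   `regulons` tibble with planted beta/mode per target, `regulon_sets`
#'   GMT-style list, `modulators` tibble of planted (tf, modulator, gamma),
#'   `candidates` = M1 plus all decoy ids, `expected_calls` empty).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config, in_modulator = FALSE))
}

#' Simulate a two-TF cohort with a planted in-modulator
#'
#' As [simulate_cohort()], but the modulator `M1` is itself generated as a
#' noisy transcriptional target of TF2 (so it belongs in regulon(TF2))
#' while conditioning TF1's target couplings through \eqn{\gamma}. The
#' truth records the expected in-modulator call (M1; upstream TF1;
#' downstream TF2).
#'
#' @param config A [sim_config()] with `n_tfs >= 2`.
#' @return As [simulate_cohort()]; `truth$expected_calls` holds the
#'   planted call (empty when `gamma = 0`).
#' @export
simulate_in_modulator_cohort <- function(config = sim_config(n_tfs = 2L)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tfs < 2L) stop("in-modulator cohort needs n_tfs >= 2", call. = FALSE)
  with_seed(config$seed, simulate_cohort_impl(config, in_modulator = TRUE))
}

simulate_cohort_impl <- function(config, in_modulator) {
  n <- config$n_samples
  k <- config$n_tfs
  tf_ids <- paste0("TF", seq_len(k))
  sample_ids <- sprintf("S%03d", seq_len(n))
  TFs <- matrix(rnorm(k * n), nrow = k, dimnames = list(tf_ids, sample_ids))

  if (in_modulator) {
    # M1 is a noisy target of TF2 and modulates TF1
    m <- 0.7 * TFs["TF2", ] + rnorm(n, sd = config$noise_sd)
  } else {
    m <- rnorm(n)
  }
  s <- rank_scaled(m)

  beta_mag <- runif(config$n_targets * k, config$beta_range[1], config$beta_range[2])
  repress <- runif(config$n_targets * k) < config$prop_repressed
  beta <- ifelse(repress, -beta_mag, beta_mag)

  rows <- list(TFs, matrix(m, nrow = 1, dimnames = list("M1", sample_ids)))
  reg_rows <- list()
  idx <- 0L
  for (tf in tf_ids) {
    t_ids <- sprintf("T%d.%03d", match(tf, tf_ids), seq_len(config$n_targets))
    b <- beta[idx + seq_len(config$n_targets)]
    idx <- idx + config$n_targets
    # only TF1's couplings are conditioned on the modulator
    g <- if (tf == "TF1") config$gamma else 0
    coupling <- outer(b, 1 + g * s)  # targets x samples
    tg <- coupling * matrix(TFs[tf, ], nrow = config$n_targets,
                            ncol = n, byrow = TRUE) +
      matrix(rnorm(config$n_targets * n, sd = config$noise_sd),
             nrow = config$n_targets)
    dimnames(tg) <- list(t_ids, sample_ids)
    rows <- c(rows, list(tg))
    reg_rows[[tf]] <- tibble::tibble(tf = tf, target = t_ids, beta = b,
                                     mode = ifelse(b < 0, -1L, 1L))
  }
  if (config$n_decoy_genes > 0) {
    d_ids <- sprintf("D%03d", seq_len(config$n_decoy_genes))
    decoys <- matrix(rnorm(config$n_decoy_genes * n),
                     nrow = config$n_decoy_genes,
                     dimnames = list(d_ids, sample_ids))
    rows <- c(rows, list(decoys))
  } else {
    d_ids <- character()
  }
  expr <- do.call(rbind, rows)

  regulons <- dplyr::bind_rows(reg_rows)
  regulon_sets <- split(regulons$target, regulons$tf)
  if (in_modulator) {
    # M1 belongs in regulon(TF2)
    regulon_sets[["TF2"]] <- c(regulon_sets[["TF2"]], "M1")
    regulons <- dplyr::bind_rows(
      regulons, tibble::tibble(tf = "TF2", target = "M1", beta = 0.7, mode = 1L))
  }
  modulators <- if (config$gamma != 0) {
    tibble::tibble(tf = "TF1", modulator = "M1", gamma = config$gamma,
                   sign = ifelse(config$gamma > 0, "positive", "negative"))
  } else {
    tibble::tibble(tf = character(), modulator = character(),
                   gamma = numeric(), sign = character())
  }
  expected_calls <- if (in_modulator && config$gamma != 0) {
    tibble::tibble(modulator = "M1", upstream_tf = "TF1", downstream_tf = "TF2")
  } else {
    tibble::tibble(modulator = character(), upstream_tf = character(),
                   downstream_tf = character())
  }
  list(expr = expr,
       truth = list(regulons = regulons, regulon_sets = regulon_sets,
                    modulators = modulators,
                    candidates = c("M1", d_ids),
                    expected_calls = expected_calls,
                    config = config))
}

#' Score modulator recovery against planted truth
#'
#' Confusion-matrix fractions over the candidate modulators of a synthetic
#' cohort: sensitivity (planted (tf, modulator) pairs recovered as
#' significant), specificity (non-planted candidates not called), and sign
#' accuracy (fraction of recovered planted pairs with the planted sign).
#'
#' @param truth The `truth` element of a simulated cohort.
#' @param significant Significant modulator summaries (from [run_mindy()]
#'   or [adjust_modulators()]).
#' @param candidates Candidate universe; defaults to `truth$candidates`.
#' @return One-row tibble: `sensitivity`, `specificity`, `sign_accuracy`
#'   (NA when undefined), plus `tp`, `fp`, `fn`, `tn` counts.
#' @export
score_recovery <- function(truth, significant, candidates = NULL) {
  candidates <- candidates %||% truth$candidates
  planted <- paste(truth$modulators$tf, truth$modulators$modulator)
  called <- if (nrow(significant) > 0) {
    paste(significant$tf, significant$modulator)
  } else character()
  called <- called[significant$modulator %in% candidates]
  tp_pairs <- intersect(called, planted)
  tp <- length(tp_pairs)
  fn <- length(setdiff(planted, called))
  fp <- length(setdiff(called, planted))
  neg <- setdiff(candidates, truth$modulators$modulator)
  tn <- length(setdiff(neg, significant$modulator))
  sign_acc <- if (tp > 0) {
    truth_sign <- setNames(truth$modulators$sign,
                           paste(truth$modulators$tf, truth$modulators$modulator))
    got <- significant$sign[match(tp_pairs, paste(significant$tf, significant$modulator))]
    mean(got == truth_sign[tp_pairs])
  } else NA_real_
  tibble::tibble(
    sensitivity = if (length(planted) > 0) tp / length(planted) else NA_real_,
    specificity = if (length(neg) > 0) tn / length(neg) else NA_real_,
    sign_accuracy = sign_acc,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
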