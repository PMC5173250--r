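# Full pipeline: regulons -> independence filter -> stratification ->
# conditional profiles -> regulon tests -> sign -> BH adjustment ->
# in-modulators. Deterministic under a fixed master seed: child seeds are
# derived per (TF, modulator) pair, so results do not depend on the order
# in which candidates are processed.

#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_mindy()] with their defaults:
#' 1000 stratum-label permutations per (TF, modulator); per-target level
#' `alpha_target = 0.01` with bootstrap stability >= 0.5 over `n_boot =
#' 100` resamples; regulon inference at BH-adjusted `alpha_regulon = 0.01`
#' with at least `min_regulon = 10` targets to proceed; tertile strata
#' (`fraction = 1/3`); independence constraint |Spearman rho| <
#' `rho_max = 0.3`; modulator reporting cut-off `alpha_adj = 0.001`
#' (BH-adjusted per TF).
#'
#' @param n_perm Stratum-label permutations per (TF, modulator).
#' @param n_boot Bootstrap resamples per (TF, modulator).
#' @param alpha_target Per-target significance level on |dMI|.
#' @param stability_min Minimum bootstrap stability for a modulated call.
#' @param alpha_adj BH-adjusted cut-off for significant modulators.
#' @param alpha_regulon BH-adjusted level for regulon inference.
#' @param min_regulon Minimum regulon size to enter conditional analysis.
#' @param fraction Stratum fraction (tertiles by default).
#' @param rho_max Independence-constraint threshold.
#' @param estimator MI estimator label.
#' @param seed Master seed for all randomness.
#' @return A list of class `mindy_config`.
#' @export
mindy_config <- function(n_perm = 1000L, n_boot = 100L, alpha_target = 0.01,
                         stability_min = 0.5, alpha_adj = 0.001,
                         alpha_regulon = 0.01, min_regulon = 10L,
                         fraction = 1 / 3, rho_max = 0.3,
                         estimator = c("copula_gaussian", "binned_plugin"),
                         seed = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(n_perm >= 100, n_boot >= 20,
            alpha_target > 0, alpha_target < 1,
            alpha_adj > 0, alpha_adj < 1,
            alpha_regulon > 0, alpha_regulon < 1,
            stability_min >= 0, stability_min <= 1,
            fraction > 0, fraction <= 0.5,
            rho_max > 0, min_regulon >= 2)
  structure(list(n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 alpha_target = alpha_target, stability_min = stability_min,
                 alpha_adj = alpha_adj, alpha_regulon = alpha_regulon,
                 min_regulon = as.integer(min_regulon), fraction = fraction,
                 rho_max = rho_max, estimator = estimator,
                 seed = as.integer(seed)),
            class = "mindy_config")
}

#' Run the full modulator-inference pipeline
#'
#' For each TF: obtain its regulon (supplied via `regulons`, or inferred
#' with [infer_regulon()]); for each candidate modulator that passes the
#' independence constraint: stratify the cohort into modulator-high and
#' modulator-low tertiles and compute the conditional MI profile of the
#' regulon ([conditional_profile()]). Each (TF, modulator) pair is then
#' tested at the regulon level ([regulon_tests()]) against the universe of
#' all records for that modulator, classified as positive or negative
#' ([classify_sign()]), and BH-adjusted per TF; significant pairs
#' (`p_adj < alpha_adj`) feed the in-modulator enumeration
#' ([find_in_modulators()]).
#'
#' Candidates default to every gene in the matrix. A TF is never its own
#' candidate; candidates that are targets of the TF they modulate are
#' allowed (required for in-modulator semantics). Excluded candidates
#' appear in the summaries with `excluded_by_independence = TRUE` and no
#' p-values.
#'
#' @param expr Numeric expression matrix, genes in rows.
#' @param tfs Character vector of TF gene ids.
#' @param candidates Candidate modulator ids; default all genes.
#' @param regulons Optional pre-computed regulons: a regulon tibble or a
#'   named list of gene sets (GMT-style, attached with
#'   [attach_regulons()]). If `NULL`, regulons are inferred.
#' @param config A [mindy_config()].
#' @return An object of class `mindy_fit`: list with `records`
#'   (conditional records), `summaries` (per TF x candidate),
#'   `significant` (the `p_adj < alpha_adj` subset), `in_modulators`,
#'   `regulons`, and `config`.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_config(n_samples = 120, n_targets = 15,
#'                                   n_decoy_genes = 10, gamma = 1, seed = 7))
#' fit <- run_mindy(sim$expr, tfs = "TF1", candidates = c("M1", "D001"),
#'                  regulons = sim$truth$regulon_sets,
#'                  config = mindy_config(n_perm = 200, seed = 7))
#' tidy(fit)
#' }
#' @export
run_mindy <- function(expr, tfs, candidates = NULL, regulons = NULL,
                      config = mindy_config()) {
  stopifnot(inherits(config, "mindy_config"))
  validate_expression_matrix(expr)
  missing_tfs <- setdiff(tfs, rownames(expr))
  if (length(missing_tfs) > 0) {
    stop("TF(s) not in matrix: ", paste(missing_tfs, collapse = ", "),
         call. = FALSE)
  }
  candidates <- candidates %||% rownames(expr)
  candidates <- intersect(candidates, rownames(expr))

  reg <- resolve_regulons(expr, tfs, regulons, config)
  sizes <- dplyr::count(reg, .data$tf)
  keep_tfs <- sizes$tf[sizes$n >= config$min_regulon]
  skipped <- setdiff(tfs, keep_tfs)
  if (length(skipped) > 0) {
    mindy_log("skipping TF(s) with regulon < ", config$min_regulon, ": ",
              paste(skipped, collapse = ", "))
  }
  if (length(keep_tfs) == 0L) {
    stop("no TF has a regulon of at least ", config$min_regulon,
         " targets (skipped: ", paste(skipped, collapse = ", "), ")",
         call. = FALSE)
  }
  reg <- dplyr::filter(reg, .data$tf %in% keep_tfs)

  # strata depend only on the candidate, so compute them once each
  strata_cache <- list()
  get_strata <- function(m) {
    if (is.null(strata_cache[[m]])) {
      strata_cache[[m]] <<- stratify(expr, m, config$fraction)
    }
    strata_cache[[m]]
  }

  grid <- tidyr::expand_grid(tf = keep_tfs, modulator = candidates) |>
    dplyr::filter(.data$tf != .data$modulator)

  per_pair <- purrr::pmap(grid, function(tf, modulator) {
    ind <- independence_filter(expr, tf, modulator, config$rho_max)
    base <- tibble::tibble(tf = tf, modulator = modulator,
                           independence_rho = ind$rho,
                           excluded_by_independence = !ind$pass)
    if (!ind$pass || sd(expr[modulator, ]) == 0) {
      base$excluded_by_independence <- TRUE
      return(list(records = NULL, summary = base))
    }
    rec <- conditional_profile(
      expr, dplyr::filter(reg, .data$tf == !!tf), get_strata(modulator),
      n_perm = config$n_perm, n_boot = config$n_boot,
      alpha_target = config$alpha_target,
      stability_min = config$stability_min,
      seed = config$seed, estimator = config$estimator
    )
    list(records = rec, summary = base)
  })

  records <- dplyr::bind_rows(purrr::map(per_pair, "records"))
  base_sum <- dplyr::bind_rows(purrr::map(per_pair, "summary"))

  summaries <- base_sum |>
    dplyr::left_join(dplyr::count(reg, .data$tf, name = "n_targets"), by = "tf")
  if (nrow(records) > 0) {
    tested <- records |>
      dplyr::group_by(.data$modulator) |>
      dplyr::group_modify(function(univ, key) {
        univ |>
          dplyr::group_by(.data$tf) |>
          dplyr::group_modify(function(recs, key2) {
            recs$tf <- key2$tf
            stats <- regulon_tests(recs, universe = dplyr::mutate(univ, modulator = key$modulator),
                                   alpha_target = config$alpha_target)
            stats$sign <- classify_sign(recs)
            stats
          }) |>
          dplyr::ungroup()
      }) |>
      dplyr::ungroup()
    summaries <- dplyr::left_join(summaries, tested, by = c("tf", "modulator"))
  } else {
    summaries <- dplyr::mutate(summaries, fet_p = NA_real_, ks_p = NA_real_,
                               n_modulated = NA_integer_,
                               sign = NA_character_)
  }
  summaries <- add_p_adj(summaries) |>
    dplyr::arrange(.data$tf, .data$modulator)

  significant <- dplyr::filter(summaries, !is.na(.data$p_adj),
                               .data$p_adj < config$alpha_adj)
  calls <- find_in_modulators(reg, significant)

  structure(list(records = records, summaries = summaries,
                 significant = significant, in_modulators = calls,
                 regulons = reg, config = config),
            class = "mindy_fit")
}

resolve_regulons <- function(expr, tfs, regulons, config) {
  if (is.null(regulons)) {
    return(purrr::map_dfr(tfs, function(tf) {
      infer_regulon(expr, tf, n_perm = config$n_perm,
                    alpha = config$alpha_regulon, seed = config$seed,
                    estimator = config$estimator)
    }))
  }
  if (is.data.frame(regulons)) {
    stopifnot(all(c("tf", "target", "mi") %in% names(regulons)))
    return(dplyr::filter(tibble::as_tibble(regulons), .data$tf %in% tfs))
  }
  if (is.list(regulons)) {
    return(attach_regulons(regulons[intersect(names(regulons), tfs)], expr,
                           estimator = config$estimator))
  }
  stop("regulons must be NULL, a regulon tibble, or a named list of sets",
       call. = FALSE)
}

#' @export
print.mindy_fit <- function(x, ...) {
  g <- glance(x)
  cat("mindy fit:", g$n_tfs, "TF(s),", g$n_candidates, "candidate(s),",
      g$n_significant, "significant modulator(s),",
      g$n_in_modulators, "in-modulator call(s)\n")
  invisible(x)
}

#' Tidy a mindy fit into the per-candidate summary table
#'
#' @param x A `mindy_fit`.
#' @param ... Unused.
#' @return Tibble of modulator summaries (one row per TF x candidate).
#' @export
tidy.mindy_fit <- function(x, ...) x$summaries

#' One-row overview of a mindy fit
#'
#' @param x A `mindy_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_tfs`, `n_candidates`, `n_excluded`,
#'   `n_records`, `n_significant`, `n_in_modulators`.
#' @export
glance.mindy_fit <- function(x, ...) {
  tibble::tibble(
    n_tfs = dplyr::n_distinct(x$regulons$tf),
    n_candidates = dplyr::n_distinct(x$summaries$modulator),
    n_excluded = sum(x$summaries$excluded_by_independence),
    n_records = nrow(x$records),
    n_significant = nrow(x$significant),
    n_in_modulators = nrow(x$in_modulators)
  )
}

#' Write the result tables of a fit to a directory
#'
#' Writes `conditional_records.tsv`, `modulator_summaries.tsv`,
#' `in_modulators.tsv`, and `run_config.json` (full provenance) under
#' `dir`.
#'
#' @param fit A `mindy_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mindy_results <- function(fit, dir) {
  stopifnot(inherits(fit, "mindy_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results_table(fit$records, file.path(dir, "conditional_records.tsv"))
  write_results_table(fit$summaries, file.path(dir, "modulator_summaries.tsv"))
  write_results_table(fit$in_modulators, file.path(dir, "in_modulators.tsv"))
  jsonlite::write_json(unclass(fit$config),
                       file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
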