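# The MINDy core: tertile stratification by modulator expression,
# differential MI per target with permutation significance and bootstrap
# stability, regulon-level FET/KS tests, sign classification, consensus,
# and in-modulator enumeration.

#' Stratify samples by a modulator's expression
#'
#' Ranks samples by the modulator's expression and returns the top and
#' bottom `floor(n * fraction)` samples (default tertiles). Ties in
#' expression are broken by sample id (lexicographic), so strata are fully
#' deterministic. The middle samples are unused.
#'
#' @param expr Numeric expression matrix, genes in rows.
#' @param modulator Gene id present in `expr`; must be non-constant.
#' @param fraction Stratum fraction in (0, 0.5]; default 1/3.
#' @return An object of class `mindy_strata`: list with `modulator`,
#'   `high` and `low` (sample-id character vectors), `fraction`.
#' @export
stratify <- function(expr, modulator, fraction = 1 / 3) {
  stopifnot(fraction > 0, fraction <= 0.5)
  if (!modulator %in% rownames(expr)) {
    stop("modulator not in matrix: ", modulator, call. = FALSE)
  }
  v <- expr[modulator, ]
  if (sd(v) == 0) stop("constant modulator: ", modulator, call. = FALSE)
  n <- length(v)
  k <- floor(n * fraction)
  if (k < 3L) stop("stratum size ", k, " < 3; too few samples", call. = FALSE)
  ids <- colnames(expr)
  ord <- order(v, ids)  # ascending; ties by sample id
  structure(
    list(modulator = modulator,
         high = ids[ord[(n - k + 1):n]],
         low  = ids[ord[1:k]],
         fraction = fraction),
    class = "mindy_strata"
  )
}

#' @export
print.mindy_strata <- function(x, ...) {
  cat("mindy strata for", x$modulator, "-", length(x$high), "high /",
      length(x$low), "low samples (fraction", signif(x$fraction, 3), ")\n")
  invisible(x)
}

#' Modulator independence constraint
#'
#' Candidates whose own expression correlates with the TF's confound the
#' conditioning, so they are excluded before any conditional analysis. The
#' constraint is |Spearman rho| < `rho_max` (default 0.3). A candidate
#' identical to the TF is always excluded.
#'
#' @param expr Numeric expression matrix.
#' @param tf,modulator Gene ids present in `expr`.
#' @param rho_max Exclusion threshold on |rho|.
#' @return One-row tibble: `pass` (logical), `rho`.
#' @export
independence_filter <- function(expr, tf, modulator, rho_max = 0.3) {
  for (g in c(tf, modulator)) {
    if (!g %in% rownames(expr)) stop("gene not in matrix: ", g, call. = FALSE)
  }
  if (identical(tf, modulator)) {
    return(tibble::tibble(pass = FALSE, rho = 1))
  }
  rho <- suppressWarnings(cor(expr[tf, ], expr[modulator, ], method = "spearman"))
  if (is.na(rho)) rho <- 0
  tibble::tibble(pass = abs(rho) < rho_max, rho = rho)
}

# dMI, the normalised differential MI: (MI_top - MI_bottom)/(MI_top +
# MI_bottom), defined as 0 when the denominator is 0. Always in [-1, 1].
compute_dmi <- function(mi_top, mi_bottom) {
  denom <- mi_top + mi_bottom
  ifelse(denom > 0, (mi_top - mi_bottom) / denom, 0)
}

# dMI for every target at once, given stratum row indices into Y.
dmi_for_strata <- function(x, Y, idx_high, idx_low, estimator) {
  mi_hi <- mi_vec(x[idx_high], Y[idx_high, , drop = FALSE], estimator)
  mi_lo <- mi_vec(x[idx_low], Y[idx_low, , drop = FALSE], estimator)
  list(dmi = compute_dmi(mi_hi, mi_lo), mi_top = mi_hi, mi_bottom = mi_lo)
}

# Fast path for stratum-label permutations (copula estimator only).
# Permuted strata are subsets of a fixed pooled sample set, so each
# target's pooled sort order is computed once; within-subset ranks then
# follow from membership by vector indexing, with no per-permutation sort.
pooled_mi_precompute <- function(x, Y, pooled) {
  k2 <- length(pooled)
  k <- k2 %/% 2L
  nt <- ncol(Y)
  Yp <- Y[pooled, , drop = FALSE]
  o <- order(rep.int(seq_len(nt), rep.int(k2, nt)), as.vector(Yp))
  rowv <- ((o - 1L) %% k2) + 1L
  qn <- qnorm(seq_len(k) / (k + 1))
  qn <- qn - mean(qn)
  const <- colSums(abs(Yp - matrix(Yp[1L, ], k2, nt, byrow = TRUE))) == 0
  list(xp = x[pooled], k2 = k2, k = k, nt = nt, rowv = rowv, qn = qn,
       ssq = sum(qn * qn), const = const)
}

# MI of every target against the TF within the member subset (size k).
pooled_mi_members <- function(pre, member) {
  if (sd(pre$xp[member]) == 0) return(numeric(pre$nt))
  xs <- pre$qn[rank(pre$xp[member], ties.method = "first")]
  xsP <- numeric(pre$k2)
  xsP[member] <- xs
  mem_sorted <- member[pre$rowv]
  pos <- pre$rowv[mem_sorted]
  num <- colSums(matrix(xsP[pos], pre$k, pre$nt) * pre$qn)
  r2 <- pmin((num / pre$ssq)^2, .r2_cap)
  r2[pre$const] <- 0
  -0.5 * log1p(-r2)
}

pooled_dmi <- function(pre, member_high) {
  mi_hi <- pooled_mi_members(pre, member_high)
  mi_lo <- pooled_mi_members(pre, !member_high)
  list(dmi = compute_dmi(mi_hi, mi_lo), mi_top = mi_hi, mi_bottom = mi_lo)
}

#' Conditional MI profile of a regulon under one candidate modulator
#'
#' For every target of the regulon: MI with the TF in the modulator-high
#' stratum (`mi_top`), in the modulator-low stratum (`mi_bottom`), and over
#' all samples (`mi_original`); the normalised differential
#' \eqn{dMI = (MI_{top}-MI_{bottom})/(MI_{top}+MI_{bottom})}; a permutation
#' p-value for |dMI| from `n_perm` random reassignments of the high/low
#' labels over the pooled stratum samples (one label reshuffle scores all
#' targets, with a seed derived from the (TF, modulator) pair); and a
#' bootstrap stability — the fraction of `n_boot` within-stratum resamples
#' in which |dMI| again reaches the target's permutation-null
#' \eqn{(1-\alpha)} quantile with the observed sign. A target is
#' `modulated` when `p_perm < alpha_target` and stability >=
#' `stability_min`. Targets constant within a stratum are kept with
#' `degenerate = TRUE` and `modulated = FALSE`.
#'
#' @param expr Numeric expression matrix.
#' @param regulon Regulon tibble for a single TF (see [infer_regulon()]).
#' @param strata `mindy_strata` from [stratify()].
#' @param n_perm Label permutations (default 1000).
#' @param n_boot Bootstrap resamples (default 100).
#' @param alpha_target Per-target significance level (default 0.01).
#' @param stability_min Minimum bootstrap stability (default 0.5).
#' @param seed Master seed; the child seed is derived from (TF, modulator).
#' @param estimator MI estimator label.
#' @return Tibble of conditional records, one row per target: `tf`,
#'   `modulator`, `target`, `mi_top`, `mi_bottom`, `mi_original`, `dmi`,
#'   `mi_shift`, `p_perm`, `stability`, `modulated`, `degenerate`.
#' @export
conditional_profile <- function(expr, regulon, strata, n_perm = 1000L,
                                n_boot = 100L, alpha_target = 0.01,
                                stability_min = 0.5, seed = 1L,
                                estimator = "copula_gaussian") {
  stopifnot(inherits(strata, "mindy_strata"))
  tf <- unique(regulon$tf)
  stopifnot(length(tf) == 1L)
  targets <- regulon$target
  missing <- setdiff(c(tf, targets), rownames(expr))
  if (length(missing) > 0) {
    stop("genes not in matrix: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- expr[tf, ]
  Y <- t(expr[targets, , drop = FALSE])
  ids <- colnames(expr)
  hi <- match(strata$high, ids)
  lo <- match(strata$low, ids)
  k <- length(hi)

  obs <- dmi_for_strata(x, Y, hi, lo, estimator)
  mi_original <- mi_vec(x, Y, estimator)
  sd0 <- function(idx) apply(Y[idx, , drop = FALSE], 2L, sd) == 0
  degenerate <- sd0(hi) | sd0(lo) | sd(x[hi]) == 0 | sd(x[lo]) == 0

  child <- derive_seed(seed, paste("cond", tf, strata$modulator, sep = ":"))
  pooled <- c(hi, lo)
  fast <- estimator == "copula_gaussian"
  if (fast) pre <- pooled_mi_precompute(x, Y, pooled)
  res <- with_seed(child, {
    # permutation null of dMI, shared label reshuffles across targets
    null_abs <- matrix(0, n_perm, length(targets))
    for (b in seq_len(n_perm)) {
      if (fast) {
        member <- logical(2 * k)
        member[sample.int(2 * k, k)] <- TRUE
        null_abs[b, ] <- abs(pooled_dmi(pre, member)$dmi)
      } else {
        pm <- sample(pooled)
        null_abs[b, ] <- abs(dmi_for_strata(x, Y, pm[1:k], pm[(k + 1):(2 * k)],
                                            estimator)$dmi)
      }
    }
    p_perm <- (1 + colSums(null_abs >= rep(abs(obs$dmi), each = n_perm))) /
      (1 + n_perm)
    crit <- apply(null_abs, 2L, quantile, probs = 1 - alpha_target, names = FALSE)
    # bootstrap: within-stratum resamples; a target is re-observed when its
    # |dMI| reaches the permutation critical value with the observed sign
    flags <- matrix(FALSE, n_boot, length(targets))
    for (b in seq_len(n_boot)) {
      hb <- sample(hi, replace = TRUE)
      lb <- sample(lo, replace = TRUE)
      db <- dmi_for_strata(x, Y, hb, lb, estimator)$dmi
      flags[b, ] <- abs(db) >= crit & (sign(db) == sign(obs$dmi) | obs$dmi == 0)
    }
    list(p_perm = p_perm, stability = colMeans(flags))
  })

  modulated <- res$p_perm < alpha_target & res$stability >= stability_min &
    !degenerate
  tibble::tibble(
    tf = tf, modulator = strata$modulator, target = targets,
    mi_top = obs$mi_top, mi_bottom = obs$mi_bottom,
    mi_original = mi_original, dmi = obs$dmi,
    mi_shift = mi_original * (1 + obs$dmi),
    p_perm = res$p_perm, stability = res$stability,
    modulated = modulated, degenerate = degenerate
  )
}

#' Regulon-level modulation tests (FET and KS)
#'
#' Tests whether the number of modulated targets exceeds chance (one-sided
#' Fisher's exact test on the 2x2 table {edge in this regulon vs rest of
#' the universe} x {modulated vs not}, where the universe is every (TF,
#' target) record evaluated for this modulator in the run) and whether
#' modulation concentrates among the strongest TF-target interactions
#' (one-sided two-sample Kolmogorov-Smirnov: `mi_original` of modulated vs
#' non-modulated targets, alternative — modulated targets have higher MI).
#' When the universe coincides with the regulon (single-TF run), the FET
#' degenerates and an exact one-sided binomial test of the modulated count
#' against `alpha_target` is used instead. Zero modulated targets give
#' `fet_p = ks_p = 1`.
#'
#' @param records Conditional records for one (TF, modulator) pair.
#' @param universe All conditional records for this modulator across all
#'   TFs in the run; defaults to `records` (single-TF fallback).
#' @param alpha_target Per-target level used by the binomial fallback.
#' @return One-row tibble: `fet_p`, `ks_p`, `n_modulated`.
#' @export
regulon_tests <- function(records, universe = NULL, alpha_target = 0.01) {
  stopifnot(nrow(records) > 0)
  n_mod <- sum(records$modulated)
  if (n_mod == 0L) {
    return(tibble::tibble(fet_p = 1, ks_p = 1, n_modulated = 0L))
  }
  single_tf <- is.null(universe) ||
    nrow(universe) == nrow(records) && setequal(
      paste(universe$tf, universe$target),
      paste(records$tf, records$target))
  if (single_tf) {
    fet_p <- binom.test(n_mod, nrow(records), p = alpha_target,
                        alternative = "greater")$p.value
  } else {
    in_reg <- paste(universe$tf, universe$target) %in%
      paste(records$tf, records$target)
    a <- sum(universe$modulated & in_reg)
    b <- sum(universe$modulated & !in_reg)
    c_ <- sum(!universe$modulated & in_reg)
    d <- sum(!universe$modulated & !in_reg)
    fet_p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                         alternative = "greater")$p.value
  }
  mi_mod <- records$mi_original[records$modulated]
  mi_rest <- records$mi_original[!records$modulated]
  ks_p <- if (length(mi_rest) == 0L) 1 else {
    # alternative "less": CDF of x below y's, i.e. modulated MI larger
    suppressWarnings(ks.test(mi_mod, mi_rest, alternative = "less")$p.value)
  }
  tibble::tibble(fet_p = fet_p, ks_p = ks_p, n_modulated = as.integer(n_mod))
}

#' Classify a modulator as positive or negative
#'
#' The sign of the median dMI over the modulated targets: positive
#' modulators increase TF-target MI at high modulator expression, negative
#' ones decrease it. An exactly zero median (or no modulated target) is
#' `"unclassified"`.
#'
#' @param records Conditional records for one (TF, modulator) pair.
#' @return `"positive"`, `"negative"`, or `"unclassified"`.
#' @export
classify_sign <- function(records) {
  d <- records$dmi[records$modulated]
  if (length(d) == 0L) return("unclassified")
  m <- median(d)
  if (m > 0) "positive" else if (m < 0) "negative" else "unclassified"
}

#' Benjamini-Hochberg adjustment of modulator summaries
#'
#' Adjusts `fet_p` across all non-excluded candidates, per TF, with
#' Benjamini-Hochberg, and returns the subset with adjusted p below
#' `alpha_adj` (default 0.001, the pipeline's reporting cut-off). `ks_p` is
#' reported alongside but not combined into the adjustment.
#'
#' @param summaries Modulator-summary tibble (see [run_mindy()]).
#' @param alpha_adj Adjusted-p cut-off.
#' @return The significant subset, with a `p_adj` column.
#' @export
adjust_modulators <- function(summaries, alpha_adj = 0.001) {
  out <- add_p_adj(summaries)
  dplyr::filter(out, !is.na(.data$p_adj), .data$p_adj < alpha_adj)
}

add_p_adj <- function(summaries) {
  summaries |>
    dplyr::group_by(.data$tf) |>
    dplyr::mutate(p_adj = {
      p <- rep(NA_real_, dplyr::n())
      ok <- !.data$excluded_by_independence & !is.na(.data$fet_p)
      p[ok] <- p.adjust(.data$fet_p[ok], method = "BH")
      p
    }) |>
    dplyr::ungroup()
}

#' Two-cohort consensus of significant modulators
#'
#' Retains (TF, modulator) pairs significant in both runs with the same
#' sign; pairs significant in only one cohort, or with conflicting signs,
#' are dropped.
#'
#' @param run_a,run_b Significant modulator summaries from two cohorts
#'   (same TF set).
#' @return Tibble of consensus pairs: `tf`, `modulator`, `sign`,
#'   `p_adj_a`, `p_adj_b`.
#' @export
consensus <- function(run_a, run_b) {
  dplyr::inner_join(
    dplyr::select(run_a, "tf", "modulator", "sign", p_adj_a = "p_adj"),
    dplyr::select(run_b, "tf", "modulator", "sign", p_adj_b = "p_adj"),
    by = c("tf", "modulator", "sign")
  )
}

#' Enumerate in-modulators
#'
#' An in-modulator lies between two TFs: it is a transcriptional target of
#' one (downstream) and a significant modulator of another (upstream). One
#' call is emitted for every (modulator, upstream TF, downstream TF) triple
#' with distinct TFs.
#'
#' @param regulons Regulon tibble for all TFs of the run.
#' @param significant Significant modulator summaries (see
#'   [adjust_modulators()]).
#' @return Tibble: `modulator`, `upstream_tf`, `downstream_tf`.
#' @export
find_in_modulators <- function(regulons, significant) {
  if (nrow(significant) == 0L) {
    return(tibble::tibble(modulator = character(), upstream_tf = character(),
                          downstream_tf = character()))
  }
  membership <- dplyr::select(regulons, downstream_tf = "tf", modulator = "target")
  significant |>
    dplyr::select(modulator = "modulator", upstream_tf = "tf") |>
    dplyr::inner_join(membership, by = "modulator",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$upstream_tf != .data$downstream_tf) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$modulator, .data$upstream_tf, .data$downstream_tf)
}
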