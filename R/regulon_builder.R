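# Regulon construction: per-TF target sets with MI strengths and
# correlation modes, either inferred from the cohort or attached from a
# user-supplied gene-set collection.

# Shared permutation null for rank-based MI: under H0 the permutation
# distribution of MI(tf, gene) given ranks is identical for every gene (up
# to ties), so one null — MI between the TF profile and a permuted rank
# vector — serves all genes of the scan.
mi_null_distribution <- function(x, n_perm, estimator, seed) {
  proto <- seq_along(x)
  with_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) mi_vec(x, cbind(sample(proto)), estimator)[1],
           numeric(1))
  })
}

# Empirical upper-tail p-values of `obs` against a null sample, add-one rule.
empirical_pvalues <- function(obs, null) {
  n <- length(null)
  snull <- sort(null)
  # count of null >= obs via position in the sorted null
  ge <- n - findInterval(obs, snull, left.open = TRUE)
  (1 + ge) / (1 + n)
}

spearman_mode <- function(x, y, ambiguous_cut = 0.05) {
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (is.na(rho)) rho <- 0
  list(mode = if (rho < 0 && abs(rho) >= ambiguous_cut) -1L else 1L,
       rho = rho, ambiguous = abs(rho) < ambiguous_cut)
}

regulon_tibble <- function(tf, target, mi, mode, p_adj, ambiguous_mode) {
  out <- tibble::tibble(tf = tf, target = target, mi = mi, mode = mode,
                        p_adj = p_adj, ambiguous_mode = ambiguous_mode)
  # total deterministic order: MI descending, ties broken by gene id
  dplyr::arrange(out, dplyr::desc(.data$mi), .data$target)
}

#' Infer a TF regulon from the expression matrix
#'
#' For every gene other than `tf`, estimates MI(tf, gene), assigns a
#' permutation p-value from a per-TF null (MI of the TF profile against
#' permuted ranks — identical across genes because the estimators are
#' rank-based), adjusts across genes with Benjamini-Hochberg, and retains
#' genes with adjusted p below `alpha`. The interaction mode (+1/-1) is the
#' sign of the Spearman correlation; |rho| < 0.05 is recorded as +1 with
#' `ambiguous_mode = TRUE`. Note that the add-one permutation floor bounds
#' the attainable BH-adjusted p at roughly \eqn{m/(k (1+n_{perm}))} for `k`
#' floor-level hits among `m` genes, so `n_perm` must comfortably exceed
#' \eqn{m / (k \alpha)} for a scan to retain anything. Optionally applies
#' the data-processing-
#' inequality (DPI) post-filter: a target whose MI with another retained
#' target exceeds both their TF MIs is taken as indirect and dropped.
#'
#' @param expr Numeric expression matrix, genes in rows.
#' @param tf Gene id of the transcription factor (must be in `expr` and
#'   non-constant).
#' @param n_perm Permutations for the MI null (default 1000).
#' @param alpha BH-adjusted significance level (default 0.01).
#' @param seed Integer master seed; a child seed is derived per TF.
#' @param estimator MI estimator label, see [mutual_information()].
#' @param apply_dpi Apply the DPI post-filter (default `FALSE`).
#' @return A tibble with columns `tf`, `target`, `mi`, `mode`, `p_adj`,
#'   `ambiguous_mode`, sorted by `mi` descending.
#' @export
infer_regulon <- function(expr, tf, n_perm = 1000L, alpha = 0.01, seed = 1L,
                          estimator = "copula_gaussian", apply_dpi = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  if (!tf %in% rownames(expr)) stop("TF not in matrix: ", tf, call. = FALSE)
  x <- expr[tf, ]
  if (sd(x) == 0) stop("TF '", tf, "' is constant; regulon undefined", call. = FALSE)
  genes <- setdiff(rownames(expr), tf)
  Y <- t(expr[genes, , drop = FALSE])
  mi <- mi_vec(x, Y, estimator)
  null <- mi_null_distribution(x, n_perm, estimator,
                               derive_seed(seed, paste0("regulon:", tf)))
  p <- empirical_pvalues(mi, null)
  p_adj <- p.adjust(p, method = "BH")
  keep <- which(p_adj < alpha)
  if (length(keep) == 0L) {
    return(regulon_tibble(character(), character(), numeric(), integer(),
                          numeric(), logical()))
  }
  modes <- lapply(keep, function(j) spearman_mode(x, Y[, j]))
  reg <- regulon_tibble(tf = tf, target = genes[keep], mi = mi[keep],
                        mode = vapply(modes, `[[`, integer(1), "mode"),
                        p_adj = p_adj[keep],
                        ambiguous_mode = vapply(modes, `[[`, logical(1), "ambiguous"))
  if (apply_dpi && nrow(reg) > 1L) reg <- dpi_filter(reg, expr, estimator)
  reg
}

# ARACNe-style DPI: for each retained target pair (a, b), if MI(a, b)
# exceeds both MI(tf, a) and MI(tf, b), the weaker TF edge is indirect.
dpi_filter <- function(reg, expr, estimator) {
  tg <- reg$target
  mi_tf <- setNames(reg$mi, tg)
  Y <- t(expr[tg, , drop = FALSE])
  drop <- character()
  for (i in seq_len(length(tg) - 1L)) {
    mi_pair <- mi_vec(Y[, i], Y[, (i + 1):length(tg), drop = FALSE], estimator)
    for (k in seq_along(mi_pair)) {
      j <- i + k
      if (mi_pair[k] > mi_tf[i] && mi_pair[k] > mi_tf[j]) {
        drop <- c(drop, if (mi_tf[i] < mi_tf[j]) tg[i] else tg[j])
      }
    }
  }
  n0 <- nrow(reg)
  reg <- reg[!reg$target %in% drop, , drop = FALSE]
  mindy_log("DPI filter removed ", n0 - nrow(reg), " target(s)")
  reg
}

#' Attach externally supplied regulons to a cohort
#'
#' Computes MI and mode from `expr` for the members of each named gene set
#' (e.g. read from GMT with [read_gene_sets()]), treating the set name as
#' the TF. Members absent from the matrix are dropped with a logged count;
#' a set name absent from the matrix is an error.
#'
#' @param sets Named list of character vectors (TF -> target ids).
#' @param expr Numeric expression matrix, genes in rows.
#' @param estimator MI estimator label.
#' @return A tibble of regulons (one row per TF-target edge), `p_adj = NA`.
#' @export
attach_regulons <- function(sets, expr, estimator = "copula_gaussian") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  purrr::map_dfr(names(sets), function(tf) {
    if (!tf %in% rownames(expr)) {
      stop("regulon TF not in matrix: ", tf, call. = FALSE)
    }
    members <- setdiff(sets[[tf]], tf)
    present <- intersect(members, rownames(expr))
    if (length(present) < length(members)) {
      mindy_log("regulon ", tf, ": dropped ",
                length(members) - length(present), " absent member(s)")
    }
    if (length(present) == 0L) {
      return(regulon_tibble(character(), character(), numeric(), integer(),
                            numeric(), logical()))
    }
    x <- expr[tf, ]
    Y <- t(expr[present, , drop = FALSE])
    mi <- mi_vec(x, Y, estimator)
    modes <- lapply(seq_along(present), function(j) spearman_mode(x, Y[, j]))
    regulon_tibble(tf = tf, target = present, mi = mi,
                   mode = vapply(modes, `[[`, integer(1), "mode"),
                   p_adj = NA_real_,
                   ambiguous_mode = vapply(modes, `[[`, logical(1), "ambiguous"))
  })
}
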