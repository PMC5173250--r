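# Empirical gene-set resampling test: does a gene set's mean aberration
# frequency exceed what equal-size random sets achieve?

#' Empirical enrichment of a gene set's mean aberration frequency
#'
#' Compares the mean aberration frequency (fraction of samples with a
#' mutation or copy-number alteration) of `gene_set` against `n_random`
#' same-size sets drawn uniformly without replacement from all genes of
#' the table. The empirical p uses the add-one rule with a `>=`
#' comparison, \eqn{p = (1 + \#\{\bar{x}_{rand} \ge \bar{x}_{obs}\}) /
#' (1 + n_{random})}, so p is never 0 and ties count against enrichment.
#' The 1st and 99th percentiles of the random-mean distribution are
#' reported as whiskers. The sampling universe is exactly the genes of the
#' supplied table; restricting the universe (e.g. to cancer-annotated
#' genes) is done by supplying a restricted table.
#'
#' @param table Aberration frequencies: a data frame whose first column is
#'   the gene id and second the frequency in \[0, 1\], or a named numeric
#'   vector.
#' @param gene_set Character vector of gene ids, all present in `table`.
#' @param n_random Number of random sets (>= 1000; default 10000).
#' @param seed Integer seed.
#' @return One-row tibble: `observed_mean`, `empirical_p`, `percentile_1`,
#'   `percentile_99`, `set_size`, `n_random`.
#' @export
empirical_set_enrichment <- function(table, gene_set, n_random = 10000L,
                                     seed = 1L) {
  if (n_random < 1000L) stop("n_random must be >= 1000", call. = FALSE)
  if (is.data.frame(table)) {
    freq <- setNames(as.numeric(table[[2]]), as.character(table[[1]]))
  } else {
    freq <- table
  }
  if (is.null(names(freq)) || anyDuplicated(names(freq))) {
    stop("aberration table needs unique gene ids", call. = FALSE)
  }
  if (any(freq < 0 | freq > 1 | is.na(freq))) {
    stop("aberration frequencies must lie in [0, 1]", call. = FALSE)
  }
  missing <- setdiff(gene_set, names(freq))
  if (length(missing) > 0) {
    stop("gene(s) missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- length(gene_set)
  observed <- mean(freq[gene_set])
  rmeans <- with_seed(seed, {
    vapply(seq_len(n_random),
           function(b) mean(freq[sample.int(length(freq), m)]),
           numeric(1))
  })
  p <- (1 + sum(rmeans >= observed)) / (1 + n_random)
  tibble::tibble(
    observed_mean = observed,
    empirical_p = p,
    percentile_1 = quantile(rmeans, 0.01, names = FALSE),
    percentile_99 = quantile(rmeans, 0.99, names = FALSE),
    set_size = m,
    n_random = as.integer(n_random)
  )
}
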