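# Mutual information engine: rank-based MI estimators plus the permutation
# and bootstrap machinery reused by every downstream stage.

# Normal scores of a vector: rank-transform (average ties), map to quantiles
# of the standard normal. The basis of the Gaussian-copula estimator.
normal_scores <- function(x) {
  qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

# Squared-correlation cap: the copula estimate is -1/2 log(1 - r^2), which
# diverges as |r| -> 1; capping r^2 bounds it at ~4.605 nats.
.r2_cap <- 0.9999

# Vectorised Gaussian-copula MI between x and every column of Y (rows =
# samples). Ranking is done within the supplied rows, so the same function
# serves full-cohort and within-stratum estimates. Ties are broken by
# first occurrence, which makes the within-subset ranks of every column an
# exact permutation of 1..n: the normal scores of each column are then a
# permutation of one fixed score vector, so all column ranks come from a
# single order() call and the score correlations from one crossprod.
# Zero-variance columns (and a zero-variance x) yield MI 0.
mi_copula_vec <- function(x, Y) {
  n <- length(x)
  nt <- ncol(Y)
  if (nt == 0L) return(numeric(0))
  if (sd(x) == 0) return(numeric(nt))
  qn <- qnorm(seq_len(n) / (n + 1))
  qn <- qn - mean(qn)
  ssq <- sum(qn * qn)
  xs <- qn[rank(x, ties.method = "first")]
  o <- order(rep.int(seq_len(nt), rep.int(n, nt)), as.vector(Y))
  rk <- integer(n * nt)
  rk[o] <- rep.int(seq_len(n), nt)
  S <- matrix(qn[rk], n, nt)
  num <- drop(crossprod(xs, S))
  r2 <- num^2 / (ssq * ssq)
  # first-occurrence ranks give a constant column spurious ranks 1..n:
  # detect and zero explicitly
  const <- colSums(abs(Y - matrix(Y[1L, ], n, nt, byrow = TRUE))) == 0
  r2[const] <- 0
  -0.5 * log1p(-pmin(r2, .r2_cap))
}

# Plug-in MI on an equal-frequency b x b grid over ranks, b = max(2,
# floor(n^(1/3))). Slower, fully nonparametric alternative estimator.
mi_binned_one <- function(x, y) {
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) return(0)
  b <- max(2L, floor(n^(1 / 3)))
  bx <- ceiling(rank(x, ties.method = "first") * b / n)
  by <- ceiling(rank(y, ties.method = "first") * b / n)
  p <- table(factor(bx, levels = 1:b), factor(by, levels = 1:b)) / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  max(0, sum(p[nz] * log(p[nz] / e[nz])))
}

mi_binned_vec <- function(x, Y) {
  vapply(seq_len(ncol(Y)), function(j) mi_binned_one(x, Y[, j]), numeric(1))
}

mi_vec <- function(x, Y, estimator = "copula_gaussian") {
  switch(estimator,
    copula_gaussian = mi_copula_vec(x, Y),
    binned_plugin   = mi_binned_vec(x, Y),
    stop("unknown estimator: ", estimator, call. = FALSE)
  )
}

#' Mutual information between two expression profiles
#'
#' Estimates mutual information (in nats) between two equal-length numeric
#' vectors with a rank-based estimator, so the estimate is invariant under
#' strictly monotone transforms of either input and symmetric in its
#' arguments. The default `copula_gaussian` estimator rank-transforms both
#' vectors to normal scores, takes the Pearson correlation r of the scores,
#' and returns \eqn{-\frac{1}{2}\log(1-r^2)}, with \eqn{r^2} capped at
#' 0.9999 (~4.605 nats). `binned_plugin` uses an equal-frequency
#' \eqn{b \times b} grid on ranks with \eqn{b = \max(2, \lfloor n^{1/3}
#' \rfloor)} and the plug-in entropy sum.
#'
#' A constant (zero-variance) input yields MI 0 with `degenerate = TRUE`
#' rather than an error, so cohort-wide scans do not abort.
#'
#' @param x,y Numeric vectors of equal length (>= 4), finite values.
#' @param estimator `"copula_gaussian"` (default) or `"binned_plugin"`.
#' @return A one-row tibble with columns `value` (nats, >= 0), `estimator`,
#'   `n`, and `degenerate`.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- 0.8 * x + rnorm(500, sd = 0.6)
#' mutual_information(x, y)
#' @export
mutual_information <- function(x, y, estimator = c("copula_gaussian", "binned_plugin")) {
  estimator <- match.arg(estimator)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  degenerate <- sd(x) == 0 || sd(y) == 0
  value <- if (degenerate) 0 else mi_vec(x, cbind(y), estimator)[1]
  tibble::tibble(value = value, estimator = estimator, n = length(x),
                 degenerate = degenerate)
}

#' Closed-form mutual information of a bivariate Gaussian
#'
#' For a bivariate normal with correlation `rho`, MI is
#' \eqn{-\frac{1}{2}\log(1-\rho^2)} nats. Serves as the analytic oracle for
#' the rank-based estimators.
#'
#' @param rho Correlation, `|rho| < 1`.
#' @return MI in nats.
#' @examples
#' gaussian_mi(0.8) # 0.5108 nats
#' @export
gaussian_mi <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  -0.5 * log1p(-rho^2)
}

#' Permutation p-value for a bivariate statistic
#'
#' Permutes `y` relative to `x` `n_perm` times and compares the magnitude of
#' the observed statistic with the permuted magnitudes using the add-one
#' rule, \eqn{p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (1 + n_{perm})},
#' so p is never 0 and is bounded below by \eqn{1/(1+n_{perm})}.
#'
#' @param x,y Numeric vectors of equal length.
#' @param statistic Function of `(x, y)` returning a single number. Defaults
#'   to Gaussian-copula MI.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A one-row tibble: `observed`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_pvalue <- function(x, y, statistic = NULL, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100 (unstable tail)", call. = FALSE)
  statistic <- statistic %||% function(x, y) mi_vec(x, cbind(y))[1]
  observed <- statistic(x, y)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) statistic(x, sample(y)), numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(observed))) / (1 + n_perm)
  tibble::tibble(observed = observed, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Bootstrap stability of a boolean call
#'
#' Resamples `n` sample indices with replacement `n_boot` times and returns
#' the fraction of resamples in which `flag_fn` still makes the call — the
#' frequency with which an inferred modulated target is re-observed in
#' subsamples of the cohort.
#'
#' @param flag_fn Function taking an integer index vector (a resample of
#'   `1:n`) and returning a single logical.
#' @param n Number of samples to resample from.
#' @param n_boot Number of bootstrap resamples (>= 20).
#' @param seed Integer seed.
#' @return Fraction in \[0, 1\].
#' @export
bootstrap_flag_stability <- function(flag_fn, n, n_boot = 100L, seed = 1L) {
  if (n_boot < 20L) stop("n_boot must be >= 20", call. = FALSE)
  flags <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(b) isTRUE(flag_fn(sample.int(n, n, replace = TRUE))),
           logical(1))
  })
  mean(flags)
}
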