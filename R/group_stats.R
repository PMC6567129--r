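#' Baringhaus-Franz Cramér statistic
#'
#' Multivariate two-sample statistic based on Euclidean inter-point
#' distances:
#' \deqn{T = \frac{mn}{m+n}\Big(\frac{1}{mn}\sum_{i,j}\|x_i-y_j\|
#'   - \frac{1}{2m^2}\sum_{i,i'}\|x_i-x_{i'}\|
#'   - \frac{1}{2n^2}\sum_{j,j'}\|y_j-y_{j'}\|\Big)}
#' T is non-negative and zero when the two samples coincide.
#'
#' @param X,Y Numeric matrices (rows = points) of equal column dimension;
#'   vectors are treated as 1-D samples.
#' @return The statistic (scalar, >= 0 up to rounding).
#' @export
cramer_statistic <- function(X, Y) {
  X <- as_points(X); Y <- as_points(Y)
  if (ncol(X) != ncol(Y))
    stop("samples must share the same dimension", call. = FALSE)
  D <- as.matrix(stats::dist(rbind(X, Y)))
  .cramer_stat_idx_cpp(D, seq_len(nrow(X)))
}

as_points <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  if (nrow(X) < 1) stop("empty sample", call. = FALSE)
  X
}

#' Permutation Cramér two-sample test
#'
#' Tests whether two multivariate samples come from the same distribution
#' using [cramer_statistic()] with a Monte-Carlo permutation null: the
#' pooled points are randomly reassigned to two samples of the original
#' sizes `replicates` times. The p-value uses the add-one convention
#' `p = (#\{null >= observed\} + 1) / (replicates + 1)`, so it is never 0;
#' the critical value is the empirical `1 - alpha` quantile of the null
#' draws.
#'
#' @inheritParams cramer_statistic
#' @param replicates Number of permutation replicates (default 1000; a
#'   warning is issued below 100).
#' @param alpha Significance level for the reported critical value.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `cramer_test`: list with `statistic`,
#'   `critical_value`, `p_value`, `replicates`, `alpha`, `seed`, and the
#'   null draws in `null_statistics`.
#' @export
cramer_test <- function(X, Y, replicates = 1000, alpha = 0.05, seed = 1) {
  X <- as_points(X); Y <- as_points(Y)
  if (ncol(X) != ncol(Y))
    stop("samples must share the same dimension", call. = FALSE)
  m <- nrow(X); n <- nrow(Y)
  if (m + n < 4) stop("need at least 4 points in total", call. = FALSE)
  if (replicates < 100)
    warning("fewer than 100 permutation replicates; the p-value is coarse")
  D <- as.matrix(stats::dist(rbind(X, Y)))
  observed <- .cramer_stat_idx_cpp(D, seq_len(m))
  set.seed(seed)
  null_stats <- .cramer_perm_cpp(D, m, as.integer(replicates))
  p <- (sum(null_stats >= observed) + 1) / (replicates + 1)
  structure(list(
    statistic = observed,
    critical_value = unname(stats::quantile(null_stats, 1 - alpha)),
    p_value = p,
    replicates = as.integer(replicates),
    alpha = alpha,
    seed = seed,
    null_statistics = null_stats
  ), class = "cramer_test")
}

#' @export
print.cramer_test <- function(x, ...) {
  cat(sprintf(paste0(
    "Permutation Cramer two-sample test\n",
    "  statistic = %.4g, critical value = %.4g (alpha = %g)\n",
    "  p = %.4g (%d Monte-Carlo permutation replicates)\n"),
    x$statistic, x$critical_value, x$alpha, x$p_value, x$replicates))
  invisible(x)
}
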