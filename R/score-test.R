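#' Variance-component score statistics
#'
#' The raw statistic is the quadratic form \eqn{Q = \hat M' K \hat M} in
#' the null-model martingale residuals; the small-sample-corrected
#' statistic rescales it by the residual sum of squares,
#' \eqn{Q^* = Q / (\hat M'\hat M)}.
#'
#' @param M Martingale residual vector (not all zero).
#' @param K Kernel matrix, dimensions matching `M`.
#' @return List with elements `Q` and `Q_star`.
#' @export
score_statistics <- function(M, K) {
  stopifnot(length(M) == nrow(K), nrow(K) == ncol(K))
  mss <- sum(M^2)
  if (mss == 0) stop("untestable: martingale residuals are all zero")
  Q <- drop(crossprod(M, K %*% M))
  list(Q = Q, Q_star = Q / mss)
}

#' Mixture weights of the null distribution
#'
#' Uncorrected test: the eigenvalues of \eqn{P_0^{1/2} K P_0^{1/2}}.
#' Corrected test (requires the observed \eqn{q = Q^*}): the eigenvalues
#' of \eqn{P_0^{1/2} P_0^* (K - qI) P_0^* P_0^{1/2}}, which are of mixed
#' sign. Singular components of `K` contribute zero weights.
#'
#' @param K Kernel matrix.
#' @param fit A [fit_null_cox()] object (provides \eqn{P_0^{1/2}} and
#'   \eqn{P_0^*}).
#' @param q Observed corrected statistic; required when
#'   `corrected = TRUE`.
#' @param corrected Whether to build the corrected-test weights.
#' @return Numeric vector of eigenvalues with attribute `origin`
#'   (`"corrected"` or `"uncorrected"`).
#' @export
mixture_weights <- function(K, fit, q = NULL, corrected = TRUE) {
  stopifnot(inherits(fit, "mks_null_cox"), nrow(K) == fit$n)
  if (corrected) {
    if (is.null(q)) stop("corrected weights require the observed q = Q*")
    inner <- fit$P0_star %*% (K - diag(q, fit$n)) %*% fit$P0_star
  } else {
    inner <- K
  }
  A <- fit$P0_half %*% inner %*% fit$P0_half
  A <- (A + t(A)) / 2
  w <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  attr(w, "origin") <- if (corrected) "corrected" else "uncorrected"
  w
}

#' Analytic p-value of the kernel score test
#'
#' Corrected test: \eqn{P(Q^* > q)} is the probability that the
#' mixed-sign mixture built from \eqn{K - qI} exceeds zero. Uncorrected
#' test: the tail of the nonnegative mixture at the observed \eqn{Q}.
#' Both tails are computed with [chisq_mix_tail()].
#'
#' @param M Martingale residual vector.
#' @param K Kernel matrix.
#' @param fit A [fit_null_cox()] object.
#' @param corrected Use the small-sample-corrected statistic (default).
#' @param accuracy Davies integration accuracy.
#' @return List: `Q`, `Q_star`, `p` (in `[0, 1]`), `method` (`"davies"`
#'   or `"moment"` fallback), `weights`.
#' @export
analytic_pvalue <- function(M, K, fit, corrected = TRUE,
                            accuracy = 1e-6) {
  qs <- score_statistics(M, K)
  if (corrected) {
    w <- mixture_weights(K, fit, q = qs$Q_star, corrected = TRUE)
    degenerate <- max(abs(w)) < 1e-12 * max(abs(qs$Q_star), 1)
    p <- if (degenerate) {
      structure(1, method = "degenerate", abs_error = 0)
    } else {
      chisq_mix_tail(w, 0, accuracy = accuracy)
    }
  } else {
    w <- mixture_weights(K, fit, corrected = FALSE)
    p <- chisq_mix_tail(w, qs$Q, accuracy = accuracy)
  }
  list(Q = qs$Q, Q_star = qs$Q_star, p = as.numeric(p),
       method = attr(p, "method"), weights = w)
}

#' Permutation p-value of the kernel score test
#'
#' Permutes the martingale residual vector against the fixed kernel
#' (equivalent to permuting the sample labels of `K`, preserving the
#' covariate-adjusted null fit) and recomputes the corrected statistic;
#' since its denominator is permutation-invariant this is equivalent to
#' permuting `Q`. Returns the add-one estimator
#' \eqn{p = (1 + \#\{Q^*_{perm} \ge Q^*_{obs}\}) / (B + 1)}.
#'
#' @param M Martingale residual vector.
#' @param K Kernel matrix.
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A p-value in `[1/(B+1), 1]`.
#' @export
permutation_pvalue <- function(M, K, B = 1000, seed = 1) {
  stopifnot(B >= 100)
  n <- length(M)
  q_obs <- drop(crossprod(M, K %*% M))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(B)) {
    mp <- M[sample.int(n)]
    if (drop(crossprod(mp, K %*% mp)) >= q_obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (B + 1)
}

#' Multiple-kernel adjustment
#'
#' Adjusts per-kernel p-values across the kernels tested
#' (Benjamini-Hochberg FDR or Bonferroni) and reports the minimum
#' adjusted p-value as the omnibus value.
#'
#' @param p Numeric vector of per-kernel p-values.
#' @param method `"fdr"` (Benjamini-Hochberg) or `"bonferroni"`.
#' @return Vector of adjusted p-values with the omnibus minimum attached
#'   as attribute `"omnibus"`.
#' @export
multi_kernel_adjust <- function(p, method = c("fdr", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(length(p) >= 1)
  adj <- p.adjust(p, method = if (method == "fdr") "BH" else "bonferroni")
  attr(adj, "omnibus") <- min(adj)
  adj
}
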