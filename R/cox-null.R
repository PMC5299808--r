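#' Fit the covariates-only Cox proportional hazards null model
#'
#' Fits \eqn{\lambda(t; X) = \lambda_0(t) \exp(X\beta)} by maximum
#' partial likelihood with the Efron approximation for tied event times
#' (via [survival::coxph()]; with `p = 0` covariates no fitting is
#' needed), then assembles every quantity the kernel score test
#' requires:
#' \itemize{
#'   \item Efron-adjusted baseline cumulative hazard increments
#'     (Breslow-type estimator with the Efron tie denominators);
#'   \item martingale residuals \eqn{\hat M_i = \Delta_i -
#'     \int Y_i(t) e^{\hat\beta'X_i} d\hat\Lambda_0(t)}, which sum to
#'     zero at convergence;
#'   \item the diagonal variance approximation \eqn{V_{ii} =
#'     e^{\hat\beta'X_i}\hat\Lambda_0(U_i) - w_i(\hat\beta, U_i)^2} with
#'     \eqn{w_i(\beta,t) = e^{\hat\beta'X_i}/\hat S_0(t)};
#'   \item the IRLS weight matrix \eqn{W}: the diagonal of the negative
#'     Hessian of the Efron log partial likelihood with respect to the
#'     linear predictor;
#'   \item the projections \eqn{P_0 = V - VX(X'VX)^{-1}X'V} and
#'     \eqn{P_0^* = I - X^*(X^{*\prime}X^*)^{-1}X^{*\prime}} with
#'     \eqn{X^* = W^{1/2}X}, plus the symmetric square root
#'     \eqn{P_0^{1/2}}.
#' }
#'
#' @param time Positive observed times \eqn{U_i = \min(T_i, C_i)}.
#' @param event Event indicators (1 = event, 0 = censored); at least one
#'   event is required.
#' @param X Covariate matrix (`n x p`, full column rank), or `NULL` for
#'   the no-covariate model.
#' @param variance Diagonal approximation used for the residual
#'   covariance inside \eqn{P_0}: `"hessian"` (default) uses the IRLS
#'   weight `W` (the negative-Hessian diagonal, always nonnegative);
#'   `"main_text"` uses the `V` with the \eqn{w_i(\beta, U_i)^2} term,
#'   which can be negative for subjects censored near the end of
#'   follow-up and can render \eqn{P_0} indefinite. Both diagonals are
#'   always computed and returned.
#' @param indefinite_tol Relative eigenvalue tolerance: the fit errors
#'   if \eqn{\lambda_{min}(P_0) < -tol \cdot \lambda_{max}}; smaller
#'   negative eigenvalues are clipped to zero in \eqn{P_0^{1/2}}.
#'
#' @return An object of class `mks_null_cox`; see Details. Components:
#'   `beta`, `eta` (linear predictor), `M` (martingale residuals), `V`,
#'   `W` (diagonals), `P0`, `P0_star`, `P0_half`, `baseline` (tibble of
#'   event times and Efron increments), `n`, `n_events`, `convergence`.
#' @export
fit_null_cox <- function(time, event, X = NULL,
                         variance = c("hessian", "main_text"),
                         indefinite_tol = 0.05) {
  variance <- match.arg(variance)
  n <- length(time)
  stopifnot(length(event) == n, all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 1) stop("no events: the null model cannot be fitted")
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n)
    if (ncol(X) == 0) X <- NULL
  }
  p <- if (is.null(X)) 0L else ncol(X)
  if (n < p + 2) stop("need n >= p + 2 observations")

  if (p > 0) {
    if (qr(X)$rank < p) stop("collinear covariates: X is rank deficient")
    fit <- survival::coxph(
      survival::Surv(time, event) ~ X, ties = "efron",
      control = survival::coxph.control(eps = 1e-10, iter.max = 50))
    beta <- unname(stats::coef(fit))
    if (any(is.na(beta))) stop("Cox null fit failed (NA coefficients)")
    conv <- list(iterations = fit$iter,
                 loglik = unname(fit$loglik[2]))
    eta <- drop(X %*% beta)
  } else {
    beta <- numeric(0)
    conv <- list(iterations = 0L, loglik = NA_real_)
    eta <- rep(0, n)
  }

  parts <- .efron_pieces(time, event, eta)
  M <- event - exp(eta) * parts$H
  V <- exp(eta) * parts$Lambda0_at - (exp(eta) / parts$S0_at)^2
  W <- parts$W

  ## W_ii = 0 is structural for subjects censored before the first event
  ## (they contribute no partial-likelihood information); negative values
  ## can only arise from numerical degeneracy.
  if (any(W < 0))
    warning("negative IRLS weights clipped to 1e-12")
  W <- pmax(W, 1e-12)

  Vp <- if (variance == "hessian") W else V
  if (p > 0) {
    VX <- Vp * X
    P0 <- diag(Vp) - VX %*% solve(crossprod(X, VX), t(VX))
    Xs <- sqrt(W) * X
    P0_star <- diag(n) - Xs %*% solve(crossprod(Xs), t(Xs))
  } else {
    P0 <- diag(Vp)
    P0_star <- diag(n)
  }
  P0 <- (P0 + t(P0)) / 2
  P0_star <- (P0_star + t(P0_star)) / 2

  eig <- eigen(P0, symmetric = TRUE)
  lmax <- max(eig$values, 0)
  if (min(eig$values) < -indefinite_tol * lmax)
    stop("P0 is indefinite beyond tolerance; smallest eigenvalue ",
         signif(min(eig$values), 4), " vs largest ", signif(lmax, 4))
  vals <- pmax(eig$values, 0)
  P0_half <- eig$vectors %*% (sqrt(vals) * t(eig$vectors))
  P0_half <- (P0_half + t(P0_half)) / 2

  structure(
    list(beta = beta, eta = eta, time = time, event = event, X = X,
         M = M, V = V, W = W, variance = variance,
         P0 = P0, P0_star = P0_star,
         P0_half = P0_half,
         baseline = tibble::tibble(time = parts$event_times,
                                   increment = parts$dLambda,
                                   n_events = parts$d),
         n = n, n_events = sum(event), convergence = conv),
    class = "mks_null_cox")
}

## Efron tie-adjusted baseline pieces at a fixed linear predictor eta.
## Returns, per subject: the cumulative baseline hazard Lambda0(U_i)
## (plain accumulation of Efron increments), the subject's own expected
## hazard accumulation H_i (with the (1 - k/d) downweighting for tied
## deaths, so that sum(Delta - e^eta H) = 0), the risk-set normaliser
## S0(U_i), and the diagonal negative Hessian W of the Efron log partial
## likelihood with respect to eta.
.efron_pieces <- function(time, event, eta) {
  n <- length(time)
  w <- exp(eta)
  event_times <- sort(unique(time[event == 1]))
  m <- length(event_times)

  H <- numeric(n)            # subject-specific integral for residuals
  W <- numeric(n)
  dLambda <- numeric(m)
  d <- integer(m)

  for (j in seq_len(m)) {
    t_j <- event_times[j]
    at_risk <- time >= t_j
    died <- event == 1 & time == t_j
    d_j <- sum(died); d[j] <- d_j
    r_j <- sum(w[at_risk])
    s_j <- sum(w[died])
    k <- seq_len(d_j) - 1
    denom <- r_j - (k / d_j) * s_j
    inc <- sum(1 / denom)
    dLambda[j] <- inc

    ## full increment to everyone at risk, then correct the tied deaths
    H[at_risk] <- H[at_risk] + inc
    if (d_j > 0)
      H[died] <- H[died] - sum((k / d_j) / denom)

    ## negative Hessian wrt eta: a_ik = w_i (1 - (k/d) I(i in D)) / denom_k
    ## W_i += sum_k a_ik - a_ik^2
    for (kk in k) {
      a <- numeric(n)
      a[at_risk] <- w[at_risk] / denom[kk + 1]
      a[died] <- a[died] * (1 - kk / d_j)
      W <- W + a - a^2
    }
  }

  ## Lambda0(U_i) and S0(U_i) by step lookup
  cum_inc <- cumsum(dLambda)
  pos <- findInterval(time, event_times)
  Lambda0_at <- ifelse(pos == 0, 0, cum_inc[pmax(pos, 1)])
  S0_at <- vapply(time, function(u) sum(w[time >= u]), numeric(1))

  list(event_times = event_times, dLambda = dLambda, d = d,
       Lambda0_at = Lambda0_at, H = H, W = W, S0_at = S0_at)
}

#' Martingale residuals of a fitted null model
#'
#' @param object A [fit_null_cox()] fit.
#' @param type Only `"martingale"` is supported.
#' @param ... Unused.
#' @return Numeric vector summing to zero (to solver tolerance).
#' @export
residuals.mks_null_cox <- function(object, type = "martingale", ...) {
  match.arg(type, "martingale")
  object$M
}

#' @export
print.mks_null_cox <- function(x, ...) {
  cat("<mks_null_cox> n =", x$n, " events =", x$n_events,
      " p =", length(x$beta), "\n")
  if (length(x$beta)) cat("  beta:", signif(x$beta, 4), "\n")
  invisible(x)
}
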