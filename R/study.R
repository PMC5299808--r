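#' Replicate the kernel test over simulated datasets
#'
#' Runs the full pipeline (community sample, covariates, survival times,
#' censoring, null Cox fit, kernels, p-values) on `n_reps` independent
#' replicates of one simulation configuration. This is the engine behind
#' the type-I-error and power studies: with `cfg$gamma = 0` the
#' per-kernel p-values should be uniform, and their rejection rate at
#' any level should match it.
#'
#' The censoring rate is calibrated once (from 10,000 Monte-Carlo latent
#' times) and reused across replicates, mirroring a fixed study design.
#'
#' @param spec A [community_spec()].
#' @param cfg An [effect_config()].
#' @param n Per-replicate sample size.
#' @param n_reps Number of replicates.
#' @param kernels Kernel codes (see [build_kernels()]).
#' @param seed Master seed; each replicate derives its own sub-seeds.
#' @param permutations If non-`NULL`, also compute permutation p-values
#'   with this many permutations.
#' @param include_uncorrected Also compute the uncorrected analytic
#'   p-value.
#' @param variance Passed to [fit_null_cox()].
#'
#' @return A tibble with columns `rep`, `kernel`, `p_value`, optionally
#'   `p_uncorrected` and `p_permutation`, plus `realized_censoring`, and
#'   the calibrated `mu` as attribute `"mu"`.
#' @export
simulate_pvalues <- function(spec, cfg, n, n_reps,
                             kernels = c("wu", "uu", "gu:0.5", "bc"),
                             seed = 1, permutations = NULL,
                             include_uncorrected = FALSE,
                             variance = "hessian") {
  stopifnot(inherits(spec, "community_spec"),
            inherits(cfg, "effect_config"), n_reps >= 1)
  seeds <- derive_seeds(seed, n_reps + 1)
  if (is.na(cfg$mu))
    cfg$mu <- calibrate_censoring(
      latent_time_factory(spec, cfg, seed = seeds[n_reps + 1]),
      cfg$target_censoring)

  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sub <- derive_seeds(seeds[r], 5)
    counts <- sample_counts(spec, n, seed = sub[1])
    X <- simulate_covariates(n, seed = sub[2])
    tt <- simulate_event_times(counts, X, cfg, seed = sub[3])
    obs <- apply_censoring(tt, cfg$mu, seed = sub[4])
    fit <- fit_null_cox(obs$time, obs$event, X, variance = variance)
    K <- build_kernels(counts, tree = spec$tree, kernels = kernels)
    perm_seeds <- if (!is.null(permutations))
      derive_seeds(sub[5], length(K)) else NULL
    pk <- lapply(seq_along(K), function(i) {
      a <- analytic_pvalue(fit$M, K[[i]], fit, corrected = TRUE)
      out <- tibble::tibble(rep = r, kernel = names(K)[i],
                            p_value = a$p)
      if (include_uncorrected)
        out$p_uncorrected <-
          analytic_pvalue(fit$M, K[[i]], fit, corrected = FALSE)$p
      if (!is.null(permutations))
        out$p_permutation <- permutation_pvalue(
          fit$M, K[[i]], B = permutations, seed = perm_seeds[i])
      out
    })
    rows[[r]] <- dplyr::bind_rows(pk)
    rows[[r]]$realized_censoring <- mean(obs$event == 0)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mu") <- cfg$mu
  out
}

#' Empirical rejection rates at a significance level
#'
#' @param pvals A [simulate_pvalues()] tibble.
#' @param alpha Significance level (default 0.05).
#' @return One row per kernel with the rejection rate of each p-value
#'   column and the replicate count.
#' @export
rejection_rates <- function(pvals, alpha = 0.05) {
  dplyr::summarise(
    dplyr::group_by(pvals, .data$kernel),
    dplyr::across(dplyr::starts_with("p_"), ~ mean(.x <= alpha)),
    n_reps = dplyr::n(), .groups = "drop")
}

#' Exact binomial confidence band for a rejection rate
#'
#' The band within which an empirical rejection rate is consistent with
#' a true rate `p0` at the given confidence, for `n_reps` replicates.
#'
#' @param n_reps Number of replicates.
#' @param p0 True rejection probability (default nominal 0.05).
#' @param conf Confidence level (default 0.99).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
binomial_band <- function(n_reps, p0 = 0.05, conf = 0.99) {
  a <- (1 - conf) / 2
  c(lower = stats::qbinom(a, n_reps, p0) / n_reps,
    upper = stats::qbinom(1 - a, n_reps, p0) / n_reps)
}

#' Empirical power across effect sizes
#'
#' Runs [simulate_pvalues()] at each value of `gamma` (re-calibrating
#' the censoring rate per effect size, since the latent-time
#' distribution changes with `gamma`) and summarises rejection rates.
#'
#' @inheritParams simulate_pvalues
#' @param setting Simulation setting 1-4 (see [effect_config()]).
#' @param gammas Numeric vector of effect sizes.
#' @param cluster `"abundant"` or `"rare"` for settings 1 and 3.
#' @param clusters Optional precomputed [cluster_otus()] partition.
#' @param alpha Significance level.
#' @param ... Further arguments to [effect_config()].
#' @return A tibble with columns `gamma`, `kernel`, `power`, `n_reps`,
#'   of class `mks_power`.
#' @export
power_curve <- function(spec, setting, gammas, n, n_reps,
                        kernels = c("wu", "uu", "gu:0.5", "bc"),
                        cluster = "abundant", clusters = NULL,
                        seed = 1, alpha = 0.05, ...) {
  if (setting %in% c(1, 3) && is.null(clusters))
    clusters <- cluster_otus(spec$tree, k = 20,
                             proportions = spec$proportions)
  seeds <- derive_seeds(seed, length(gammas))
  out <- lapply(seq_along(gammas), function(i) {
    cfg <- effect_config(spec, setting = setting, gamma = gammas[i],
                         clusters = clusters, cluster = cluster, ...)
    pv <- simulate_pvalues(spec, cfg, n = n, n_reps = n_reps,
                           kernels = kernels, seed = seeds[i])
    rr <- rejection_rates(pv, alpha = alpha)
    tibble::tibble(gamma = gammas[i], kernel = rr$kernel,
                   power = rr$p_value, n_reps = rr$n_reps)
  })
  structure(dplyr::bind_rows(out),
            class = c("mks_power", class(tibble::tibble())))
}

#' Plot empirical power curves
#'
#' @param object A [power_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mks_power
#' @export
autoplot.mks_power <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$gamma, y = .data$power,
                               colour = .data$kernel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::labs(x = expression(gamma), y = "empirical power",
                  colour = "kernel") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
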