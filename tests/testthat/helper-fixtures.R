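## Small shared fixtures; heavy objects are cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_spec <- function() cached("small_spec", community_spec(q = 50, seed = 11))

small_sim <- function() cached("small_sim", {
  spec <- small_spec()
  cfg <- effect_config(spec, setting = 2, gamma = 0)
  simulate_survival_data(spec, cfg, n = 40, seed = 4)
})

## a toy fitted null model on data with ties
toy_fit <- function() cached("toy_fit", {
  set.seed(42)
  n <- 40
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  tt <- round(rexp(n, exp(0.4 * X[, 1])), 1) + 0.1
  ev <- rbinom(n, 1, 0.7)
  list(time = tt, event = ev, X = X,
       fit = fit_null_cox(tt, ev, X))
})

## Efron log partial likelihood as a function of the linear predictor,
## written independently of the package internals (test oracle)
efron_loglik_eta <- function(time, event, eta) {
  s <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t0)
    R <- which(time >= t0)
    d <- length(D)
    r <- sum(exp(eta[R])); sd_ <- sum(exp(eta[D]))
    s <- s + sum(eta[D]) - sum(log(r - (seq_len(d) - 1) / d * sd_))
  }
  s
}
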