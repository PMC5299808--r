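#' Specify a synthetic microbial community
#'
#' Builds the population-level description of a synthetic 16S community:
#' a random rooted bifurcating phylogeny over `q` OTUs with exponential
#' branch lengths, a heavy-tailed mean composition (a log-normal
#' rank-abundance spectrum renormalised to sum to one), and a single
#' Dirichlet-multinomial overdispersion parameter. This emulates the
#' sparse, high-dimensional profiles typical of real surveys, where
#' hundreds of OTUs are observed and many are present in only a subset
#' of samples.
#'
#' @param q Number of OTUs (tree tips). Default 856.
#' @param seed Integer seed; the spec is deterministic given `(q, seed)`.
#' @param total_reads Sequencing depth per sample. Default 1000.
#' @param theta Dirichlet-multinomial overdispersion, in (0, 1).
#'   Default 0.02.
#' @param sdlog Standard deviation (log scale) of the log-normal
#'   abundance spectrum. Default 1.5.
#'
#' @return An object of class `community_spec`: a list with elements
#'   `q`, `tree` (class `phylo`, tips named `otu1..otuq`), `proportions`
#'   (named, sums to 1), `theta`, `total_reads`.
#'
#' @examples
#' spec <- community_spec(q = 50, seed = 1)
#' sum(spec$proportions)
#' @export
community_spec <- function(q = 856, seed = 1, total_reads = 1000,
                           theta = 0.02, sdlog = 1.5) {
  if (!is.numeric(q) || length(q) != 1 || q < 3)
    stop("`q` must be a single integer >= 3")
  q <- as.integer(q)
  stopifnot(theta > 0, theta < 1, total_reads >= 1)
  set.seed(seed)
  tree <- ape::rtree(q, br = stats::rexp)
  tree$tip.label <- paste0("otu", seq_len(q))
  pi <- stats::rlnorm(q, meanlog = 0, sdlog = sdlog)
  pi <- pi / sum(pi)
  names(pi) <- tree$tip.label
  structure(
    list(q = q, tree = tree, proportions = pi, theta = theta,
         total_reads = as.integer(total_reads), seed = seed),
    class = "community_spec"
  )
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec>", x$q, "OTUs,", x$total_reads,
      "reads/sample, theta =", x$theta, "\n")
  cat("  top-10 OTU share:",
      round(100 * sum(sort(x$proportions, decreasing = TRUE)[1:10]), 1),
      "%\n")
  invisible(x)
}

#' Sample OTU count profiles from a Dirichlet-multinomial community
#'
#' Draws `n` samples of `spec$total_reads` reads each. Per-sample
#' compositions are Dirichlet with concentration
#' \eqn{\alpha_j = \pi_j (1 - \theta) / \theta}, so the marginal counts
#' have mean \eqn{N \pi_j} and variance
#' \eqn{N \pi_j (1 - \pi_j) (1 + (N - 1)\theta)}.
#'
#' @param spec A [community_spec()].
#' @param n Number of samples.
#' @param seed Integer seed.
#'
#' @return An `n x q` integer matrix; rows (samples `s1..sn`) sum to
#'   `spec$total_reads`, columns named by OTU.
#' @export
sample_counts <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "community_spec"), n >= 1)
  n <- as.integer(n)
  set.seed(seed)
  alpha <- spec$proportions * (1 - spec$theta) / spec$theta
  g <- matrix(rgamma(n * spec$q, shape = rep(alpha, each = n)),
              nrow = n, ncol = spec$q)
  p <- g / rowSums(g)
  counts <- t(vapply(seq_len(n),
                     function(i) rmultinom(1, spec$total_reads, p[i, ])[, 1],
                     integer(spec$q)))
  dimnames(counts) <- list(paste0("s", seq_len(n)), names(spec$proportions))
  counts
}

#' Partition OTUs into phylogenetic clusters
#'
#' Clusters the tips of a phylogeny by partitioning-around-medoids (PAM,
#' k-medoids) on the cophenetic (tip-to-tip path length) distance
#' matrix. When the mean composition is supplied, the expected fraction
#' of reads in each cluster is reported, which is how "abundant" and
#' "rare" clusters are chosen for the simulation settings.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param k Number of clusters (default 20); `2 <= k <=` number of tips.
#' @param proportions Optional named mean composition over the tips.
#'
#' @return An object of class `otu_clusters`: list with `labels`
#'   (integer vector in `1..k`, named by tip), `medoids` (tip labels),
#'   `k`, `objective` (sum of within-cluster distances to medoids), and
#'   `cluster_abundance` (per-cluster expected read fraction, or `NULL`).
#' @export
cluster_otus <- function(tree, k = 20, proportions = NULL) {
  if (inherits(tree, "community_spec")) {
    proportions <- tree$proportions
    tree <- tree$tree
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; cophenetic distances undefined")
  ntip <- length(tree$tip.label)
  if (k < 2 || k > ntip) stop("`k` must be in 2..number of tips")
  d <- ape::cophenetic.phylo(tree)
  if (k == ntip) {
    ## every tip is its own (zero-cost) medoid
    labels <- stats::setNames(seq_len(ntip), tree$tip.label)
    medoids <- tree$tip.label
  } else {
    fit <- cluster::pam(stats::as.dist(d), k = k, variant = "original")
    labels <- fit$clustering[tree$tip.label]
    medoids <- fit$medoids
  }
  ab <- NULL
  if (!is.null(proportions)) {
    ab <- as.numeric(tapply(proportions[names(labels)], labels, sum))
    ab <- ab / sum(ab)
  }
  structure(
    list(labels = labels, medoids = medoids, k = k,
         objective = .pam_objective(d, labels, medoids),
         cluster_abundance = ab),
    class = "otu_clusters"
  )
}

.pam_objective <- function(d, labels, medoids) {
  sum(vapply(seq_along(medoids),
             function(g) sum(d[medoids[g], names(labels)[labels == g]]),
             numeric(1)))
}

#' Simulate adjustment covariates
#'
#' One standard-normal and one Bernoulli(0.5) covariate, independent of
#' each other and of the taxonomic profiles.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return An `n x 2` matrix with columns `x1`, `x2`.
#' @export
simulate_covariates <- function(n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
}

#' Configure an association between the community and survival
#'
#' Encodes the four simulation settings that relate OTU profiles to
#' exponential survival times:
#' \describe{
#'   \item{1}{abundance (total counts) of one phylogenetic cluster;}
#'   \item{2}{mean-standardised counts of the ten most abundant OTUs;}
#'   \item{3}{presence/absence of each OTU in one phylogenetic cluster;}
#'   \item{4}{presence/absence of 40 randomly selected OTUs.}
#' }
#' For settings 1 and 3 the associated cluster is the one whose expected
#' read fraction is closest to 19.7\% (`cluster = "abundant"`) or 0.9\%
#' (`cluster = "rare"`).
#'
#' @param spec A [community_spec()].
#' @param setting Integer 1-4.
#' @param gamma Effect size of the community summary (0 = null).
#' @param clusters An [cluster_otus()] result; required for settings 1
#'   and 3.
#' @param cluster `"abundant"` or `"rare"` (settings 1 and 3).
#' @param beta Length-2 coefficients of the adjustment covariates.
#' @param lambda Exponential baseline scale (> 0).
#' @param target_censoring Intended censoring fraction (0.25 or 0.5).
#' @param n_random Number of random OTUs for setting 4.
#' @param seed Seed for the random OTU draw of setting 4.
#'
#' @return Object of class `effect_config` with the resolved `target_set`
#'   (integer OTU indices) and, once calibrated, the censoring rate `mu`.
#' @export
effect_config <- function(spec, setting, gamma = 0, clusters = NULL,
                          cluster = c("abundant", "rare"),
                          beta = c(0.5, 0.5), lambda = 1,
                          target_censoring = 0.25, n_random = 40,
                          seed = 1) {
  stopifnot(inherits(spec, "community_spec"),
            setting %in% 1:4, lambda > 0, length(beta) == 2,
            target_censoring > 0, target_censoring < 1)
  cluster <- match.arg(cluster)
  pi <- spec$proportions
  if (setting %in% c(1, 3)) {
    if (is.null(clusters))
      stop("settings 1 and 3 need `clusters` from cluster_otus()")
    target_frac <- if (cluster == "abundant") 0.197 else 0.009
    g <- which.min(abs(clusters$cluster_abundance - target_frac))
    target_set <- which(names(pi) %in%
                          names(clusters$labels)[clusters$labels == g])
  } else if (setting == 2) {
    target_set <- order(pi, decreasing = TRUE)[1:10]
  } else {
    set.seed(seed)
    target_set <- sort(sample.int(spec$q, n_random))
  }
  structure(
    list(setting = as.integer(setting), target_set = target_set,
         gamma = gamma, beta = beta, lambda = lambda,
         target_censoring = target_censoring, cluster = cluster,
         mu = NA_real_),
    class = "effect_config"
  )
}

#' Community summary entering the survival model
#'
#' For setting 1 (and the null form of all settings) the raw summary is
#' the total count over the target OTUs; setting 2 uses counts divided
#' by the per-OTU mean across samples before summing (so no single OTU
#' dominates); settings 3 and 4 use the number of target OTUs present.
#' The summary is standardised to have sample mean 0 and SD 1 exactly.
#'
#' @param counts Count matrix (samples x OTUs).
#' @param cfg An [effect_config()].
#' @return Numeric vector of standardised summaries, one per sample.
#' @export
community_summary <- function(counts, cfg) {
  A <- cfg$target_set
  s <- switch(as.character(cfg$setting),
    "1" = rowSums(counts[, A, drop = FALSE]),
    "2" = {
      zbar <- colMeans(counts[, A, drop = FALSE])
      if (any(zbar == 0))
        stop("setting 2: a target OTU has zero mean count across samples")
      rowSums(sweep(counts[, A, drop = FALSE], 2, zbar, "/"))
    },
    rowSums(counts[, A, drop = FALSE] > 0)
  )
  if (sd(s) == 0)
    stop("degenerate target set (setting ", cfg$setting,
         "): community summary has zero variance across samples")
  as.numeric(scale(s))
}

#' Simulate latent event times under a proportional-hazards model
#'
#' Draws \eqn{T_i = -\log(U_i) / (\lambda \exp(X_i'\beta + \gamma s_i))}
#' with \eqn{U_i \sim} Uniform(0, 1) and \eqn{s_i} the standardised
#' community summary of the configured setting. With `gamma = 0` all
#' settings reduce to the identical exponential null model and the
#' counts do not enter.
#'
#' @param counts Count matrix (samples x OTUs), row-aligned with `X`.
#' @param X Covariate matrix (`n x 2`).
#' @param cfg An [effect_config()].
#' @param seed Integer seed.
#' @return Positive numeric vector of latent event times, with the
#'   standardised summary attached as attribute `"summary"` (zero vector
#'   under the null).
#' @export
simulate_event_times <- function(counts, X, cfg, seed = 1) {
  stopifnot(inherits(cfg, "effect_config"), nrow(X) >= 1)
  if (!is.null(counts)) stopifnot(nrow(counts) == nrow(X))
  n <- nrow(X)
  s <- if (cfg$gamma == 0) rep(0, n) else community_summary(counts, cfg)
  lin <- drop(X %*% cfg$beta) + cfg$gamma * s
  set.seed(seed)
  tt <- -log(runif(n)) / (cfg$lambda * exp(lin))
  attr(tt, "summary") <- s
  tt
}

#' Calibrate the exponential censoring rate
#'
#' Given draws from the latent event-time distribution, finds the rate
#' `mu` of an independent Exp(mu) censoring time such that the expected
#' censored fraction \eqn{E[1 - e^{-\mu T}]} equals the target. The
#' expectation is computed exactly over the supplied Monte-Carlo sample,
#' and the root is bracketed and solved monotonically, so the realised
#' calibration error is dominated by the Monte-Carlo size (10,000 draws
#' keeps it well inside 0.02).
#'
#' @param latent Either a numeric vector of latent times or a function
#'   `f(m)` returning `m` draws.
#' @param target Target censoring fraction, in (0, 1).
#' @param n_cal Monte-Carlo size when `latent` is a factory function.
#' @return The calibrated rate `mu` (a single positive number).
#' @export
calibrate_censoring <- function(latent, target, n_cal = 10000) {
  stopifnot(target > 0, target < 1)
  tt <- if (is.function(latent)) latent(n_cal) else latent
  tt <- as.numeric(tt)
  if (!any(is.finite(tt) & tt > 0))
    stop("censoring calibration failed: no finite positive latent times")
  f <- function(mu) mean(1 - exp(-mu * tt)) - target
  upper <- 1 / stats::median(tt)
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, lower = 0, upper = upper, tol = 1e-10)$root
}

#' Apply independent exponential censoring
#'
#' @param latent Latent event times.
#' @param mu Censoring rate; `mu = 0` means no censoring (all events).
#' @param seed Integer seed.
#' @return A tibble with `time` (observed `min(T, C)`), `event`
#'   (1 if the event was observed), and the latent `t_true`, `c_true`.
#' @export
apply_censoring <- function(latent, mu, seed = 1) {
  stopifnot(mu >= 0)
  n <- length(latent)
  set.seed(seed)
  cc <- if (mu == 0) rep(Inf, n) else rexp(n, rate = mu)
  latent <- as.numeric(latent)  # drop any attached summary attribute
  tibble::tibble(
    time = pmin(latent, cc),
    event = as.integer(latent <= cc),
    t_true = as.numeric(latent),
    c_true = cc
  )
}

#' Simulate a complete survival dataset from a community specification
#'
#' Convenience wrapper: samples counts, covariates, and censored
#' survival times under an [effect_config()]. If `cfg$mu` has not been
#' calibrated yet, it is calibrated here from a fresh Monte-Carlo sample
#' of latent times and stored in the returned config.
#'
#' @param spec A [community_spec()].
#' @param cfg An [effect_config()].
#' @param n Sample size.
#' @param seed Integer seed (all sub-draws derive from it).
#' @param n_cal Monte-Carlo size for censoring calibration.
#' @return A list of class `mks_sim` with `counts`, `data` (tibble:
#'   `sample_id`, `time`, `event`, `x1`, `x2`), `latent`, `cfg` (with
#'   `mu` filled in), and `spec`.
#' @export
simulate_survival_data <- function(spec, cfg, n, seed = 1, n_cal = 10000) {
  stopifnot(inherits(spec, "community_spec"), inherits(cfg, "effect_config"))
  seeds <- derive_seeds(seed, 5)
  counts <- sample_counts(spec, n, seed = seeds[1])
  X <- simulate_covariates(n, seed = seeds[2])
  if (is.na(cfg$mu)) {
    cfg$mu <- calibrate_censoring(
      latent_time_factory(spec, cfg, seed = seeds[5]),
      cfg$target_censoring, n_cal = n_cal)
  }
  tt <- simulate_event_times(counts, X, cfg, seed = seeds[3])
  obs <- apply_censoring(tt, cfg$mu, seed = seeds[4])
  data <- tibble::tibble(sample_id = rownames(counts),
                         time = obs$time, event = obs$event,
                         x1 = X[, 1], x2 = X[, 2])
  structure(list(counts = counts, data = data,
                 latent = obs[c("t_true", "c_true")],
                 cfg = cfg, spec = spec),
            class = "mks_sim")
}

#' Factory of latent event-time draws for calibration
#'
#' Returns a function `f(m)` that simulates `m` independent latent event
#' times under the configured setting. Under the null (`gamma = 0`) the
#' counts never enter and only covariates are drawn; otherwise a fresh
#' community sample of size `m` is generated.
#'
#' @inheritParams simulate_survival_data
#' @return A function of one argument `m`.
#' @export
latent_time_factory <- function(spec, cfg, seed = 1) {
  force(spec); force(cfg)
  seeds <- derive_seeds(seed, 3)
  function(m) {
    counts <- if (cfg$gamma == 0) NULL else
      sample_counts(spec, m, seed = seeds[1])
    X <- simulate_covariates(m, seed = seeds[2])
    as.numeric(simulate_event_times(counts, X, cfg, seed = seeds[3]))
  }
}

#' Derive a stream of sub-seeds from a master seed
#'
#' @param seed Master integer seed.
#' @param k Number of sub-seeds.
#' @return Integer vector of length `k`, each below 2^31.
#' @export
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}
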