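test_that("community spec satisfies its invariants and is deterministic", {
  spec <- small_spec()
  expect_s3_class(spec$tree, "phylo")
  expect_equal(length(spec$tree$tip.label), 50)
  expect_equal(sum(spec$proportions), 1, tolerance = 1e-12)
  expect_true(all(spec$proportions >= 0))
  expect_true(spec$theta > 0 && spec$theta < 1)
  expect_true(all(spec$tree$edge.length >= 0))

  again <- community_spec(q = 50, seed = 11)
  expect_identical(spec$proportions, again$proportions)
  expect_identical(spec$tree$edge, again$tree$edge)

  tiny <- community_spec(q = 3, seed = 7)
  expect_equal(nrow(tiny$tree$edge), 4)  # rooted bifurcating 3-tip tree
  expect_length(tiny$proportions, 3)
  expect_error(community_spec(q = 2), "q")
})

test_that("count rows always sum to the sequencing depth", {
  counts <- sample_counts(small_spec(), n = 30, seed = 2)
  expect_true(all(rowSums(counts) == 1000))
  expect_true(all(counts >= 0))
  expect_identical(counts, sample_counts(small_spec(), n = 30, seed = 2))
})

test_that("Dirichlet-multinomial moments match closed forms", {
  # theta -> 0: column means converge to the multinomial expectation
  spec0 <- community_spec(q = 20, seed = 3, theta = 1e-6,
                          total_reads = 1000)
  cc <- sample_counts(spec0, n = 5000, seed = 5)
  mu <- 1000 * spec0$proportions
  se <- sqrt(1000 * spec0$proportions * (1 - spec0$proportions) / 5000)
  big <- spec0$proportions > 0.01
  expect_true(all(abs(colMeans(cc)[big] - mu[big]) < 4 * se[big]))

  # theta = 0.1: variance inflated by 1 + (N-1)*theta over multinomial
  spec1 <- community_spec(q = 20, seed = 3, theta = 0.1,
                          total_reads = 1000)
  c1 <- sample_counts(spec1, n = 5000, seed = 6)
  pi <- spec1$proportions
  v_dm <- 1000 * pi * (1 - pi) * (1 + 999 * 0.1)
  v_mult <- 1000 * pi * (1 - pi)
  emp <- apply(c1, 2, var)
  big <- pi > 0.02
  expect_true(all(emp[big] > v_mult[big]))                     # inflation
  expect_true(all(abs(emp[big] / v_dm[big] - 1) < 0.15))       # closed form
})

test_that("PAM clustering recovers separated subtrees and the exact optimum", {
  # two 3-tip subtrees joined by a long internal branch
  tr <- ape::read.tree(text = paste0(
    "((a:1,(b:1,c:1):1):10,(d:1,(e:1,f:1):1):10);"))
  cl <- cluster_otus(tr, k = 2)
  expect_equal(length(unique(cl$labels[c("a", "b", "c")])), 1)
  expect_equal(length(unique(cl$labels[c("d", "e", "f")])), 1)
  expect_false(cl$labels["a"] == cl$labels["d"])

  # k = number of tips: singletons, zero objective
  cl6 <- cluster_otus(tr, k = 6)
  expect_equal(sort(unique(cl6$labels)), 1:6)
  expect_equal(cl6$objective, 0)

  # exhaustive-search oracle on a small random tree
  set.seed(8)
  tr2 <- ape::rtree(12)
  d <- ape::cophenetic.phylo(tr2)
  cl2 <- cluster_otus(tr2, k = 3)
  combs <- utils::combn(rownames(d), 3)
  best <- min(apply(combs, 2, function(med)
    sum(apply(d[med, , drop = FALSE], 2, min))))
  expect_equal(cl2$objective, best, tolerance = 1e-12)

  expect_error(cluster_otus(ape::rtree(5), k = 6), "k")
  tr_nb <- ape::rtree(5); tr_nb$edge.length <- NULL
  expect_error(cluster_otus(tr_nb, k = 2), "branch length")
})

test_that("covariates have the stated marginals and are reproducible", {
  X <- simulate_covariates(5000, seed = 9)
  expect_true(all(X[, 2] %in% c(0, 1)))
  expect_lt(abs(mean(X[, 1])), 3 / sqrt(5000))
  expect_lt(abs(mean(X[, 2]) - 0.5), 3 * 0.5 / sqrt(5000))
  expect_identical(X, simulate_covariates(5000, seed = 9))
})

test_that("null event times are exponential and setting-independent", {
  spec <- small_spec()
  cl <- cluster_otus(spec$tree, k = 5, proportions = spec$proportions)
  X <- matrix(0, 5000, 2)
  cfg <- effect_config(spec, setting = 1, gamma = 0, clusters = cl,
                       beta = c(0, 0), lambda = 2)
  tt <- simulate_event_times(NULL, X, cfg, seed = 10)
  expect_gt(stats::ks.test(tt, stats::pexp, rate = 2)$p.value, 0.001)

  # gamma = 0 makes all settings draw the identical stream
  counts <- sample_counts(spec, 50, seed = 1)
  Xs <- simulate_covariates(50, seed = 2)
  tts <- lapply(c(1, 3, 4), function(st) {
    cfg_s <- effect_config(spec, setting = st, gamma = 0, clusters = cl)
    simulate_event_times(counts, Xs, cfg_s, seed = 3)
  })
  expect_equal(as.numeric(tts[[1]]), as.numeric(tts[[2]]))
  expect_equal(as.numeric(tts[[1]]), as.numeric(tts[[3]]))
})

test_that("the community summary is standardised exactly", {
  spec <- small_spec()
  counts <- sample_counts(spec, 40, seed = 1)
  for (st in c(1, 2, 3)) {
    cfg <- effect_config(spec, setting = st, gamma = 1,
                         clusters = cluster_otus(spec$tree, k = 5,
                           proportions = spec$proportions))
    s <- community_summary(counts, cfg)
    expect_equal(mean(s), 0, tolerance = 1e-12)
    expect_equal(sd(s), 1, tolerance = 1e-12)
  }
})

test_that("a degenerate target set raises an informative error", {
  spec <- small_spec()
  counts <- sample_counts(spec, 20, seed = 1)
  cfg <- effect_config(spec, setting = 3, gamma = 1, seed = 2,
                       clusters = cluster_otus(spec$tree, k = 5,
                         proportions = spec$proportions))
  # force a summary with zero variance: every target OTU present everywhere
  counts[, cfg$target_set] <- 5
  expect_error(community_summary(counts, cfg), "zero variance")
})

test_that("censoring calibration hits its target", {
  # mu = 0: no censoring at all
  obs <- apply_censoring(rexp(50, 1), mu = 0, seed = 1)
  expect_true(all(obs$event == 1))
  expect_true(all(obs$time == obs$t_true))

  # closed form: T ~ Exp(1), target 0.25 -> mu = 1/3
  set.seed(2)
  tt <- rexp(2e5, 1)
  mu <- calibrate_censoring(tt, target = 0.25)
  expect_lt(abs(mu - 1 / 3), 0.01)

  # iid Exp(lambda) pair: mu = lambda gives 50% censoring
  mu2 <- calibrate_censoring(rexp(2e5, 3), target = 0.5)
  expect_lt(abs(mu2 - 3), 0.1)

  # realized censoring within 0.02 of target, averaged over replicates
  spec <- small_spec()
  cfg <- effect_config(spec, setting = 2, gamma = 0)
  fac <- latent_time_factory(spec, cfg, seed = 3)
  mu3 <- calibrate_censoring(fac, target = 0.25)
  set.seed(4)
  frac <- mean(vapply(1:100, function(i) {
    tt_i <- fac(200)
    mean(rexp(200, mu3) < tt_i)
  }, 1))
  expect_lte(abs(frac - 0.25), 0.02)

  expect_error(calibrate_censoring(rep(Inf, 10), 0.25), "calibration")
})

test_that("simulate_survival_data assembles a consistent dataset", {
  sim <- small_sim()
  expect_true(all(sim$data$time ==
                    pmin(sim$latent$t_true, sim$latent$c_true)))
  expect_identical(sim$data$event,
                   as.integer(sim$latent$t_true <= sim$latent$c_true))
  expect_true(all(sim$data$time > 0))
  expect_equal(sim$data$sample_id, rownames(sim$counts))
  expect_false(is.na(sim$cfg$mu))
})
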