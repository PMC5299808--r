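test_that("branch profiles accumulate tip fractions up the tree", {
  set.seed(21)
  tr <- ape::rtree(10)
  tr$tip.label <- paste0("otu", 1:10)
  counts <- matrix(rpois(4 * 10, 4), 4, 10,
                   dimnames = list(paste0("s", 1:4), tr$tip.label))
  counts[counts == 0] <- 1  # keep all rows positive
  prof <- branch_profile(tr, counts)

  # brute-force per-branch oracle: sum of descendant tips' fractions
  rel <- counts / rowSums(counts)
  desc_tips <- function(node) {
    if (node <= 10) return(node)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  for (e in seq_len(nrow(tr$edge))) {
    tips <- tr$tip.label[desc_tips(tr$edge[e, 2])]
    expect_equal(prof$p[, e], rowSums(rel[, tips, drop = FALSE]),
                 tolerance = 1e-12)
  }

  # branches leaving the root carry everything: fractions sum to 1
  root <- 11
  root_edges <- which(tr$edge[, 1] == root)
  expect_equal(unname(rowSums(prof$p[, root_edges])), rep(1, 4),
               tolerance = 1e-12)

  # one concentrated sample: profile is the 0/1 root-path indicator
  conc <- matrix(0, 1, 10, dimnames = list("z", tr$tip.label))
  conc[1, "otu3"] <- 7
  pc <- branch_profile(tr, conc)$p[1, ]
  expect_true(all(pc %in% c(0, 1)))
  tip3 <- which(tr$tip.label == "otu3")
  expect_equal(sum(pc), length(ape::nodepath(tr, root, tip3)) - 1)

  bad <- counts; colnames(bad)[1] <- "missing_otu"
  expect_error(branch_profile(tr, bad), "missing_otu")
})

test_that("UniFrac distances satisfy their boundary cases", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  counts <- rbind(A = c(a = 10, b = 0, c = 0),
                  B = c(a = 0, b = 10, c = 0),
                  A2 = c(a = 10, b = 0, c = 0),
                  C = c(a = 0, b = 0, c = 10))
  prof <- branch_profile(tr, counts)

  for (v in list(c("unweighted", NA), c("generalized", 0.5),
                 c("generalized", 1))) {
    d <- unifrac_distance(prof, v[1], alpha = as.numeric(v[2]))
    expect_equal(max(abs(d - t(d))), 0)
    expect_equal(unname(diag(d)), rep(0, 4))
    expect_equal(d["A", "A2"], 0)          # identical profiles
    expect_equal(d["A", "C"], 1)           # disjoint root subtrees
    expect_true(all(d >= 0 & d <= 1 + 1e-10))
  }

  # hand-evaluated generalized(alpha = 1) for A vs B:
  # branches: a (l=1, |1-0|), b (l=1, |0-1|), ab-internal (l=1, p=1 both),
  # c (l=1, p=0) -> num = 2, den = 1 + 1 + 2 = 4
  d1 <- unifrac_distance(prof, "generalized", alpha = 1)
  expect_equal(d1["A", "B"], 0.5)

  # alpha = 1 equals the weighted formula computed directly
  set.seed(3)
  tr2 <- ape::rtree(8); tr2$tip.label <- paste0("otu", 1:8)
  cc <- matrix(rpois(6 * 8, 3) + 1, 6, 8,
               dimnames = list(paste0("s", 1:6), tr2$tip.label))
  pr2 <- branch_profile(tr2, cc)
  dw <- unifrac_distance(pr2, "weighted")
  l <- pr2$edge_length
  manual <- sum(l * abs(pr2$p[1, ] - pr2$p[2, ])) /
    sum(l * (pr2$p[1, ] + pr2$p[2, ]))
  expect_equal(dw[1, 2], manual, tolerance = 1e-12)
  expect_equal(dw, unifrac_distance(pr2, "generalized", alpha = 1))

  # continuity in alpha near 1
  d99 <- unifrac_distance(pr2, "generalized", alpha = 0.99)
  expect_lt(max(abs(d99 - dw)), 0.02)
})

test_that("unweighted UniFrac agrees with picante", {
  skip_if_not_installed("picante")
  set.seed(13)
  tr <- ape::rtree(15); tr$tip.label <- paste0("otu", 1:15)
  cc <- matrix(rbinom(8 * 15, 10, 0.3), 8, 15,
               dimnames = list(paste0("s", 1:8), tr$tip.label))
  cc[rowSums(cc) == 0, 1] <- 1
  ours <- unifrac_distance(branch_profile(tr, cc), "unweighted")
  ref <- as.matrix(picante::unifrac(cc, tr))
  expect_equal(ours[rownames(ref), colnames(ref)], ref,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Bray-Curtis matches the direct formula", {
  expect_equal(bray_curtis_distance(rbind(A = c(2, 1, 0),
                                          B = c(0, 1, 3)))["A", "B"], 5 / 7)
  m <- rbind(A = c(3, 2, 0), B = c(3, 2, 0), C = c(0, 0, 9))
  d <- bray_curtis_distance(m)
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 1)  # disjoint support
  # double-sum oracle
  set.seed(4)
  z <- matrix(rpois(12, 5), 3, 4)
  dz <- bray_curtis_distance(z)
  expect_equal(dz[1, 2], sum(abs(z[1, ] - z[2, ])) / sum(z[1, ] + z[2, ]))
  # equal-depth counts and proportions coincide
  eq <- rbind(a = c(600, 300, 100), b = c(100, 800, 100))
  expect_equal(bray_curtis_distance(eq), bray_curtis_distance(eq / 1000),
               ignore_attr = TRUE)
  expect_error(bray_curtis_distance(rbind(c(1, 2), c(0, 0))), "zero")
})

test_that("the Gower transform produces centered PSD kernels", {
  expect_equal(kernel_from_distance(matrix(0, 3, 3)), matrix(0, 3, 3),
               ignore_attr = TRUE)

  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  expect_equal(kernel_from_distance(d2),
               0.6^2 / 4 * matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)

  # Gower duality: Euclidean distances give the centered Gram matrix
  set.seed(5)
  z <- matrix(rnorm(24), 6, 4)
  d <- as.matrix(dist(z))
  k <- kernel_from_distance(d)
  zc <- scale(z, center = TRUE, scale = FALSE)
  expect_equal(k, zc %*% t(zc), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(attr(k, "clipped"), 0)

  # double centering: rows sum to zero; PSD after clipping
  cc <- sample_counts(small_spec(), 12, seed = 6)
  db <- bray_curtis_distance(cc)
  kb <- kernel_from_distance(db)
  expect_lt(max(abs(rowSums(kb))), 1e-6 * norm(kb, "F"))
  ev <- eigen(kb, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))

  # a provably non-Euclidean metric (unit star K_{1,3}) must be clipped
  dstar <- matrix(2, 4, 4) - diag(2, 4)
  dstar[1, ] <- dstar[, 1] <- 1; dstar[1, 1] <- 0
  expect_gt(attr(kernel_from_distance(dstar), "clipped"), 0)

  expect_error(kernel_from_distance(matrix(0, 1, 1)), "two samples")
})

test_that("distances and kernels are permutation equivariant", {
  spec <- small_spec()
  cc <- sample_counts(spec, 10, seed = 7)
  prof <- branch_profile(spec$tree, cc)
  d <- unifrac_distance(prof, "generalized", alpha = 0.5)
  k <- kernel_from_distance(d)
  set.seed(8)
  pm <- sample(10)
  dp <- unifrac_distance(branch_profile(spec$tree, cc[pm, ]),
                         "generalized", alpha = 0.5)
  expect_equal(dp, d[pm, pm], tolerance = 1e-14, ignore_attr = TRUE)
  kp <- kernel_from_distance(dp)
  expect_equal(kp, k[pm, pm], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("build_kernels shares one profile pass and honours codes", {
  spec <- small_spec()
  cc <- sample_counts(spec, 8, seed = 9)
  K <- build_kernels(cc, spec$tree, c("wu", "uu", "gu:0.5", "bc"))
  expect_named(K, c("weighted_unifrac", "unweighted_unifrac",
                    "generalized_unifrac_0.5", "bray_curtis"))
  prof <- branch_profile(spec$tree, cc)
  expect_equal(K$generalized_unifrac_0.5,
               kernel_from_distance(
                 unifrac_distance(prof, "generalized", alpha = 0.5)),
               ignore_attr = TRUE)
  expect_equal(K$bray_curtis,
               kernel_from_distance(bray_curtis_distance(cc)),
               ignore_attr = TRUE)
  expect_error(build_kernels(cc, NULL, "wu"), "tree")
  expect_error(build_kernels(cc, spec$tree, "xx"), "unknown kernel")
})
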