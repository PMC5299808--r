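#' Per-branch abundance profile of samples on a phylogeny
#'
#' For every branch of the tree, computes the fraction of each sample's
#' reads carried by tips descending from that branch. This is the shared
#' internal representation of the UniFrac distance family: one postorder
#' pass accumulates the within-sample relative abundances of the tips up
#' the tree, so the profile of a parent branch is the sum of its
#' children's profiles.
#'
#' @param tree A rooted `phylo` tree with branch lengths over the OTUs.
#' @param counts Count matrix (samples x OTUs); every column name must
#'   be a tip label, and every row must contain at least one read.
#'
#' @return An object of class `branch_profile`: list with `p`
#'   (samples x branches matrix of descending read fractions, branches
#'   in `tree$edge` order), `edge_length`, and `tree`.
#' @export
branch_profile <- function(tree, counts) {
  stopifnot(inherits(tree, "phylo"), is.matrix(counts))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing) > 0)
    stop("OTUs not found on the tree: ", paste(missing, collapse = ", "))
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("samples with zero total reads: ",
         paste(rownames(counts)[rs <= 0], collapse = ", "))

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n <- nrow(counts)
  rel <- counts / rs

  ## node_frac[, v]: fraction of each sample's reads descending from node v
  node_frac <- matrix(0, nrow = n, ncol = ntip + nnode)
  idx <- match(tree$tip.label, colnames(counts))
  present <- !is.na(idx)
  node_frac[, which(present)] <- rel[, idx[present], drop = FALSE]

  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    node_frac[, parent] <- node_frac[, parent] + node_frac[, child]
  }
  p <- node_frac[, tree$edge[, 2], drop = FALSE]
  rownames(p) <- rownames(counts)
  structure(list(p = p, edge_length = tree$edge.length, tree = tree),
            class = "branch_profile")
}

#' UniFrac distances from a branch profile
#'
#' Computes the unweighted or generalized UniFrac distance between all
#' pairs of samples. With branch lengths \eqn{l_b} and branch read
#' fractions \eqn{p_b^A, p_b^B}:
#' \describe{
#'   \item{unweighted}{\eqn{d = \sum_b l_b |I(p_b^A>0) - I(p_b^B>0)| /
#'     \sum_b l_b I(p_b^A>0 \lor p_b^B>0)};}
#'   \item{generalized(\eqn{\alpha})}{\eqn{d = \sum_b l_b
#'     (p_b^A+p_b^B)^\alpha \frac{|p_b^A-p_b^B|}{p_b^A+p_b^B} /
#'     \sum_b l_b (p_b^A+p_b^B)^\alpha}, branches with
#'     \eqn{p_b^A+p_b^B=0} omitted.}
#' }
#' The weighted UniFrac distance is the generalized distance at
#' \eqn{\alpha = 1}.
#'
#' @param profile A [branch_profile()] (or a `phylo` tree, in which case
#'   `counts` must be supplied).
#' @param variant `"unweighted"`, `"generalized"`, or `"weighted"`
#'   (alias for generalized with `alpha = 1`).
#' @param alpha Exponent in `[0, 1]` for the generalized variant.
#' @param counts Count matrix, only if `profile` is a tree.
#'
#' @return A symmetric `n x n` distance matrix with zero diagonal and a
#'   `"metric"` attribute.
#' @export
unifrac_distance <- function(profile,
                             variant = c("unweighted", "generalized",
                                         "weighted"),
                             alpha = 0.5, counts = NULL) {
  variant <- match.arg(variant)
  if (inherits(profile, "phylo")) profile <- branch_profile(profile, counts)
  stopifnot(inherits(profile, "branch_profile"))
  if (variant == "weighted") { variant <- "generalized"; alpha <- 1 }
  if (variant == "generalized") stopifnot(alpha >= 0, alpha <= 1)

  p <- profile$p
  l <- profile$edge_length
  n <- nrow(p)
  if (n < 2) stop("need at least two samples")
  d <- .unifrac_pairs_multi(
    t(p), l,
    alphas = if (variant == "generalized") alpha else numeric(0),
    unweighted = variant == "unweighted")[[1]]
  dimnames(d) <- list(rownames(p), rownames(p))
  metric <- if (variant == "unweighted") "unifrac_unweighted"
            else sprintf("unifrac_generalized(%g)", alpha)
  attr(d, "metric") <- metric
  d
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{d(A,B) = \sum_j |Z_{Aj} - Z_{Bj}| / \sum_j (Z_{Aj} + Z_{Bj})} on
#' raw counts (with equal sequencing depth this coincides with the
#' proportion-based definition). Computed via [vegan::vegdist()].
#'
#' @param counts Count matrix (samples x OTUs) with positive row sums.
#' @return Symmetric distance matrix in `[0, 1]` with a `"metric"`
#'   attribute.
#' @export
bray_curtis_distance <- function(counts) {
  stopifnot(is.matrix(counts) || is.data.frame(counts))
  counts <- as.matrix(counts)
  if (any(rowSums(counts) <= 0))
    stop("undefined distance: sample(s) with zero total reads")
  d <- as.matrix(vegan::vegdist(counts, method = "bray"))
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Transform a distance matrix into a positive semi-definite kernel
#'
#' Applies the Gower double-centering transform
#' \eqn{K = -\frac12 (I - 11'/n) D^{(2)} (I - 11'/n)} (with \eqn{D^{(2)}}
#' the elementwise square), then eigendecomposes and replaces negative
#' eigenvalues by zero so the kernel is positive semi-definite. The
#' number of genuinely negative eigenvalues clipped (below
#' \eqn{-10^{-10}\lambda_{max}}) is recorded.
#'
#' @param d Symmetric distance matrix with zero diagonal (`n >= 2`).
#' @return A symmetric PSD kernel matrix with attributes `"clipped"`
#'   (count of negative eigenvalues set to zero) and `"metric"`
#'   (inherited from `d` when present).
#' @export
kernel_from_distance <- function(d) {
  stopifnot(is.matrix(d))
  n <- nrow(d)
  if (n < 2) stop("need at least two samples")
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix is not symmetric")
  a <- -0.5 * d^2
  k <- a - outer(rowMeans(a), colMeans(a), "+") + mean(a)
  k <- (k + t(k)) / 2
  eig <- eigen(k, symmetric = TRUE)
  lmax <- max(eig$values, 0)
  clipped <- sum(eig$values < -1e-10 * lmax)
  vals <- pmax(eig$values, 0)
  k <- eig$vectors %*% (vals * t(eig$vectors))
  k <- (k + t(k)) / 2
  dimnames(k) <- dimnames(d)
  attr(k, "clipped") <- clipped
  attr(k, "metric") <- attr(d, "metric")
  k
}

#' Build the kernels requested for a test
#'
#' Kernel specifications follow the short codes `"wu"` (weighted
#' UniFrac), `"uu"` (unweighted UniFrac), `"gu:<alpha>"` (generalized
#' UniFrac, e.g. `"gu:0.5"`), and `"bc"` (Bray-Curtis).
#'
#' @param counts Count matrix (samples x OTUs).
#' @param tree Rooted `phylo` tree; required for any UniFrac kernel.
#' @param kernels Character vector of kernel codes.
#' @return Named list of kernel matrices (see [kernel_from_distance()]).
#' @export
build_kernels <- function(counts, tree = NULL,
                          kernels = c("wu", "uu", "gu:0.5", "bc")) {
  specs <- lapply(kernels, parse_kernel_spec)
  names(specs) <- vapply(specs, `[[`, "", "name")
  fams <- vapply(specs, `[[`, "", "family")
  needs_tree <- any(fams != "bc")

  ## all UniFrac variants share one branch-profile pass
  dists <- vector("list", length(specs))
  if (needs_tree) {
    if (is.null(tree)) stop("a tree is required for UniFrac kernels")
    prof <- branch_profile(tree, counts)
    uf <- which(fams != "bc")
    alphas <- vapply(specs[uf], function(sp)
      switch(sp$family, wu = 1, gu = sp$alpha, uu = NA_real_), numeric(1))
    gen <- uf[!is.na(alphas)]
    dd <- .unifrac_pairs_multi(t(prof$p), prof$edge_length,
                               alphas = alphas[!is.na(alphas)],
                               unweighted = anyNA(alphas))
    dists[gen] <- dd[seq_along(gen)]
    if (anyNA(alphas)) dists[uf[is.na(alphas)]] <- dd[length(dd)]
    for (i in uf) {
      dimnames(dists[[i]]) <- list(rownames(prof$p), rownames(prof$p))
      attr(dists[[i]], "metric") <-
        if (is.na(alphas[match(i, uf)])) "unifrac_unweighted"
        else sprintf("unifrac_generalized(%g)", alphas[match(i, uf)])
    }
  }
  for (i in which(fams == "bc")) dists[[i]] <- bray_curtis_distance(counts)
  out <- lapply(dists, kernel_from_distance)
  names(out) <- names(specs)
  out
}

parse_kernel_spec <- function(code) {
  parts <- strsplit(code, ":", fixed = TRUE)[[1]]
  fam <- parts[1]
  if (!fam %in% c("wu", "uu", "gu", "bc"))
    stop("unknown kernel code: ", code,
         " (supported: wu, uu, gu:<alpha>, bc)")
  alpha <- if (fam == "gu") {
    if (length(parts) < 2) 0.5 else as.numeric(parts[2])
  } else NA_real_
  name <- switch(fam,
    wu = "weighted_unifrac", uu = "unweighted_unifrac",
    gu = sprintf("generalized_unifrac_%g", alpha), bc = "bray_curtis")
  list(family = fam, alpha = alpha, name = name, code = code)
}
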