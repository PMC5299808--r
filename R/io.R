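#' Align samples across the count matrix, metadata, and tree
#'
#' Inner-joins the metadata and count matrix on sample ids (when both
#' carry them), validates the outcome columns, extracts a numeric
#' covariate matrix, and drops OTUs that cannot be placed on the tree
#' (with a message reporting how many were excluded).
#'
#' @inheritParams kernel_surv_test
#' @return List with `counts`, `time`, `event`, `X` (or `NULL`), `tree`,
#'   and `ids`.
#' @export
align_samples <- function(data, counts, tree = NULL, time = "time",
                          event = "event", covariates = character(),
                          id_col = "sample_id") {
  data <- as.data.frame(data)
  for (col in c(time, event, covariates))
    if (!col %in% names(data)) stop("column not found in `data`: ", col)

  if (id_col %in% names(data) && !is.null(rownames(counts))) {
    ids <- intersect(data[[id_col]], rownames(counts))
    if (length(ids) == 0)
      stop("no overlapping sample ids between `data` and `counts`")
    dropped <- setdiff(union(data[[id_col]], rownames(counts)), ids)
    if (length(dropped) > 0)
      warning("dropping ", length(dropped),
              " sample(s) absent from one input: ",
              paste(utils::head(dropped, 5), collapse = ", "),
              if (length(dropped) > 5) ", ..." else "")
    data <- data[match(ids, data[[id_col]]), , drop = FALSE]
    counts <- counts[ids, , drop = FALSE]
  } else {
    if (nrow(data) != nrow(counts))
      stop("`data` and `counts` have different numbers of samples ",
           "and no sample ids to join on")
    ids <- if (!is.null(rownames(counts))) rownames(counts)
           else as.character(seq_len(nrow(counts)))
  }

  tvec <- data[[time]]
  evec <- data[[event]]
  if (!is.numeric(tvec) || any(!is.finite(tvec)) || any(tvec <= 0))
    stop("`", time, "` must be positive and finite")
  if (!all(evec %in% c(0, 1)))
    stop("`", event, "` must be coded 1 = event, 0 = censored")

  X <- NULL
  if (length(covariates) > 0) {
    X <- stats::model.matrix(
      stats::reformulate(covariates, intercept = FALSE), data = data)
    if (nrow(X) != nrow(data))
      stop("missing values in covariates")
  }

  if (!is.null(tree)) {
    on_tree <- colnames(counts) %in% tree$tip.label
    if (!any(on_tree)) stop("no OTUs of `counts` are tips of `tree`")
    if (any(!on_tree)) {
      message(sum(!on_tree),
              " OTU(s) not placed on the tree were excluded")
      counts <- counts[, on_tree, drop = FALSE]
    }
  }
  if (any(rowSums(counts) <= 0))
    stop("sample(s) with zero reads after OTU filtering")

  list(counts = counts, time = as.numeric(tvec),
       event = as.integer(evec), X = X, tree = tree, ids = ids)
}

#' Read an OTU count table
#'
#' Tab-separated, samples as rows: first column sample ids, header row
#' OTU ids. Use `transpose = TRUE` if the file stores OTUs as rows.
#'
#' @param path File path.
#' @param transpose Transpose after reading.
#' @return Integer matrix with sample row names and OTU column names.
#' @export
read_otu_table <- function(path, transpose = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "numeric"
  if (any(!is.finite(m)) || any(m < 0))
    stop("OTU table contains missing or negative entries")
  if (transpose) m <- t(m)
  m
}

#' Write an OTU count table (samples as rows)
#' @param counts Count matrix.
#' @param path File path.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (TSV with header)
#' @param path File path.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Write test results with a commented provenance header
#'
#' @param x An `mks_test` object (or its `tidy()` tibble).
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path, seed = NULL) {
  tab <- if (inherits(x, "mks_test")) tidy(x) else x
  hdr <- c(
    paste0("# mksurv results, package version ",
           as.character(utils::packageVersion("mksurv"))),
    if (inherits(x, "mks_test"))
      paste0("# n=", x$n, " events=", x$n_events, " adjust=", x$adjust),
    if (!is.null(seed)) paste0("# seed=", seed))
  out <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric),
                                          ~ signif(.x, 6)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path File path.
#' @return A tibble (header comments are skipped).
#' @export
read_results <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      check.names = FALSE))
}

#' Write a simulated dataset to disk
#'
#' Writes `<prefix>_counts.tsv` (samples as rows), `<prefix>_tree.nwk`,
#' and `<prefix>_metadata.tsv` (`sample_id`, `time`, `event`, `x1`,
#' `x2`).
#'
#' @param sim A [simulate_survival_data()] result.
#' @param prefix Output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "mks_sim"))
  files <- c(counts = paste0(prefix, "_counts.tsv"),
             tree = paste0(prefix, "_tree.nwk"),
             metadata = paste0(prefix, "_metadata.tsv"))
  write_otu_table(sim$counts, files["counts"])
  ape::write.tree(sim$spec$tree, files["tree"])
  utils::write.table(sim$data, files["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(files)
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' Validates branch lengths; unrooted trees are midpoint-rooted (UniFrac
#' values depend on the rooting, which is reported via a message).
#'
#' @param path Newick file path.
#' @return A rooted `phylo` object.
#' @export
read_phylo_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (!ape::is.rooted(tree)) {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("tree is unrooted and phangorn is unavailable for ",
           "midpoint rooting")
    message("unrooted tree: applying midpoint rooting")
    tree <- phangorn::midpoint(tree)
  }
  tree
}
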