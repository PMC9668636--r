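#' Connectivity matrix helpers
#'
#' Structural connectomes are symmetric node x node matrices with zero
#' diagonal: streamline counts, binary presence, or FA edge weights. These
#' helpers validate and construct them; node labels live in `dimnames`.
#'
#' @param entries square numeric matrix.
#' @param node_labels optional character vector of node names.
#' @param kind one of `"count"`, `"binary"`, `"fa"` (validation only).
#' @return The validated matrix with labels attached.
#' @export
connectivity_matrix <- function(entries, node_labels = NULL,
                                kind = c("count", "binary", "fa")) {
  kind <- match.arg(kind)
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) stop("connectivity matrix must be square")
  if (any(entries < 0)) stop("connectivity entries must be non-negative")
  if (any(diag(entries) != 0)) stop("connectivity diagonal must be zero")
  if (max(abs(entries - t(entries))) > 1e-12) stop("connectivity matrix must be symmetric")
  if (kind == "binary" && !all(entries %in% c(0, 1))) {
    stop("binary matrix entries must be 0 or 1")
  }
  if (kind == "fa" && any(entries > 1)) stop("FA entries must lie in [0, 1]")
  if (!is.null(node_labels)) {
    stopifnot(length(node_labels) == nrow(entries))
    dimnames(entries) <- list(node_labels, node_labels)
  }
  entries
}

#' Binarize a streamline-count matrix
#'
#' Two nodes are connected when at least one streamline links them: an entry
#' is 1 iff the count is >= 1.
#'
#' @param counts symmetric non-negative count matrix.
#' @return Binary matrix of the same shape, labels preserved.
#' @examples
#' m <- matrix(c(0, 3, 3, 0), 2, 2)
#' binarize(m)
#' @export
binarize <- function(counts) {
  counts <- connectivity_matrix(counts, kind = "count")
  (counts >= 1) * 1
}

#' Group connection-probability matrix
#'
#' Entrywise mean of the subjects' binary connectivity matrices: an entry of
#' 0.5 means the connection is detected in 50% of subjects of the group.
#'
#' @param binaries list of binary connectivity matrices on the same node set.
#' @return Probability matrix in \[0, 1\].
#' @export
group_probability <- function(binaries) {
  check_matrix_list(binaries)
  Reduce(`+`, binaries) / length(binaries)
}

#' Group-mean FA matrix
#'
#' Per edge, the mean FA over the subjects in which the edge was
#' reconstructed; absent edges are treated as missing, not as FA = 0, so an
#' edge present in two of five subjects with FA 0.4 and 0.6 averages 0.5.
#' Entries where no subject has the edge are 0.
#'
#' @param fa_matrices list of FA-weighted matrices (zero where absent).
#' @param binaries matching list of binary matrices.
#' @return Group FA matrix in \[0, 1\].
#' @export
group_fa <- function(fa_matrices, binaries) {
  check_matrix_list(fa_matrices)
  check_matrix_list(binaries)
  stopifnot(length(fa_matrices) == length(binaries))
  for (k in seq_along(fa_matrices)) {
    if (any(fa_matrices[[k]] > 1)) stop("FA entries must lie in [0, 1]")
    if (any(fa_matrices[[k]][binaries[[k]] == 0] != 0)) {
      stop("FA must be zero where the binary matrix is zero")
    }
  }
  total <- Reduce(`+`, fa_matrices)
  support <- Reduce(`+`, binaries)
  out <- total
  out[support > 0] <- total[support > 0] / support[support > 0]
  out
}

#' Group-level matrices for one cohort
#'
#' Convenience wrapper producing both the connection-probability matrix and
#' the group-mean FA matrix from a cohort tibble (see [generate_cohort()]).
#'
#' @param subjects tibble with list-columns `count_matrix` and `fa_matrix`.
#' @return List with `probability`, `group_fa`, `n_subjects`.
#' @export
group_matrices <- function(subjects) {
  stopifnot(nrow(subjects) >= 1)
  binaries <- lapply(subjects$count_matrix, binarize)
  list(
    probability = group_probability(binaries),
    group_fa = group_fa(subjects$fa_matrix, binaries),
    n_subjects = nrow(subjects)
  )
}

check_matrix_list <- function(ms) {
  stopifnot(is.list(ms), length(ms) >= 1)
  dims <- unique(lapply(ms, dim))
  if (length(dims) != 1) stop("matrices have mismatched dimensions")
  labs <- unique(lapply(ms, rownames))
  if (length(labs) != 1) stop("matrices have mismatched node labels")
  invisible(ms)
}

#' Read and write labelled connectivity matrices as TSV
#'
#' Matrices are stored with node labels in the header row and first column.
#'
#' @param m connectivity matrix with node labels.
#' @param path file path.
#' @return `read_connectivity_tsv()` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_connectivity_tsv <- function(m, path) {
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_connectivity_tsv
#' @export
read_connectivity_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
    check.names = FALSE
  ))
  connectivity_matrix(m, node_labels = rownames(m))
}
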