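#' Fixed-density thresholding of a group probability matrix
#'
#' Removes the most improbable connections within a site by retaining only
#' the K highest-probability edges, where
#' `K = floor(density * n_nodes * (n_nodes - 1) / 2)`; at the default 15%
#' density with 90 nodes, K = 600. Ties at the cutoff are broken
#' deterministically by lexicographic node-pair order, so equal densities are
#' achieved across all sites. If fewer than K edges have nonzero probability,
#' all nonzero edges are retained with a warning.
#'
#' @param probability group connection-probability matrix.
#' @param density target edge density in (0, 1\]; default 0.15.
#' @return An `edge_mask`: binary matrix with attribute `retained_count`.
#' @examples
#' p <- matrix(0, 4, 4)
#' p[1, 2] <- p[2, 1] <- 0.9
#' p[3, 4] <- p[4, 3] <- 0.2
#' density_threshold(p, density = 1 / 6)
#' @export
density_threshold <- function(probability, density = 0.15) {
  if (density <= 0 || density > 1) stop("`density` must lie in (0, 1]")
  probability <- connectivity_matrix(probability)
  n <- nrow(probability)
  k_target <- floor(density * n * (n - 1) / 2)
  ut <- which(upper.tri(probability), arr.ind = TRUE)
  # lexicographic (i, j) order within probability ties
  ord <- order(-probability[ut], ut[, 1], ut[, 2])
  nonzero <- sum(probability[ut] > 0)
  k <- as.integer(min(k_target, nonzero))
  if (k < k_target) {
    warning(sprintf(
      "only %d nonzero edges available; target density needs %d - retaining all nonzero",
      nonzero, k_target
    ))
  }
  mask <- matrix(0, n, n, dimnames = dimnames(probability))
  keep <- ut[ord[seq_len(k)], , drop = FALSE]
  mask[keep] <- 1
  mask[keep[, c(2, 1), drop = FALSE]] <- 1
  structure(mask,
    retained_count = k,
    class = c("edge_mask", "matrix", "array")
  )
}

#' Apply an edge mask to a connectivity matrix
#'
#' Zeroes every entry outside the mask; entries inside are preserved.
#'
#' @param m connectivity matrix.
#' @param mask an [density_threshold()] mask (or any binary matrix of the
#'   same shape).
#' @return Masked matrix.
#' @export
apply_mask <- function(m, mask) {
  m <- as.matrix(m)
  if (!identical(dim(m), dim(mask))) stop("matrix and mask shapes differ")
  m * unclass(mask)
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf(
    "<edge_mask> %d x %d, %d edges retained\n",
    nrow(x), ncol(x), attr(x, "retained_count")
  ))
  invisible(x)
}
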