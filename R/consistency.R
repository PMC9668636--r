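#' Cross-site consistency: relative difference between group matrices
#'
#' Consistency between two sites' group-level matrices (connection
#' probability or group FA) is quantified edgewise by the relative difference
#' in percent,
#' `100 * |a - b| / ((a + b) / 2)`,
#' evaluated wherever at least one of the two entries is nonzero (the union
#' support); lower values mean more consistent network architecture. The
#' statistic is symmetric in its arguments and bounded by 200% (attained when
#' an edge is present at one site only).
#'
#' @param a,b group-level matrices of equal shape and node labels
#'   (probability or FA), non-negative.
#' @return A `consistency_result`: list with `edgewise` (percent matrix, `NA`
#'   off support), `summary_mean` and `summary_max` (percent, over the union
#'   support), and `support_count`.
#' @examples
#' a <- matrix(c(0, 1, 1, 0), 2, 2)
#' b <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
#' relative_difference(a, b)$summary_mean # 66.67
#' @export
relative_difference <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("matrices must have the same shape")
  if (!identical(rownames(a), rownames(b))) stop("node labels must match")
  if (any(a < 0) || any(b < 0)) stop("entries must be non-negative")
  edgewise <- matrix(NA_real_, nrow(a), ncol(a), dimnames = dimnames(a))
  support <- (a + b) > 0
  diag(support) <- FALSE
  edgewise[support] <- 100 * abs(a - b)[support] / ((a + b)[support] / 2)
  ut <- upper.tri(edgewise)
  vals <- edgewise[ut & support]
  structure(
    list(
      edgewise = edgewise,
      summary_mean = if (length(vals)) mean(vals) else NA_real_,
      summary_max = if (length(vals)) max(vals) else NA_real_,
      support_count = length(vals)
    ),
    class = "consistency_result"
  )
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf(
    "<consistency_result> mean %.1f%%, max %.1f%% over %d edges\n",
    x$summary_mean, x$summary_max, x$support_count
  ))
  invisible(x)
}

#' @export
glance.consistency_result <- function(x, ...) {
  tibble::tibble(
    summary_mean = x$summary_mean,
    summary_max = x$summary_max,
    support_count = x$support_count
  )
}

#' @export
tidy.consistency_result <- function(x, ...) {
  ut <- which(upper.tri(x$edgewise) & !is.na(x$edgewise), arr.ind = TRUE)
  tibble::tibble(
    node_i = ut[, 1], node_j = ut[, 2],
    difference_pct = x$edgewise[ut]
  )
}
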