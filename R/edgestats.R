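#' Residualize edge values on age and sex
#'
#' Ordinary least-squares residuals of the values on intercept + age + sex,
#' fitted over all usable subjects with both groups pooled; the residuals
#' have mean zero. This is the covariate adjustment applied before the
#' group-label permutation test (Freedman-Lane simplification: residuals are
#' held fixed while labels are permuted).
#'
#' @param values numeric vector of per-subject edge values (e.g. FA).
#' @param age,sex covariate vectors of the same length.
#' @return Residual vector.
#' @export
residualize <- function(values, age, sex) {
  stopifnot(length(values) == length(age), length(values) == length(sex))
  if (length(values) < 3) stop("residualization needs at least 3 subjects")
  X <- cbind(1, age, sex)
  fit <- lm.fit(X, values)
  if (fit$rank < ncol(X)) stop("rank-deficient covariate design (constant age or sex)")
  unname(fit$residuals)
}

#' Pooled-variance two-sample t statistic and Cohen's d
#'
#' `edge_ttest()` returns the pooled two-sample t with sign
#' controls - patients (positive when patients' FA is reduced);
#' `cohens_d()` the standardized mean difference with the pooled-SD
#' denominator, so d = t * sqrt(1/n1 + 1/n2).
#'
#' @param values numeric vector (typically residualized edge FA).
#' @param groups factor/character with levels `"control"` and `"patient"`.
#' @return Single numeric; `NA` when a group has < 2 values or the pooled
#'   variance is zero (untestable edge).
#' @examples
#' edge_ttest(c(2, 4, 1, 3), rep(c("control", "patient"), each = 2)) # 0.7071
#' @export
edge_ttest <- function(values, groups) {
  st <- group_stats(values, groups)
  if (is.null(st)) return(NA_real_)
  st$md / sqrt(st$vp * (1 / st$n1 + 1 / st$n2))
}

#' @rdname edge_ttest
#' @export
cohens_d <- function(values, groups) {
  st <- group_stats(values, groups)
  if (is.null(st)) return(NA_real_)
  st$md / sqrt(st$vp)
}

group_stats <- function(values, groups) {
  is_c <- groups == "control"
  x <- values[is_c]
  y <- values[!is_c]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) return(NULL)
  vp <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  if (vp <= 0) return(NULL)
  list(md = mean(x) - mean(y), vp = vp, n1 = n1, n2 = n2)
}

#' Edgewise covariate-adjusted permutation statistics
#'
#' For every edge with at least `min_per_group` usable subjects per group
#' (subjects lacking the edge are excluded from that edge's test, not
#' treated as FA = 0), FA is residualized on age and sex over the usable
#' subjects, and the pooled two-sample t (controls - patients) and Cohen's d
#' are computed on the residuals. Group labels are then permuted uniformly
#' `n_perm` times (residuals fixed) and the empirical two-sided p-value is
#' `(1 + #\{|t_perm| >= |t_obs|\}) / (n_perm + 1)`; Benjamini-Hochberg
#' step-up across all tested edges gives `q_fdr`. With `exhaustive = TRUE`
#' all distinct assignments of the observed group sizes are enumerated
#' (identity included) and `p_perm` is the exact enumeration fraction.
#'
#' @param subjects cohort tibble with `fa_matrix` list-column and `age`,
#'   `sex`, `group` columns (see [generate_cohort()]).
#' @param n_perm number of permutations (>= 100; the full analysis default
#'   is 50,000, scaled-down runs commonly use 1,000).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all label assignments instead of sampling.
#' @param min_per_group minimum usable subjects per group for an edge to be
#'   tested.
#' @return An `edge_test_result` tibble: `node_i`, `node_j`, `n_control`,
#'   `n_patient`, `t`, `d`, `p_perm`, `q_fdr`, `testable`, ordered by edge.
#' @export
edge_stats <- function(subjects, n_perm = 1000, seed = 1L, exhaustive = FALSE,
                       min_per_group = 2) {
  if (!exhaustive && n_perm < 100) stop("`n_perm` must be at least 100")
  if (!all(c("control", "patient") %in% subjects$group)) {
    stop("both controls and patients are required")
  }
  n_sub <- nrow(subjects)
  n_nodes <- nrow(subjects$fa_matrix[[1]])
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  # subjects x edges value matrix, NA where the edge is absent
  V <- t(vapply(seq_len(n_sub), function(s) {
    fa <- subjects$fa_matrix[[s]][ut]
    present <- subjects$count_matrix[[s]][ut] > 0
    ifelse(present, fa, NA_real_)
  }, numeric(nrow(ut))))

  is_c <- subjects$group == "control"
  usable <- !is.na(V)
  n1 <- colSums(usable & is_c)
  n2 <- colSums(usable & !is_c)
  tested <- n1 >= min_per_group & n2 >= min_per_group

  # residualize per tested edge over its usable subjects; covariates that are
  # constant among an edge's usable subjects carry no information there and
  # are dropped from that edge's design
  R <- matrix(NA_real_, n_sub, ncol(V))
  for (e in which(tested)) {
    ok <- usable[, e]
    X <- cbind(1, subjects$age[ok], subjects$sex[ok])
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) > 1))
    R[ok, e] <- lm.fit(X[, keep, drop = FALSE], V[ok, e])$residuals
  }

  perm_labels <- if (exhaustive) {
    combs <- utils::combn(n_sub, sum(is_c))
    apply(combs, 2, function(ix) seq_len(n_sub) %in% ix)
  } else {
    withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(p) sample(is_c), logical(n_sub))
    })
  }

  t_obs <- perm_t_stats(R, matrix(is_c, ncol = 1))[, 1]
  zero_var <- tested & !is.finite(t_obs)
  tested <- tested & is.finite(t_obs)
  t_perm <- perm_t_stats(R[, tested, drop = FALSE], perm_labels)

  p <- rep(NA_real_, ncol(V))
  if (exhaustive) {
    p[tested] <- rowMeans(abs(t_perm) >= abs(t_obs[tested]) - 1e-12)
  } else {
    exceed <- rowSums(abs(t_perm) >= abs(t_obs[tested]) - 1e-12)
    p[tested] <- (1 + exceed) / (n_perm + 1)
  }
  q <- rep(NA_real_, ncol(V))
  q[tested] <- p.adjust(p[tested], method = "BH")

  d_obs <- t_obs * sqrt(1 / n1 + 1 / n2)
  observed <- n1 + n2 > 0
  res <- tibble::tibble(
    node_i = ut[, 1], node_j = ut[, 2],
    n_control = n1, n_patient = n2,
    t = ifelse(tested, t_obs, NA_real_),
    d = ifelse(tested, d_obs, NA_real_),
    p_perm = p, q_fdr = q,
    testable = tested
  )[observed, ]
  if (any(zero_var)) {
    warning(sprintf("%d edges with zero pooled variance flagged untestable", sum(zero_var)))
  }
  attr(res, "n_perm") <- if (exhaustive) ncol(perm_labels) else n_perm
  attr(res, "exhaustive") <- exhaustive
  attr(res, "node_labels") <- rownames(subjects$fa_matrix[[1]])
  class(res) <- c("edge_test_result", class(res))
  res
}

# t statistics for many permutations at once via masked group sums.
# R: subjects x edges residual matrix (NA = unusable); labels: subjects x
# n_perm logical (TRUE = control). Returns edges x n_perm.
perm_t_stats <- function(R, labels) {
  if (ncol(R) == 0) return(matrix(numeric(0), 0, ncol(labels)))
  M <- !is.na(R)
  X <- R
  X[!M] <- 0
  Q <- X^2
  Z <- matrix(as.numeric(labels), nrow(labels))
  n1 <- crossprod(M, Z)
  n2 <- colSums(M) - n1
  s1 <- crossprod(X, Z)
  s2 <- colSums(X) - s1
  q1 <- crossprod(Q, Z)
  q2 <- colSums(Q) - q1
  m1 <- s1 / n1
  m2 <- s2 / n2
  ss <- (q1 - n1 * m1^2) + (q2 - n2 * m2^2)
  vp <- ss / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(vp * (1 / n1 + 1 / n2))
  t[!is.finite(t)] <- NA_real_
  t
}

#' Staged detection sets with effect-size gating
#'
#' The three detection stages mirror the analysis ladder: edges with a large
#' effect (signed d > `d_threshold`, i.e. FA reduced in patients), those that
#' additionally survive the density-threshold mask, and those that further
#' survive FDR (q < `q_level`). The sets are nested by construction.
#'
#' @param results an `edge_test_result` from [edge_stats()].
#' @param mask an edge mask from [density_threshold()] (or `NULL` to skip
#'   masking, in which case the second stage equals the first).
#' @param d_threshold effect-size gate (default 0.8, the conventional "large
#'   effect" cut).
#' @param q_level FDR level (default 0.05).
#' @param absolute gate on |d| instead of signed d.
#' @return A `stage_detections` object: list of three edge tibbles
#'   `large_effect`, `surviving_threshold`, `surviving_fdr`.
#' @export
stage_detections <- function(results, mask = NULL, d_threshold = 0.8,
                             q_level = 0.05, absolute = FALSE) {
  stopifnot(inherits(results, "edge_test_result"))
  dv <- if (absolute) abs(results$d) else results$d
  large <- results$testable & !is.na(dv) & dv > d_threshold
  in_mask <- if (is.null(mask)) {
    rep(TRUE, nrow(results))
  } else {
    unclass(mask)[cbind(results$node_i, results$node_j)] > 0
  }
  thr <- large & in_mask
  fdr <- thr & !is.na(results$q_fdr) & results$q_fdr < q_level
  pick <- function(sel) results[sel, c("node_i", "node_j", "t", "d", "p_perm", "q_fdr")]
  structure(
    list(
      large_effect = pick(large),
      surviving_threshold = pick(thr),
      surviving_fdr = pick(fdr)
    ),
    class = "stage_detections"
  )
}

#' @export
print.stage_detections <- function(x, ...) {
  cat(sprintf(
    "<stage_detections> large effect: %d; survive thresholding: %d; survive thresholding + FDR: %d\n",
    nrow(x$large_effect), nrow(x$surviving_threshold), nrow(x$surviving_fdr)
  ))
  invisible(x)
}

#' @export
tidy.stage_detections <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$large_effect, stage = "large_effect"),
    dplyr::mutate(x$surviving_threshold, stage = "surviving_threshold"),
    dplyr::mutate(x$surviving_fdr, stage = "surviving_fdr")
  )
}

#' @export
glance.edge_test_result <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x),
    n_tested = sum(x$testable),
    n_perm = attr(x, "n_perm"),
    n_large_effect = sum(x$testable & x$d > 0.8, na.rm = TRUE),
    n_q_lt_05 = sum(x$q_fdr < 0.05, na.rm = TRUE)
  )
}
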