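# Shared fixtures built in code at test time.

# Memoised default-config experiment: several test files assert properties of
# the same run, so it is computed once per test session.
.experiment_cache <- new.env(parent = emptyenv())

get_default_experiment <- function() {
  if (is.null(.experiment_cache$ex)) {
    .experiment_cache$ex <- run_experiment(default_experiment_config(seed = 20260920))
  }
  .experiment_cache$ex
}

# Build a cohort tibble directly from a subjects x edges value matrix (all
# edges present in all subjects); edges fill the upper triangle of the
# smallest graph that holds them.
make_cohort <- function(values, groups, age = NULL, sex = NULL, site = "S1") {
  values <- as.matrix(values)
  n_sub <- nrow(values)
  n_edges <- ncol(values)
  n_nodes <- 2
  while (choose(n_nodes, 2) < n_edges) n_nodes <- n_nodes + 1
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  labels <- sprintf("node%02d", seq_len(n_nodes))
  # default covariates cycle with short periods so they stay balanced across
  # any contiguous group split (no accidental group confounding)
  if (is.null(age)) age <- 60 + ((seq_len(n_sub) - 1) * 7) %% 21
  if (is.null(sex)) sex <- rep_len(c(0L, 1L), n_sub)
  mk <- function(vals) {
    m <- matrix(0, n_nodes, n_nodes, dimnames = list(labels, labels))
    idx <- ut[seq_len(n_edges), , drop = FALSE]
    m[idx] <- vals
    m[idx[, c(2, 1), drop = FALSE]] <- vals
    m
  }
  tibble::tibble(
    subject_id = sprintf("%s_%02d", site, seq_len(n_sub)),
    site_id = site,
    group = groups,
    age = age,
    sex = sex,
    count_matrix = lapply(seq_len(n_sub), function(s) mk(rep(1, n_edges))),
    fa_matrix = lapply(seq_len(n_sub), function(s) mk(values[s, ]))
  )
}

# Small deterministic truth for generator tests.
tiny_truth <- function(n_nodes = 12, n_core = 20, prob = 1, fa = 0.45,
                       affected = logical(n_core), spurious_edge_rate = 0,
                       fa_subject_sd = 0, disease_delta = 0.05) {
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  core <- tibble::tibble(
    node_i = ut[seq_len(n_core), 1],
    node_j = ut[seq_len(n_core), 2],
    prob = rep_len(prob, n_core),
    fa_baseline = rep_len(fa, n_core),
    affected = affected
  )
  network_truth(n_nodes, core,
    spurious_edge_rate = spurious_edge_rate,
    fa_subject_sd = fa_subject_sd, disease_delta = disease_delta
  )
}

# Identity scale maps for n_voxels voxels.
unit_maps <- function(n_voxels, lmax = 6) {
  m <- matrix(1, n_voxels, lmax / 2 + 1)
  structure(m, class = c("scale_maps", "matrix", "array"))
}

# Pooled-t statistic from first principles (independent oracle).
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vp <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(vp * (1 / n1 + 1 / n2))
}
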