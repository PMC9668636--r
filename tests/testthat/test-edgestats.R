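test_that("residualization reduces to centering when covariates carry no signal", {
  withr::with_seed(7, {
    v <- rnorm(20)
    age <- rep(c(60, 70), 10) # orthogonal-by-construction checks below use lm
    sex <- rep_len(c(0, 1), 20)
  })
  # age and sex orthogonal to the values: fitted slopes zero -> centered values
  v_bal <- rep(c(1, 3), 10)
  r <- residualize(v_bal, age = rep(65, 20) + rep(c(-1, 1), each = 10), sex = sex)
  # independent oracle: normal-equations solve
  X <- cbind(1, rep(65, 20) + rep(c(-1, 1), each = 10), sex)
  oracle <- v_bal - X %*% solve(crossprod(X), crossprod(X, v_bal))
  expect_equal(r, as.numeric(oracle), tolerance = 1e-10)

  # perfect linear dependence on age -> zero residuals
  age2 <- seq(55, 85, length.out = 20)
  expect_lt(max(abs(residualize(0.01 * age2, age2, sex))), 1e-10)

  # random case matches the normal equations
  r2 <- residualize(v, age2, sex)
  X2 <- cbind(1, age2, sex)
  oracle2 <- v - X2 %*% solve(crossprod(X2), crossprod(X2, v))
  expect_equal(r2, as.numeric(oracle2), tolerance = 1e-10)
  expect_lt(abs(mean(r2)), 1e-12)

  expect_error(residualize(v[1:2], age2[1:2], sex[1:2]), "at least 3")
  expect_error(residualize(v, rep(70, 20), rep(1, 20)), "rank-deficient")
})

test_that("pooled t and Cohen's d match hand computation and stats::t.test", {
  vals <- c(2, 4, 1, 3)
  grp <- rep(c("control", "patient"), each = 2)
  expect_equal(edge_ttest(vals, grp), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(vals, grp), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(edge_ttest(c(1, 2, 1, 2), grp), 0)
  expect_equal(cohens_d(c(1, 2, 1, 2), grp), 0)

  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- rnorm(8)
      y <- rnorm(11) + 0.5
    })
    vals <- c(x, y)
    grp <- rep(c("control", "patient"), c(8, 11))
    t_pkg <- edge_ttest(vals, grp)
    t_ref <- stats::t.test(x, y, var.equal = TRUE)$statistic
    expect_equal(t_pkg, unname(t_ref), tolerance = 1e-10)
    # algebraic identity d = t * sqrt(1/n1 + 1/n2)
    expect_equal(cohens_d(vals, grp), t_pkg * sqrt(1 / 8 + 1 / 11), tolerance = 1e-12)
  }

  expect_true(is.na(edge_ttest(c(1, 1, 1, 1), rep(c("control", "patient"), each = 2))))
  expect_true(is.na(edge_ttest(c(1, 2, 3), c("control", "control", "patient"))))
})

test_that("exhaustive permutation p-values match full enumeration", {
  withr::with_seed(8, V <- matrix(rnorm(6 * 4), 6, 4) + outer(rep(c(1, 0), each = 3), c(2, 0, 0, 1)))
  groups <- rep(c("control", "patient"), each = 3)
  age <- c(60, 65, 70, 62, 68, 74)
  sex <- c(0, 1, 0, 1, 0, 1)
  cohort <- make_cohort(V, groups, age = age, sex = sex)
  res <- edge_stats(cohort, exhaustive = TRUE)

  X <- cbind(1, age, sex)
  H <- X %*% solve(crossprod(X), t(X))
  combs <- utils::combn(6, 3)
  for (e in 1:4) {
    r <- as.numeric((diag(6) - H) %*% V[, e])
    t_obs <- pooled_t_oracle(r[1:3], r[4:6])
    t_all <- apply(combs, 2, function(ix) pooled_t_oracle(r[ix], r[-ix]))
    p_oracle <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
    expect_equal(res$p_perm[e], p_oracle, tolerance = 1e-12)
    expect_equal(res$t[e], t_obs, tolerance = 1e-10)
  }
  expect_equal(attr(res, "n_perm"), choose(6, 3))
})

test_that("permutation p-values are calibrated and super-uniform under the null", {
  n_sub <- 40
  n_edges <- 990 # fills a 45-node upper triangle prefix
  withr::with_seed(9, V <- matrix(rnorm(n_sub * n_edges), n_sub, n_edges))
  groups <- rep(c("control", "patient"), each = n_sub / 2)
  cohort <- make_cohort(V, groups, age = withr::with_seed(10, rnorm(n_sub, 70, 8)))
  res <- edge_stats(cohort, n_perm = 1000, seed = 11)
  p <- res$p_perm[res$testable]
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
  # super-uniformity: empirical CDF does not exceed the uniform by more than
  # Monte-Carlo slack anywhere on a grid
  for (q in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p <= q), q + 3 * sqrt(q * (1 - q) / n_edges))
  }
})

test_that("a constant shift on all edges survives FDR at large n", {
  n_sub <- 60
  n_edges <- 45
  withr::with_seed(12, {
    V <- matrix(rnorm(n_sub * n_edges, sd = 0.5), n_sub, n_edges)
  })
  groups <- rep(c("control", "patient"), each = n_sub / 2)
  V[groups == "patient", ] <- V[groups == "patient", ] - 1.5
  cohort <- make_cohort(V, groups)
  res <- edge_stats(cohort, n_perm = 1000, seed = 13)
  expect_true(all(res$q_fdr[res$testable] < 0.05))
  expect_true(all(res$d[res$testable] > 0))
})

test_that("subjects lacking an edge are excluded from its test", {
  V <- rbind(
    c(0.5, 0.52), c(0.55, NA), c(0.52, 0.50), c(0.48, 0.51),
    c(0.40, 0.42), c(0.42, NA), c(0.41, 0.40), c(0.39, 0.43)
  )
  groups <- rep(c("control", "patient"), each = 4)
  cohort <- make_cohort(ifelse(is.na(V), 0, V), groups)
  # absent edges: zero the counts where V was NA
  for (s in which(rowSums(is.na(V)) > 0)) {
    m <- cohort$count_matrix[[s]]
    m[1, 3] <- m[3, 1] <- 0 # second edge of the triangle prefix
    cohort$count_matrix[[s]] <- m
  }
  res <- edge_stats(cohort, n_perm = 100, seed = 14)
  e2 <- res[res$node_i == 1 & res$node_j == 3, ]
  expect_equal(e2$n_control, 3)
  expect_equal(e2$n_patient, 3)
})

test_that("detection stages are nested and gated as specified", {
  ex <- get_default_experiment()
  for (det in ex$detections) {
    k_large <- nrow(det$large_effect)
    k_thr <- nrow(det$surviving_threshold)
    k_fdr <- nrow(det$surviving_fdr)
    expect_lte(k_thr, k_large)
    expect_lte(k_fdr, k_thr)
    keys <- function(e) paste(e$node_i, e$node_j)
    expect_true(all(keys(det$surviving_threshold) %in% keys(det$large_effect)))
    expect_true(all(keys(det$surviving_fdr) %in% keys(det$surviving_threshold)))
    expect_true(all(det$large_effect$d > 0.8))
  }

  res <- ex$edge_results$UT
  empty_mask <- matrix(0, ex$truth$n_nodes, ex$truth$n_nodes)
  det0 <- stage_detections(res, structure(empty_mask, class = c("edge_mask", "matrix", "array")))
  expect_equal(nrow(det0$surviving_threshold), 0)
  expect_equal(nrow(det0$surviving_fdr), 0)

  res_flat <- res
  res_flat$d <- pmin(res_flat$d, 0.5)
  det_flat <- stage_detections(res_flat, ex$masks$UT)
  expect_equal(nrow(det_flat$large_effect), 0)
  expect_equal(nrow(det_flat$surviving_fdr), 0)
})

test_that("site-confounded pooling inflates effect sizes; harmonization undoes it", {
  sch <- default_scheme(45)
  truth <- random_network_truth(
    n_nodes = 30, n_core = 80, n_affected = 8,
    spurious_edge_rate = 0, seed = 15, disease_delta = 0.03
  )
  hi <- site_spec("HI", 22, 6,
    sh_order_scales = c("0" = 1, "2" = 1.35, "4" = 1.05, "6" = 1),
    seed = 16
  )
  lo <- site_spec("LO", 6, 22,
    sh_order_scales = c("0" = 1.05, "2" = 0.65, "4" = 0.95, "6" = 1),
    seed = 17
  )
  coh_hi <- generate_cohort(hi, truth, sch)
  coh_lo <- generate_cohort(lo, truth, sch)
  d_site <- function(subjects) {
    res <- edge_stats(subjects, n_perm = 100, seed = 18)
    res$d[res$testable]
  }
  n_large <- function(d) sum(d > 0.8)
  d_hi <- d_site(coh_hi)
  d_lo <- d_site(coh_lo)
  pooled <- dplyr::bind_rows(coh_hi, coh_lo)
  d_raw <- d_site(pooled)
  # confounded pooling: controls mostly from the FA-raised scanner, patients
  # from the FA-lowered one -> spuriously large control-minus-patient effects
  expect_gt(n_large(d_raw), max(n_large(d_hi), n_large(d_lo)))

  f_hi <- lapply(
    generate_dwi_phantom(hi, 100, sch, seed = 19)$signals,
    function(s) compute_rish(fit_sh(s, sch))
  )
  f_lo <- lapply(
    generate_dwi_phantom(lo, 100, sch, seed = 19)$signals,
    function(s) compute_rish(fit_sh(s, sch))
  )
  coh_lo_h <- harmonize_cohort(coh_lo, compute_scale_maps(f_lo, f_hi), sch)
  pooled_h <- dplyr::bind_rows(coh_hi, coh_lo_h)
  d_harm <- d_site(pooled_h)
  expect_lte(n_large(d_harm), max(n_large(d_hi), n_large(d_lo)))
  expect_lt(mean(d_harm), mean(d_raw))
})
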