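test_that("degenerate generator reproduces the core edge set exactly", {
  truth <- tiny_truth(n_nodes = 12, n_core = 20, prob = 1)
  site <- site_spec("A", 4, 3, noise_sd = 0, seed = 2)
  cohort <- generate_cohort(site, truth, default_scheme(45))
  core <- matrix(0, 12, 12, dimnames = list(truth$node_labels, truth$node_labels))
  core[cbind(truth$core_edges$node_i, truth$core_edges$node_j)] <- 1
  core <- core + t(core)
  for (s in seq_len(nrow(cohort))) {
    expect_equal(binarize(cohort$count_matrix[[s]]), core)
  }
})

test_that("generated matrices are symmetric, zero-diagonal and reproducible", {
  truth <- random_network_truth(
    n_nodes = 20, n_core = 40, n_affected = 5,
    spurious_edge_rate = 5, seed = 3
  )
  site <- site_spec("A", 3, 3, seed = 4)
  c1 <- generate_cohort(site, truth, default_scheme(45))
  c2 <- generate_cohort(site, truth, default_scheme(45))
  expect_identical(c1$fa_matrix, c2$fa_matrix)
  expect_identical(c1$count_matrix, c2$count_matrix)
  for (s in seq_len(nrow(c1))) {
    m <- c1$count_matrix[[s]]
    fa <- c1$fa_matrix[[s]]
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(fa >= 0 & fa <= 1))
    expect_true(all(fa[m == 0] == 0)) # FA zero exactly where no connection
  }
  expect_true(all(c1$age >= 50 & c1$age <= 90))
})

test_that("per-edge detection frequencies are binomially consistent", {
  truth <- random_network_truth(
    n_nodes = 90, n_core = 600, n_affected = 10,
    prob_range = c(0.9, 0.9), spurious_edge_rate = 0, seed = 5
  )
  site <- site_spec("A", 50, 0, noise_sd = 0, seed = 6)
  cohort <- generate_cohort(site, truth, default_scheme(45))
  prob <- group_probability(lapply(cohort$count_matrix, binarize))
  freq <- prob[cbind(truth$core_edges$node_i, truth$core_edges$node_j)]
  band <- 3 * sqrt(0.9 * 0.1 / 50)
  expect_gte(mean(abs(freq - 0.9) <= band), 0.95)
})

test_that("empirical edge probability converges to the detection probability", {
  truth <- random_network_truth(
    n_nodes = 15, n_core = 50, n_affected = 5,
    prob_range = c(0.3, 0.9), spurious_edge_rate = 0, seed = 7
  )
  site <- site_spec("A", 500, 0, noise_sd = 0, seed = 8)
  cohort <- generate_cohort(site, truth, default_scheme(45))
  prob <- group_probability(lapply(cohort$count_matrix, binarize))
  freq <- prob[cbind(truth$core_edges$node_i, truth$core_edges$node_j)]
  dev <- abs(freq - truth$core_edges$prob)
  expect_lt(mean(dev), 0.05) # law-of-large-numbers convergence at n = 500
  expect_lt(max(dev), 3.5 * sqrt(0.25 / 500)) # no edge beyond binomial range
})

test_that("scanner scaling of SH power shifts control FA between sites", {
  truth <- tiny_truth(n_nodes = 12, n_core = 20, prob = 1, fa = 0.5)
  plain <- site_spec("P", 10, 0, noise_sd = 0, seed = 9)
  scaled <- site_spec("Q", 10, 0,
    sh_order_scales = c("0" = 1.2, "2" = 1, "4" = 1, "6" = 1),
    noise_sd = 0, seed = 9
  )
  gm_plain <- group_matrices(generate_cohort(plain, truth, default_scheme(45)))
  gm_scaled <- group_matrices(generate_cohort(scaled, truth, default_scheme(45)))
  core <- cbind(truth$core_edges$node_i, truth$core_edges$node_j)
  expect_gt(mean(abs(gm_scaled$group_fa[core] - gm_plain$group_fa[core])), 0.005)
})

test_that("patients lose disease_delta of FA on affected edges only", {
  n_core <- 100
  affected <- rep(c(TRUE, FALSE), each = 50)
  truth <- tiny_truth(
    n_nodes = 16, n_core = n_core, prob = 1, fa = 0.5,
    affected = affected, fa_subject_sd = 0, disease_delta = 0.05
  )
  site <- site_spec("A", 60, 60, noise_sd = 0.01, seed = 10)
  cohort <- generate_cohort(site, truth, default_scheme(45))
  gm_c <- group_matrices(cohort[cohort$group == "control", ])
  gm_p <- group_matrices(cohort[cohort$group == "patient", ])
  core <- cbind(truth$core_edges$node_i, truth$core_edges$node_j)
  diff <- (gm_c$group_fa - gm_p$group_fa)[core]
  # affected edges drop by delta (within sampling error of the noisy FA)
  expect_equal(mean(diff[affected]), 0.05, tolerance = 0.01)
  # unaffected edges show no systematic group difference at alpha = 0.01
  tt <- stats::t.test(diff[!affected])
  expect_gt(tt$p.value, 0.01)
})

test_that("phantoms share ground truth across sites and scale stated orders", {
  sch <- default_scheme(45)
  a <- site_spec("A", 3, 0, noise_sd = 0, seed = 11)
  b <- site_spec("B", 3, 0, noise_sd = 0, seed = 12)
  ph_a <- generate_dwi_phantom(a, 25, sch, seed = 13)
  ph_b <- generate_dwi_phantom(b, 25, sch, seed = 13)
  # no scanner effect, no noise: identical signals voxelwise across sites
  expect_identical(ph_a$signals, ph_b$signals)

  scaled <- site_spec("C", 3, 0,
    sh_order_scales = c("0" = 1, "2" = 2, "4" = 1, "6" = 1),
    noise_sd = 0, seed = 14
  )
  ph_c <- generate_dwi_phantom(scaled, 25, sch, seed = 13)
  for (s in 1:3) {
    E_ref <- compute_rish(fit_sh(ph_a$signals[[s]], sch))
    E_sc <- compute_rish(fit_sh(ph_c$signals[[s]], sch))
    expect_equal(unname(E_sc[, "E2"]), unname(2 * E_ref[, "E2"]), tolerance = 1e-6)
    expect_equal(unname(E_sc[, "E0"]), unname(E_ref[, "E0"]), tolerance = 1e-6)
  }

  expect_error(generate_dwi_phantom(a, 0, sch, seed = 1), "n_voxels")
})

test_that("phantom volumes round-trip through NIfTI with gradient tables", {
  skip_if_not_installed("RNifti")
  sch <- default_scheme(20)
  site <- site_spec("A", 2, 0, noise_sd = 0, seed = 15)
  ph <- generate_dwi_phantom(site, 10, sch, seed = 16)
  dir <- withr::local_tempdir()
  paths <- write_phantom_nifti(ph, dir)
  back <- read_phantom_nifti(
    paths,
    file.path(dir, "scheme.bvec"), file.path(dir, "scheme.bval")
  )
  expect_equal(back$signals[[1]], ph$signals[[1]],
    ignore_attr = TRUE, tolerance = 1e-6
  )
  expect_equal(back$scheme$bvalues, sch$bvalues)
})

test_that("cohort covariates export to CSV", {
  truth <- tiny_truth()
  site <- site_spec("A", 2, 2, noise_sd = 0, seed = 17)
  cohort <- generate_cohort(site, truth, default_scheme(45))
  path <- withr::local_tempfile(fileext = ".csv")
  write_covariates_csv(cohort, path)
  back <- read.csv(path)
  expect_equal(back$subject_id, cohort$subject_id)
  expect_equal(back$group, cohort$group)
})
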