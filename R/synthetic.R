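#' Site specification for the synthetic multi-site generator
#'
#' Describes one acquisition site: cohort sizes, the scanner effect (a
#' multiplicative scaling of the diffusion signal's SH power per even order,
#' the kind of acquisition-related difference RISH harmonization removes),
#' measurement noise, and the age distribution of its cohort.
#'
#' @param site_id short site name.
#' @param n_controls,n_patients cohort sizes (>= 0).
#' @param sh_order_scales named numeric vector mapping even SH orders
#'   (names `"0"`, `"2"`, ...) to multiplicative signal-power scales (> 0);
#'   orders not named scale by 1. All 1 means no scanner effect.
#' @param noise_sd Gaussian signal noise standard deviation, as a fraction of
#'   the b = 0 signal.
#' @param age_mean,age_sd cohort age distribution in years (normal, truncated
#'   to 50-90).
#' @param burden multiplier on the disease effect `disease_delta` for this
#'   site's patients (1 = nominal; > 1 emulates a high-burden cohort).
#' @param seed site-specific RNG seed used for noise realisations.
#' @return A `site_spec` object.
#' @export
site_spec <- function(site_id, n_controls, n_patients,
                      sh_order_scales = c("0" = 1, "2" = 1, "4" = 1, "6" = 1),
                      noise_sd = 0.02, age_mean = 70, age_sd = 8,
                      burden = 1, seed = 1L) {
  stopifnot(n_controls >= 0, n_patients >= 0, noise_sd >= 0, burden >= 0)
  if (any(sh_order_scales <= 0)) stop("all `sh_order_scales` must be > 0")
  if (is.null(names(sh_order_scales))) stop("`sh_order_scales` must be named by order")
  structure(
    list(
      site_id = site_id, n_controls = n_controls, n_patients = n_patients,
      sh_order_scales = sh_order_scales, noise_sd = noise_sd,
      age_mean = age_mean, age_sd = age_sd, burden = burden,
      seed = as.integer(seed)
    ),
    class = "site_spec"
  )
}

#' @export
print.site_spec <- function(x, ...) {
  cat(sprintf(
    "<site_spec> %s: %d controls, %d patients, scales [%s], noise %.3f\n",
    x$site_id, x$n_controls, x$n_patients,
    paste(sprintf("l%s=%.2f", names(x$sh_order_scales), x$sh_order_scales),
      collapse = ", "
    ), x$noise_sd
  ))
  invisible(x)
}

#' Ground-truth network for the synthetic generator
#'
#' The planted truth: a shared core edge set detected with high per-edge
#' probability in every subject, a rate of subject-random spurious edges
#' (emulating tractography error: reconstructed in different network
#' locations per subject, hence low group-level probability), and a planted
#' subset of disease-affected core edges whose FA is reduced in patients.
#'
#' @param n_nodes number of network nodes (default 90, as in an AAL-style
#'   cortical/subcortical parcellation).
#' @param core_edges tibble with columns `node_i`, `node_j` (1-based,
#'   i < j), `prob` (per-edge detection probability in \[0, 1\]),
#'   `fa_baseline` (per-edge mean FA in (0, 1)), and logical `affected`.
#' @param spurious_edge_rate expected number of random extra edges per
#'   subject, drawn uniformly over non-core pairs.
#' @param fa_subject_sd between-subject FA standard deviation.
#' @param disease_delta FA reduction on affected edges in patients
#'   (multiplied by the site's `burden`).
#' @return A `network_truth` object.
#' @export
network_truth <- function(n_nodes, core_edges, spurious_edge_rate = 40,
                          fa_subject_sd = 0.03, disease_delta = 0.035) {
  if (n_nodes < 2) stop("`n_nodes` must be at least 2")
  core_edges <- tibble::as_tibble(core_edges)
  stopifnot(all(c("node_i", "node_j", "prob", "fa_baseline", "affected")
  %in% names(core_edges)))
  if (any(core_edges$node_i >= core_edges$node_j)) stop("edges must have node_i < node_j")
  if (any(core_edges$node_j > n_nodes)) stop("edge nodes exceed `n_nodes`")
  if (any(core_edges$prob < 0 | core_edges$prob > 1)) {
    stop("detection probabilities must lie in [0, 1]")
  }
  if (any(core_edges$fa_baseline <= 0 | core_edges$fa_baseline >= 1)) {
    stop("`fa_baseline` must lie in (0, 1)")
  }
  stopifnot(spurious_edge_rate >= 0, fa_subject_sd >= 0, disease_delta >= 0)
  structure(
    list(
      n_nodes = n_nodes, core_edges = core_edges,
      spurious_edge_rate = spurious_edge_rate,
      fa_subject_sd = fa_subject_sd, disease_delta = disease_delta,
      node_labels = sprintf("node%02d", seq_len(n_nodes))
    ),
    class = "network_truth"
  )
}

#' @describeIn network_truth Draw a random ground truth: `n_core` core pairs
#'   with detection probabilities uniform in `prob_range` and FA baselines
#'   uniform in `fa_range`; `n_affected` affected edges sampled among core
#'   edges with detection probability >= 0.8 (so the planted effect lies in
#'   the high-probability network that survives thresholding).
#' @param n_core,n_affected core and affected edge counts.
#' @param prob_range,fa_range ranges for detection probability and FA
#'   baseline.
#' @param seed RNG seed.
#' @export
random_network_truth <- function(n_nodes = 90, n_core = 600, n_affected = 60,
                                 prob_range = c(0.6, 0.95),
                                 fa_range = c(0.30, 0.60),
                                 spurious_edge_rate = 40,
                                 fa_subject_sd = 0.03, disease_delta = 0.035,
                                 seed = 1L) {
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  if (n_core > n_pairs) stop("`n_core` exceeds the number of node pairs")
  withr::with_seed(seed, {
    idx <- sort(sample.int(n_pairs, n_core))
    pairs <- pair_from_index(idx, n_nodes)
    prob <- runif(n_core, prob_range[1], prob_range[2])
    eligible <- which(prob >= 0.8)
    if (length(eligible) < n_affected) eligible <- order(prob, decreasing = TRUE)[seq_len(n_affected)]
    affected <- rep(FALSE, n_core)
    affected[sample(eligible, n_affected)] <- TRUE
    core <- tibble::tibble(
      node_i = pairs[, 1], node_j = pairs[, 2],
      prob = prob,
      fa_baseline = runif(n_core, fa_range[1], fa_range[2]),
      affected = affected
    )
  })
  network_truth(n_nodes, core,
    spurious_edge_rate = spurious_edge_rate,
    fa_subject_sd = fa_subject_sd, disease_delta = disease_delta
  )
}

#' @export
print.network_truth <- function(x, ...) {
  cat(sprintf(
    "<network_truth> %d nodes, %d core edges (%d affected), spurious rate %.1f/subject\n",
    x$n_nodes, nrow(x$core_edges), sum(x$core_edges$affected),
    x$spurious_edge_rate
  ))
  invisible(x)
}

# upper-triangle linear index (column-major over i < j) -> (i, j)
pair_from_index <- function(idx, n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut[idx, , drop = FALSE]
}

#' Generate a synthetic cohort for one site
#'
#' Draws each subject's network (core edges independently with their
#' detection probabilities, plus Poisson-distributed spurious edges uniform
#' over non-core pairs, resampled per subject) and produces each present
#' edge's FA through the full signal model: an axially symmetric diffusion
#' tensor with random orientation targeting the edge's FA, its noise-free
#' signal projected onto the even SH basis, per-order power scaled by the
#' site's scanner effect, resynthesis, Gaussian noise, and a log-linear
#' tensor refit. Harmonization applied downstream therefore genuinely
#' restores FA rather than undoing a shortcut.
#'
#' Patients' affected edges target `fa_baseline - burden * disease_delta`.
#' Ages are normal truncated to 50-90 years; sex alternates 0/1 (covariates
#' exist for adjustment; no particular demography is claimed).
#'
#' @param site a [site_spec()].
#' @param truth a [network_truth()].
#' @param scheme a [gradient_scheme()]; default 45 directions at
#'   b = 1200 s/mm^2.
#' @param seed RNG seed (defaults to the site's seed); byte-identical output
#'   for equal seeds.
#' @return Tibble with one row per subject: `subject_id`, `site_id`,
#'   `group` (`"control"`/`"patient"`), `age`, `sex`, and list-columns
#'   `count_matrix`, `fa_matrix`, `edge_signals` (per-edge signal matrix with
#'   the edge index, consumed by [harmonize_cohort()]).
#' @export
generate_cohort <- function(site, truth, scheme = default_scheme(), seed = site$seed) {
  stopifnot(inherits(site, "site_spec"), inherits(truth, "network_truth"),
    inherits(scheme, "gradient_scheme"))
  n <- truth$n_nodes
  n_sub <- site$n_controls + site$n_patients
  if (n_sub == 0) return(empty_cohort())
  core <- truth$core_edges
  core_idx <- pair_to_index(core$node_i, core$node_j, n)
  n_pairs <- n * (n - 1) / 2
  noncore_idx <- setdiff(seq_len(n_pairs), core_idx)
  lmax <- 6
  B <- sh_basis(scheme$directions[scheme$dwi, , drop = FALSE], lmax)
  Binv <- solve(crossprod(B), t(B))
  order_scale <- sqrt(order_scale_vector(site, lmax))

  groups <- rep(c("control", "patient"), c(site$n_controls, site$n_patients))
  withr::with_seed(seed, {
    age <- pmin(90, pmax(50, rnorm(n_sub, site$age_mean, site$age_sd)))
    sex <- rep_len(c(0L, 1L), n_sub)
    rows <- lapply(seq_len(n_sub), function(s) {
      present_core <- which(rbinom(nrow(core), 1, core$prob) == 1)
      n_sp <- min(rpois(1, truth$spurious_edge_rate), length(noncore_idx))
      sp_idx <- if (n_sp > 0) sample(noncore_idx, n_sp) else integer(0)
      edges <- rbind(
        cbind(core$node_i[present_core], core$node_j[present_core]),
        pair_from_index(sp_idx, n)
      )
      ne <- nrow(edges)
      fa_target <- c(
        core$fa_baseline[present_core] -
          (groups[s] == "patient") * site$burden * truth$disease_delta *
            core$affected[present_core],
        runif(n_sp, 0.30, 0.60)
      ) + rnorm(ne, 0, truth$fa_subject_sd)
      fa_target <- pmin(0.95, pmax(0.05, fa_target))
      signals <- edge_signal_model(fa_target, scheme, B, Binv, order_scale,
        site$noise_sd)
      fa <- fit_tensor_fa(signals, scheme)
      counts <- 1L + rpois(ne, 5)
      list(edges = edges, counts = counts, fa = fa, signals = signals)
    })
  })
  labels <- truth$node_labels
  tibble::tibble(
    subject_id = sprintf("%s_%03d", site$site_id, seq_len(n_sub)),
    site_id = site$site_id,
    group = groups,
    age = age,
    sex = sex,
    count_matrix = lapply(rows, function(r) edge_matrix(r$edges, r$counts, n, labels)),
    fa_matrix = lapply(rows, function(r) edge_matrix(r$edges, r$fa, n, labels)),
    edge_signals = lapply(rows, function(r) list(edges = r$edges, signals = r$signals))
  )
}

empty_cohort <- function() {
  tibble::tibble(
    subject_id = character(), site_id = character(), group = character(),
    age = numeric(), sex = integer(),
    count_matrix = list(), fa_matrix = list(), edge_signals = list()
  )
}

# per-edge signal model: tensor signal -> SH fit -> per-order site scaling ->
# resynthesis -> Gaussian noise -> positive clamp. Returns edges x measurements.
edge_signal_model <- function(fa_target, scheme, B, Binv, order_scale, noise_sd) {
  ne <- length(fa_target)
  nmeas <- length(scheme$bvalues)
  if (ne == 0) return(matrix(0, 0, nmeas))
  axes <- matrix(rnorm(3 * ne), ncol = 3)
  axes <- axes / sqrt(rowSums(axes^2))
  ev <- axial_eigenvalues_for_fa(fa_target)
  sig <- axial_tensor_signals(axes, ev$par, ev$perp, scheme)
  coefs <- t(Binv %*% t(sig[, scheme$dwi, drop = FALSE]))
  coefs <- sweep(coefs, 2, order_scale, `*`)
  out <- matrix(1, ne, nmeas)
  out[, scheme$dwi] <- coefs %*% t(B)
  if (noise_sd > 0) out <- out + matrix(rnorm(ne * nmeas, 0, noise_sd), ne, nmeas)
  pmax(out, 1e-4)
}

order_scale_vector <- function(site, lmax) {
  orders <- sh_orders(lmax)
  sc <- rep(1, length(orders))
  for (nm in names(site$sh_order_scales)) {
    sc[orders == as.integer(nm)] <- site$sh_order_scales[[nm]]
  }
  sc
}

pair_to_index <- function(i, j, n) {
  ut <- which(upper.tri(matrix(0, n, n)))
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- seq_along(ut)
  m[cbind(i, j)]
}

edge_matrix <- function(edges, values, n, labels) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (nrow(edges) > 0) {
    m[edges] <- values
    m[edges[, c(2, 1), drop = FALSE]] <- values
  }
  m
}

#' Generate a voxel-level diffusion-signal phantom for one site
#'
#' Every voxel carries ground-truth SH coefficients shared across sites
#' (drawn from `seed`, which must therefore be common to all sites being
#' compared); per-subject multiplicative variation is likewise seeded
#' site-independently, so with no scanner effect and no noise two sites'
#' phantoms are voxelwise identical. The site's scanner effect multiplies
#' order-l coefficients by `sqrt(sh_order_scales[l])` (scaling SH power E_l
#' by the stated factor), signals are resynthesized on the scheme's
#' directions, and Gaussian noise of sd `noise_sd` (seeded from the site's
#' own seed) is added. One phantom is produced per control subject of the
#' site.
#'
#' @param site a [site_spec()].
#' @param n_voxels number of voxels (>= 1).
#' @param scheme a [gradient_scheme()].
#' @param seed shared seed for the ground-truth coefficients.
#' @return List with `signals` (list of voxels x measurements matrices, one
#'   per control), `truth_coefficients`, `scheme`, `site`.
#' @export
generate_dwi_phantom <- function(site, n_voxels, scheme = default_scheme(),
                                 seed = 1L) {
  stopifnot(inherits(site, "site_spec"), inherits(scheme, "gradient_scheme"))
  if (n_voxels < 1) stop("`n_voxels` must be at least 1")
  lmax <- 6
  truth_coefs <- withr::with_seed(seed, phantom_truth_coefficients(n_voxels, lmax))
  order_scale <- sqrt(order_scale_vector(site, lmax))
  B <- sh_basis(scheme$directions[scheme$dwi, , drop = FALSE], lmax)
  nmeas <- length(scheme$bvalues)
  signals <- lapply(seq_len(site$n_controls), function(s) {
    jitter <- withr::with_seed(seed + 7919L * s, exp(rnorm(1, 0, 0.05)))
    coefs <- sweep(truth_coefs * jitter, 2, order_scale, `*`)
    out <- matrix(1, n_voxels, nmeas)
    out[, scheme$dwi] <- coefs %*% t(B)
    if (site$noise_sd > 0) {
      noise <- withr::with_seed(
        site$seed + s,
        matrix(rnorm(n_voxels * nmeas, 0, site$noise_sd), n_voxels, nmeas)
      )
      out <- out + noise
    }
    pmax(out, 1e-4)
  })
  list(
    signals = signals, truth_coefficients = truth_coefs,
    scheme = scheme, site = site
  )
}

# shared ground truth: positive mean DW level with decaying per-order power
phantom_truth_coefficients <- function(n_voxels, lmax) {
  orders <- sh_orders(lmax)
  level <- runif(n_voxels, 0.4, 0.7)
  coefs <- matrix(0, n_voxels, length(orders))
  coefs[, 1] <- level * sqrt(4 * pi)
  amp <- c("2" = 0.12, "4" = 0.05, "6" = 0.02)
  for (l in c(2, 4, 6)) {
    idx <- which(orders == l)
    coefs[, idx] <- matrix(
      rnorm(n_voxels * length(idx), 0, amp[[as.character(l)]]),
      n_voxels
    ) * level
  }
  colnames(coefs) <- sh_coef_names(lmax)
  coefs
}

#' Harmonize a synthetic cohort's edge FA
#'
#' Applies site-to-reference scale maps to every subject's per-edge diffusion
#' signals (refit SH, multiply order-l coefficients by the map's per-order
#' scale, resynthesize) and refits the tensor, replacing `fa_matrix`. Scale
#' maps computed on a phantom voxel grid are collapsed to their per-order
#' voxelwise mean before application: the generator's scanner effects are
#' global per order, so the maps are spatially flat up to noise and their
#' mean is the natural summary on the edge "grid".
#'
#' @param subjects cohort tibble from [generate_cohort()].
#' @param maps a `scale_maps` matrix from [compute_scale_maps()].
#' @param scheme the [gradient_scheme()] used to generate the cohort.
#' @return The cohort tibble with harmonized `fa_matrix` (and updated
#'   `edge_signals`).
#' @export
harmonize_cohort <- function(subjects, maps, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  s_l <- colMeans(unclass(maps))
  lmax <- 2 * (length(s_l) - 1)
  coef_scale <- rep(s_l, times = 2 * seq(0, lmax, by = 2) + 1)
  B <- sh_basis(scheme$directions[scheme$dwi, , drop = FALSE], lmax)
  Binv <- solve(crossprod(B), t(B))
  n <- nrow(subjects$fa_matrix[[1]])
  labels <- rownames(subjects$fa_matrix[[1]])
  harmonized <- lapply(subjects$edge_signals, function(es) {
    sig <- es$signals
    if (nrow(sig) == 0) return(es)
    coefs <- t(Binv %*% t(sig[, scheme$dwi, drop = FALSE]))
    coefs <- sweep(coefs, 2, coef_scale, `*`)
    sig[, scheme$dwi] <- coefs %*% t(B)
    es$signals <- pmax(sig, 1e-4)
    es
  })
  subjects$edge_signals <- harmonized
  subjects$fa_matrix <- lapply(seq_len(nrow(subjects)), function(s) {
    es <- harmonized[[s]]
    fa <- if (nrow(es$signals) > 0) fit_tensor_fa(es$signals, scheme) else numeric(0)
    edge_matrix(es$edges, fa, n, labels)
  })
  subjects
}

#' Write cohort covariates as CSV
#'
#' @param subjects cohort tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(subjects, path) {
  utils::write.csv(
    subjects[, c("subject_id", "site_id", "group", "age", "sex")],
    path,
    row.names = FALSE
  )
  invisible(path)
}
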