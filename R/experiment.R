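#' Default configuration for the synthetic multi-site experiment
#'
#' Encodes the study conditions the synthetic pipeline emulates: four
#' sporadic-disease sites of 20 controls and 20 patients each (pooling to 80
#' per group), one high-burden reference site (20 controls, 25 patients,
#' burden x1.5) playing the monogenic-SVD role, a 90-node network with 600
#' high-probability core edges, 60 planted affected edges, subject-random
#' spurious edges, per-site scanner effects expressed as per-order SH power
#' scalings, 15% density thresholding, and 1000-permutation edgewise
#' statistics. `disease_delta` is set so the planted effect lands near
#' Cohen's d of 1 at the generator's noise levels.
#'
#' @param seed master seed; all site and analysis seeds are derived from it.
#' @param n_perm permutations for the edgewise tests.
#' @return A named list accepted by [run_experiment()].
#' @export
default_experiment_config <- function(seed = 20260920, n_perm = 1000) {
  list(
    seed = as.integer(seed),
    n_nodes = 90, n_core = 600, n_affected = 60,
    prob_range = c(0.60, 0.95), fa_range = c(0.30, 0.60),
    spurious_edge_rate = 40,
    fa_subject_sd = 0.03, disease_delta = 0.040,
    density = 0.15,
    n_perm = n_perm, d_threshold = 0.8, q_level = 0.05,
    n_phantom_voxels = 300, n_harmonization_controls = 15,
    scheme = list(n_dirs = 45, bvalue = 1200, n_b0 = 1),
    reference_site = "UT",
    sites = list(
      list(
        site_id = "UT", n_controls = 20, n_patients = 20, burden = 1.0,
        sh_order_scales = c("0" = 1.00, "2" = 1.00, "4" = 1.00, "6" = 1.00),
        noise_sd = 0.02
      ),
      list(
        site_id = "ZO", n_controls = 20, n_patients = 20, burden = 1.0,
        sh_order_scales = c("0" = 1.05, "2" = 1.25, "4" = 1.10, "6" = 1.00),
        noise_sd = 0.02
      ),
      list(
        site_id = "HK", n_controls = 20, n_patients = 20, burden = 0.7,
        sh_order_scales = c("0" = 1.10, "2" = 0.70, "4" = 0.90, "6" = 1.00),
        noise_sd = 0.02
      ),
      list(
        site_id = "SI", n_controls = 20, n_patients = 20, burden = 0.7,
        sh_order_scales = c("0" = 0.95, "2" = 1.15, "4" = 1.05, "6" = 1.00),
        noise_sd = 0.02
      )
    ),
    reference_cohort = list(
      site_id = "MU", n_controls = 20, n_patients = 25, burden = 1.5,
      sh_order_scales = c("0" = 1.02, "2" = 0.85, "4" = 0.95, "6" = 1.00),
      noise_sd = 0.02
    )
  )
}

#' Read and write experiment configurations as YAML
#'
#' @param config experiment configuration list.
#' @param path file path.
#' @return `read_experiment_config()` returns the configuration list; the
#'   writer returns `path` invisibly.
#' @export
write_experiment_config <- function(config, path) {
  as_map <- function(s) {
    s$sh_order_scales <- as.list(s$sh_order_scales)
    s
  }
  config$sites <- lapply(config$sites, as_map)
  config$reference_cohort <- as_map(config$reference_cohort)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  config <- yaml::read_yaml(path)
  fix_scales <- function(s) {
    s$sh_order_scales <- unlist(s$sh_order_scales)
    s
  }
  config$sites <- lapply(config$sites, fix_scales)
  config$reference_cohort <- fix_scales(config$reference_cohort)
  config$prob_range <- unlist(config$prob_range)
  config$fa_range <- unlist(config$fa_range)
  config
}

validate_config <- function(config) {
  required <- c(
    "seed", "n_nodes", "n_core", "n_affected", "spurious_edge_rate",
    "fa_subject_sd", "disease_delta", "density", "n_perm", "sites",
    "reference_cohort", "scheme", "reference_site"
  )
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("configuration is missing fields: ", paste(missing, collapse = ", "))
  }
  ids <- vapply(config$sites, `[[`, "", "site_id")
  if (anyDuplicated(ids)) stop("duplicate site ids in configuration")
  if (!config$reference_site %in% ids) {
    stop(sprintf("reference_site '%s' is not among the sites", config$reference_site))
  }
  invisible(config)
}

config_site_specs <- function(config) {
  mk <- function(s, k) {
    site_spec(
      site_id = s$site_id, n_controls = s$n_controls,
      n_patients = s$n_patients, sh_order_scales = s$sh_order_scales,
      noise_sd = s$noise_sd, burden = s$burden,
      seed = config$seed + 97L * k
    )
  }
  sites <- Map(mk, config$sites, seq_along(config$sites))
  names(sites) <- vapply(sites, `[[`, "", "site_id")
  reference <- mk(config$reference_cohort, length(sites) + 1L)
  list(sites = sites, reference = reference)
}

#' Run the full synthetic multi-site experiment
#'
#' Orchestrates the whole pipeline on synthetic data with planted ground
#' truth: cohort and phantom generation per site, RISH scale maps against
#' the reference site and cohort harmonization, cross-site consistency of
#' probability and FA group matrices under the four conditions (neither,
#' harmonization only, thresholding only, both), per-site and pooled
#' edgewise permutation statistics (pooling concatenates the sporadic sites'
#' subjects with no site covariate, so harmonization is the only site
#' correction), staged detections, precision against the high-burden
#' reference cohort's surviving edges and against the planted truth, and
#' sensitivity counts. Deterministic given the configuration seed.
#'
#' @param config configuration list, see [default_experiment_config()].
#' @return An `svd_experiment` object; see [tidy.svd_experiment()] for the
#'   tabular views (`consistency`, `detection_summary`, `table1`,
#'   `recovery`).
#' @export
run_experiment <- function(config = default_experiment_config()) {
  validate_config(config)
  scheme <- default_scheme(
    n_dirs = config$scheme$n_dirs, bvalue = config$scheme$bvalue,
    n_b0 = config$scheme$n_b0
  )
  truth <- random_network_truth(
    n_nodes = config$n_nodes, n_core = config$n_core,
    n_affected = config$n_affected, prob_range = config$prob_range,
    fa_range = config$fa_range, spurious_edge_rate = config$spurious_edge_rate,
    fa_subject_sd = config$fa_subject_sd, disease_delta = config$disease_delta,
    seed = config$seed
  )
  specs <- config_site_specs(config)
  cohorts <- lapply(specs$sites, generate_cohort, truth = truth, scheme = scheme)
  reference_cohort <- generate_cohort(specs$reference, truth = truth, scheme = scheme)

  # scale maps from matched-control phantoms, site -> reference site
  maps <- site_scale_maps(specs$sites, config, scheme)
  harmonized <- Map(function(subjects, m) harmonize_cohort(subjects, m, scheme),
    cohorts, maps[names(cohorts)]
  )

  consistency <- consistency_conditions(cohorts, harmonized, config)

  analyses <- c(
    cohorts,
    list(
      MU = reference_cohort,
      pooled_raw = dplyr::bind_rows(cohorts),
      pooled_harmonized = dplyr::bind_rows(harmonized)
    )
  )
  seeds <- config$seed + 1009L * seq_along(analyses)
  detections <- list()
  masks <- list()
  results <- list()
  for (k in seq_along(analyses)) {
    nm <- names(analyses)[k]
    subjects <- analyses[[k]]
    gm <- group_matrices(subjects)
    masks[[nm]] <- density_threshold(gm$probability, config$density)
    results[[nm]] <- edge_stats(subjects, n_perm = config$n_perm, seed = seeds[k])
    detections[[nm]] <- stage_detections(results[[nm]], masks[[nm]],
      d_threshold = config$d_threshold, q_level = config$q_level
    )
  }

  reference <- build_reference(detections$MU,
    provenance = "high-burden reference cohort (thresholding + FDR)"
  )
  planted <- reference_edge_set(
    truth$core_edges[truth$core_edges$affected, ],
    provenance = "planted affected edges"
  )

  summary_rows <- list()
  for (nm in setdiff(names(detections), "MU")) {
    for (stage in names(detections[[nm]])) {
      det <- detections[[nm]][[stage]]
      sc_ref <- score_precision(det, reference)
      sc_true <- score_precision(det, planted)
      summary_rows[[length(summary_rows) + 1]] <- tibble::tibble(
        cohort = nm, stage = stage, n_detected = nrow(det),
        tp = sc_ref$tp, fp = sc_ref$fp, precision = sc_ref$precision,
        tp_planted = sc_true$tp, precision_planted = sc_true$precision
      )
    }
  }
  detection_summary <- dplyr::bind_rows(summary_rows)

  table1 <- tidyr::pivot_wider(
    detection_summary[, c("cohort", "stage", "tp", "fp", "precision")],
    names_from = "cohort",
    values_from = c("tp", "fp", "precision")
  )

  recovery <- recovery_stats(detections$pooled_harmonized, planted,
    masks$pooled_harmonized)

  structure(
    list(
      config = config, truth = truth, scheme = scheme,
      cohorts = cohorts, harmonized = harmonized,
      reference_cohort = reference_cohort,
      scale_maps = maps, masks = masks,
      edge_results = results, detections = detections,
      reference = reference, planted = planted,
      consistency = consistency,
      detection_summary = detection_summary,
      table1 = table1, recovery = recovery,
      sensitivity = vapply(detections, sensitivity_count, integer(1))
    ),
    class = "svd_experiment"
  )
}

site_scale_maps <- function(sites, config, scheme) {
  phantom_seed <- config$seed + 13L
  n_train <- config$n_harmonization_controls
  features <- lapply(sites, function(site) {
    train <- site
    train$n_controls <- min(n_train, site$n_controls)
    ph <- generate_dwi_phantom(train, config$n_phantom_voxels, scheme,
      seed = phantom_seed)
    lapply(ph$signals, function(sig) compute_rish(fit_sh(sig, scheme)))
  })
  ref <- features[[config$reference_site]]
  lapply(features, function(f) compute_scale_maps(f, ref))
}

consistency_conditions <- function(cohorts, harmonized, config) {
  n_train <- config$n_harmonization_controls
  controls <- function(subjects) {
    ctl <- subjects[subjects$group == "control", ]
    head(ctl, n_train)
  }
  site_gm <- function(cohort_list) lapply(cohort_list, function(s) group_matrices(controls(s)))
  gm_raw <- site_gm(cohorts)
  gm_harm <- site_gm(harmonized)
  masks <- lapply(gm_raw, function(g) density_threshold(g$probability, config$density))
  ids <- names(cohorts)
  pairs <- utils::combn(ids, 2)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]
    b <- pairs[2, p]
    for (condition in c("none", "harmonized", "thresholded", "both")) {
      ga <- if (condition %in% c("harmonized", "both")) gm_harm[[a]] else gm_raw[[a]]
      gb <- if (condition %in% c("harmonized", "both")) gm_harm[[b]] else gm_raw[[b]]
      pa <- ga$probability; pb <- gb$probability
      fa <- ga$group_fa; fb <- gb$group_fa
      if (condition %in% c("thresholded", "both")) {
        pa <- apply_mask(pa, masks[[a]]); pb <- apply_mask(pb, masks[[b]])
        fa <- apply_mask(fa, masks[[a]]); fb <- apply_mask(fb, masks[[b]])
      }
      for (metric in c("probability", "fa")) {
        cr <- if (metric == "probability") {
          relative_difference(pa, pb)
        } else {
          relative_difference(fa, fb)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          condition = condition, metric = metric, site_a = a, site_b = b,
          mean_pct = cr$summary_mean, max_pct = cr$summary_max,
          support_count = cr$support_count
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

recovery_stats <- function(detections, planted, mask) {
  in_mask <- unclass(mask)[cbind(planted$node_i, planted$node_j)] > 0
  planted_in_mask <- planted[in_mask, ]
  det <- detections$surviving_fdr
  recovered <- sum(edge_keys(det) %in% edge_keys(planted_in_mask))
  sc <- score_precision(det, reference_edge_set(planted))
  tibble::tibble(
    n_planted = nrow(planted),
    n_planted_in_mask = nrow(planted_in_mask),
    n_detected = nrow(det),
    n_recovered = recovered,
    recovery = recovered / nrow(planted_in_mask),
    precision_vs_planted = sc$precision
  )
}

#' @export
print.svd_experiment <- function(x, ...) {
  cat("<svd_experiment>\n")
  cat(sprintf(
    "  sites: %s (+ reference %s); pooled %d controls / %d patients\n",
    paste(names(x$cohorts), collapse = ", "), x$reference_cohort$site_id[1],
    sum(dplyr::bind_rows(x$cohorts)$group == "control"),
    sum(dplyr::bind_rows(x$cohorts)$group == "patient")
  ))
  cs <- dplyr::summarise(
    dplyr::group_by(x$consistency, .data$condition, .data$metric),
    mean_pct = mean(.data$mean_pct), .groups = "drop"
  )
  cat("  mean cross-site difference (%) by condition:\n")
  for (r in seq_len(nrow(cs))) {
    cat(sprintf(
      "    %-12s %-12s %6.1f\n", cs$condition[r], cs$metric[r], cs$mean_pct[r]
    ))
  }
  cat(sprintf(
    "  pooled harmonized: recovery %.2f, precision vs planted %.2f, sensitivity %d\n",
    x$recovery$recovery, x$recovery$precision_vs_planted,
    x$sensitivity[["pooled_harmonized"]]
  ))
  invisible(x)
}

#' Tabular views of an experiment
#'
#' `tidy()` returns the per-cohort, per-stage detection summary (counts and
#' precision against the reference cohort and against the planted truth);
#' `glance()` a one-row overview.
#'
#' @param x an `svd_experiment`.
#' @param ... unused.
#' @export
tidy.svd_experiment <- function(x, ...) x$detection_summary

#' @rdname tidy.svd_experiment
#' @export
glance.svd_experiment <- function(x, ...) {
  cs <- function(cond, metric) {
    v <- x$consistency
    mean(v$mean_pct[v$condition == cond & v$metric == metric])
  }
  tibble::tibble(
    prob_diff_raw = cs("none", "probability"),
    prob_diff_thresholded = cs("thresholded", "probability"),
    fa_diff_raw = cs("none", "fa"),
    fa_diff_harmonized = cs("harmonized", "fa"),
    fa_diff_both = cs("both", "fa"),
    recovery = x$recovery$recovery,
    precision_vs_planted = x$recovery$precision_vs_planted,
    sensitivity_pooled_harmonized = x$sensitivity[["pooled_harmonized"]]
  )
}

#' Write the experiment's tabular outputs
#'
#' Emits the consistency table, detection summary, the wide precision table
#' and the recovery summary as CSV files, plus a JSON run manifest with the
#' seed and configuration, into `dir`.
#'
#' @param x an `svd_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(x, dir) {
  stopifnot(inherits(x, "svd_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(x$consistency, file.path(dir, "consistency.csv"), row.names = FALSE)
  utils::write.csv(x$detection_summary, file.path(dir, "detection_summary.csv"),
    row.names = FALSE)
  utils::write.csv(x$table1, file.path(dir, "precision_table.csv"), row.names = FALSE)
  utils::write.csv(x$recovery, file.path(dir, "recovery.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(seed = x$config$seed, n_perm = x$config$n_perm,
        sites = vapply(x$config$sites, `[[`, "", "site_id")),
      file.path(dir, "manifest.json"),
      auto_unbox = TRUE
    )
  }
  invisible(dir)
}
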