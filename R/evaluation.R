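#' Build the reference edge set from a reference cohort's detections
#'
#' The reference standard for disease-affected connections is the set of
#' edges that survive thresholding and FDR in a high-burden reference cohort
#' (the role the monogenic-SVD CADASIL sample plays in multicentre SVD
#' analyses). Rebuilding from the same detections is idempotent; an empty
#' surviving set raises a warning since downstream precision is then
#' undefined.
#'
#' @param detections a [stage_detections()] result for the reference cohort.
#' @param provenance short free-text description of the reference's origin.
#' @return A `reference_edge_set`: tibble of `node_i`, `node_j` with a
#'   `provenance` attribute.
#' @export
build_reference <- function(detections, provenance = "reference cohort, thresholding + FDR") {
  stopifnot(inherits(detections, "stage_detections"))
  edges <- detections$surviving_fdr[, c("node_i", "node_j")]
  if (nrow(edges) == 0) {
    warning("reference cohort has no edges surviving thresholding and FDR; precision will be undefined")
  }
  structure(edges, provenance = provenance,
    class = c("reference_edge_set", class(edges)))
}

#' @describeIn build_reference Construct a reference directly from an edge
#'   tibble (e.g. the planted affected edges of a synthetic truth).
#' @param edges tibble with `node_i`, `node_j`.
#' @export
reference_edge_set <- function(edges, provenance = "planted truth") {
  edges <- tibble::as_tibble(edges)[, c("node_i", "node_j")]
  structure(edges, provenance = provenance,
    class = c("reference_edge_set", class(edges)))
}

#' Precision of a detected edge set against a reference
#'
#' True positives are detected edges also present in the reference; false
#' positives the remainder; precision = TP / (TP + FP). An empty detected
#' set yields TP = FP = 0 and undefined (NA) precision, reported as "N/A" in
#' tabular output.
#'
#' @param detected tibble of detected edges (`node_i`, `node_j`), e.g. one
#'   stage of [stage_detections()].
#' @param reference a `reference_edge_set`.
#' @return One-row tibble: `tp`, `fp`, `precision`.
#' @examples
#' ref <- reference_edge_set(data.frame(node_i = 1:40, node_j = 41:80))
#' det <- data.frame(node_i = c(1:37, 5), node_j = c(41:77, 90))
#' score_precision(det, ref) # 37 / 38
#' @export
score_precision <- function(detected, reference) {
  stopifnot(inherits(reference, "reference_edge_set"))
  if (nrow(reference) == 0) warning("empty reference edge set")
  det_keys <- unique(edge_keys(detected))
  ref_keys <- edge_keys(reference)
  tp <- sum(det_keys %in% ref_keys)
  fp <- length(det_keys) - tp
  tibble::tibble(
    tp = tp, fp = fp,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

edge_keys <- function(edges) {
  i <- pmin(edges$node_i, edges$node_j)
  j <- pmax(edges$node_i, edges$node_j)
  paste(i, j, sep = "-")
}

#' Sensitivity indicator: connections surviving thresholding and FDR
#'
#' The number of connections with a large effect size that survive both the
#' density-threshold mask and FDR correction, used as an indicator of
#' sensitivity (detected true and false positives both count).
#'
#' @param detections a [stage_detections()] result.
#' @return Integer count.
#' @export
sensitivity_count <- function(detections) {
  stopifnot(inherits(detections, "stage_detections"))
  nrow(detections$surviving_fdr)
}

#' Reported detection counts from the multicentre SVD cohorts
#'
#' True/false-positive counts of connections detected as affected in four
#' sporadic-SVD cohorts (UT, ZO, HK, SI) and in their pooled data before and
#' after harmonization, scored against the CADASIL reference standard at
#' three stages: large effect size (d > 0.8), surviving thresholding, and
#' surviving thresholding + FDR. These published integers are the input to
#' the precision arithmetic that validates [score_precision()]; the package
#' does not claim to regenerate them from raw data (the underlying cohorts
#' are not redistributable).
#'
#' @return Tibble with columns `cohort`, `stage`, `tp`, `fp`.
#' @export
reported_detection_counts <- function() {
  path <- system.file("extdata", "multisite_svd_detection_counts.csv",
    package = "rishnet", mustWork = TRUE
  )
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Precision table from reported counts
#'
#' Applies the precision formula TP / (TP + FP) to a table of detection
#' counts (by default the shipped multicentre SVD counts), producing the
#' familiar cohort x stage precision table; empty detection sets give "N/A".
#'
#' @param counts tibble with `cohort`, `stage`, `tp`, `fp`.
#' @return The input with `precision` (numeric, NA when undefined) added.
#' @export
precision_from_counts <- function(counts = reported_detection_counts()) {
  dplyr::mutate(
    counts,
    precision = ifelse(.data$tp + .data$fp > 0,
      .data$tp / (.data$tp + .data$fp), NA_real_
    )
  )
}
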