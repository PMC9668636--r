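#' Write phantom signal volumes to disk
#'
#' Writes one NIfTI volume per subject (voxels laid out along the first
#' axis, measurements along the fourth) together with the FSL-style
#' `bvec`/`bval` gradient table. Requires the RNifti package.
#'
#' @param phantom result of [generate_dwi_phantom()].
#' @param dir output directory (created if needed).
#' @return Character vector of written signal file paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI output requires the RNifti package")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_bvec_bval(
    phantom$scheme,
    file.path(dir, "scheme.bvec"), file.path(dir, "scheme.bval")
  )
  paths <- vapply(seq_along(phantom$signals), function(s) {
    sig <- phantom$signals[[s]]
    vol <- array(sig, dim = c(nrow(sig), 1, 1, ncol(sig)))
    path <- file.path(
      dir,
      sprintf("%s_control%02d.nii.gz", phantom$site$site_id, s)
    )
    RNifti::writeNifti(RNifti::asNifti(vol), path)
    path
  }, character(1))
  invisible(paths)
}

#' Read phantom signal volumes written by [write_phantom_nifti()]
#'
#' @param paths NIfTI file paths.
#' @param bvec_path,bval_path gradient table paths.
#' @return List with `signals` (list of voxels x measurements matrices) and
#'   `scheme`.
#' @export
read_phantom_nifti <- function(paths, bvec_path, bval_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI input requires the RNifti package")
  }
  scheme <- read_bvec_bval(bvec_path, bval_path)
  signals <- lapply(paths, function(p) {
    vol <- RNifti::readNifti(p)
    matrix(vol, nrow = dim(vol)[1], ncol = dim(vol)[4])
  })
  list(signals = signals, scheme = scheme)
}
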