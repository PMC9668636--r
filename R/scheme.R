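#' Diffusion gradient schemes
#'
#' A gradient scheme pairs unit gradient directions with b-values, mirroring an
#' FSL-style `bvec`/`bval` table. Single-shell acquisitions are assumed: all
#' nonzero b-values must be equal. At least one b = 0 measurement and enough
#' distinct diffusion-weighted directions for the intended spherical-harmonic
#' order are required downstream.
#'
#' @param directions numeric matrix, one row per measurement, three columns
#'   (x, y, z). Rows with b = 0 may be zero vectors; diffusion-weighted rows
#'   must have unit norm (tolerance 1e-6).
#' @param bvalues numeric vector of b-values in s/mm^2, one per row of
#'   `directions`.
#' @return An object of class `gradient_scheme`: a list with `directions`,
#'   `bvalues`, and logical index `dwi` flagging nonzero-b measurements.
#' @examples
#' sch <- default_scheme(n_dirs = 45, bvalue = 1200)
#' sum(sch$dwi)
#' @export
gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  storage.mode(directions) <- "double"
  if (ncol(directions) != 3) stop("`directions` must have three columns")
  if (nrow(directions) != length(bvalues)) {
    stop("`directions` and `bvalues` must have the same length")
  }
  bvalues <- as.numeric(bvalues)
  dwi <- bvalues > 0
  if (!any(!dwi)) stop("scheme needs at least one b = 0 measurement")
  if (!any(dwi)) stop("scheme needs at least one diffusion-weighted direction")
  norms <- sqrt(rowSums(directions[dwi, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("diffusion-weighted directions must have unit norm (tolerance 1e-6)")
  }
  b_nz <- unique(bvalues[dwi])
  if (length(b_nz) > 1) stop("only single-shell schemes are supported")
  structure(
    list(directions = directions, bvalues = bvalues, dwi = dwi),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf(
    "<gradient_scheme> %d measurements: %d b=0, %d at b=%g s/mm^2\n",
    length(x$bvalues), sum(!x$dwi), sum(x$dwi), unique(x$bvalues[x$dwi])
  ))
  invisible(x)
}

#' @describeIn gradient_scheme Deterministic scheme with `n_dirs` directions
#'   spread over the sphere by a Fibonacci spiral (plus `n_b0` b = 0 rows),
#'   emulating a typical clinical single-shell protocol.
#' @param n_dirs number of diffusion-weighted directions.
#' @param bvalue shell b-value in s/mm^2.
#' @param n_b0 number of b = 0 measurements.
#' @export
default_scheme <- function(n_dirs = 45, bvalue = 1200, n_b0 = 1) {
  dirs <- fibonacci_sphere(n_dirs)
  directions <- rbind(matrix(0, n_b0, 3), dirs)
  gradient_scheme(directions, c(rep(0, n_b0), rep(bvalue, n_dirs)))
}

# Fibonacci spiral point set on the unit sphere; deterministic and well spread.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Read and write FSL-style gradient tables
#'
#' `bvec` files hold three whitespace-separated rows (x, y, z components, one
#' column per measurement); `bval` files hold one row of b-values.
#'
#' @param scheme a [gradient_scheme()].
#' @param bvec_path,bval_path file paths.
#' @return `write_bvec_bval()` returns the paths invisibly;
#'   `read_bvec_bval()` returns a [gradient_scheme()].
#' @export
write_bvec_bval <- function(scheme, bvec_path, bval_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  write.table(t(scheme$directions), bvec_path,
    row.names = FALSE, col.names = FALSE
  )
  cat(paste(scheme$bvalues, collapse = " "), "\n", file = bval_path)
  invisible(c(bvec_path, bval_path))
}

#' @rdname write_bvec_bval
#' @export
read_bvec_bval <- function(bvec_path, bval_path) {
  bvec <- as.matrix(read.table(bvec_path))
  bval <- scan(bval_path, quiet = TRUE)
  gradient_scheme(t(bvec), bval)
}
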