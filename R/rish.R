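#' Real even spherical-harmonic basis
#'
#' Evaluates the real, even-order spherical-harmonic basis (orthonormal on the
#' sphere, Condon-Shortley phase as in common dMRI tooling; antipodal symmetry
#' is implied by restricting to even orders) at a set of unit directions.
#' Coefficient columns are ordered by increasing order l = 0, 2, ..., lmax and,
#' within each order, by m = -l, ..., l.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param lmax maximum (even) harmonic order.
#' @return n x `n_sh_coef(lmax)` design matrix.
#' @export
sh_basis <- function(directions, lmax = 6) {
  if (lmax %% 2 != 0 || lmax < 0) stop("`lmax` must be a non-negative even integer")
  directions <- as.matrix(directions)
  x <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  n <- nrow(directions)
  B <- matrix(0, n, n_sh_coef(lmax))
  col <- 0L
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, x) # rows m = 0..l, includes Condon-Shortley phase
    if (is.null(dim(P))) P <- matrix(P, l + 1, n)
    for (m in seq(-l, l)) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
        exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      col <- col + 1L
      B[, col] <- if (m < 0) {
        sqrt(2) * nrm * P[am + 1, ] * sin(am * phi)
      } else if (m == 0) {
        nrm * P[1, ]
      } else {
        sqrt(2) * nrm * P[am + 1, ] * cos(am * phi)
      }
    }
  }
  colnames(B) <- sh_coef_names(lmax)
  B
}

#' @describeIn sh_basis Number of real even-order SH coefficients up to `lmax`:
#'   (lmax + 1)(lmax + 2) / 2.
#' @export
n_sh_coef <- function(lmax = 6) (lmax + 1) * (lmax + 2) / 2

#' @describeIn sh_basis Harmonic order l of each coefficient column.
#' @export
sh_orders <- function(lmax = 6) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}

sh_coef_names <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) {
    sprintf("c%d_%d", l, seq(-l, l))
  }))
}

#' Fit spherical harmonics to diffusion-weighted signals
#'
#' Least-squares fit of the real even SH basis to each voxel's
#' diffusion-weighted signal. b = 0 measurements are excluded from the fit and
#' used to normalize the signal per voxel (their mean divides the DW signal);
#' the stored b0 restores physical units on resynthesis.
#'
#' @param signals numeric matrix, voxels x measurements, matching `scheme`.
#' @param scheme a [gradient_scheme()].
#' @param lmax maximum even harmonic order (default 6).
#' @return An `sh_coefficients` object: list with `coefficients`
#'   (voxels x coefficients), `lmax`, and `b0` (per-voxel mean b = 0 signal).
#' @examples
#' sch <- default_scheme(45)
#' sig <- cbind(1, matrix(0.4, 3, 45)) # isotropic signal, 3 voxels
#' fit <- fit_sh(sig, sch)
#' max(abs(fit$coefficients[, -1])) # higher orders vanish
#' @export
fit_sh <- function(signals, scheme, lmax = 6) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  signals <- as.matrix(signals)
  if (ncol(signals) != length(scheme$bvalues)) {
    stop("`signals` columns must match the scheme's measurements")
  }
  if (any(!is.finite(signals))) stop("`signals` must be finite")
  ncoef <- n_sh_coef(lmax)
  ndir <- sum(scheme$dwi)
  if (ndir < ncoef) {
    stop(sprintf(
      "underdetermined SH fit: %d diffusion-weighted directions < %d coefficients required for lmax %d",
      ndir, ncoef, lmax
    ))
  }
  B <- sh_basis(scheme$directions[scheme$dwi, , drop = FALSE], lmax)
  b0 <- rowMeans(signals[, !scheme$dwi, drop = FALSE])
  S <- signals[, scheme$dwi, drop = FALSE] / b0
  # normal equations; Fibonacci/acquisition direction sets are well conditioned
  coefs <- t(solve(crossprod(B), crossprod(B, t(S))))
  dimnames(coefs) <- list(rownames(signals), colnames(B))
  structure(list(coefficients = coefs, lmax = lmax, b0 = b0),
    class = "sh_coefficients"
  )
}

#' @export
print.sh_coefficients <- function(x, ...) {
  cat(sprintf(
    "<sh_coefficients> %d voxels, lmax %d (%d coefficients)\n",
    nrow(x$coefficients), x$lmax, ncol(x$coefficients)
  ))
  invisible(x)
}

#' Rotation-invariant spherical-harmonic (RISH) features
#'
#' The RISH feature of order l is the power of the signal's SH expansion in
#' that order, E_l = sum over m of c_lm^2. Being a per-order power in an
#' orthonormal basis, E_l is invariant to rotations of the sampling frame, so
#' it captures scanner-related signal-power differences independently of
#' fibre orientation.
#'
#' @param coeffs an `sh_coefficients` object from [fit_sh()].
#' @return A `rish_features` matrix, voxels x orders, columns `E0`, `E2`, ...
#' @export
compute_rish <- function(coeffs) {
  stopifnot(inherits(coeffs, "sh_coefficients"))
  orders <- sh_orders(coeffs$lmax)
  ls <- seq(0, coeffs$lmax, by = 2)
  E <- vapply(ls, function(l) {
    rowSums(coeffs$coefficients[, orders == l, drop = FALSE]^2)
  }, numeric(nrow(coeffs$coefficients)))
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  colnames(E) <- paste0("E", ls)
  structure(E, class = c("rish_features", "matrix", "array"), lmax = coeffs$lmax)
}

#' Site-to-reference harmonization scale maps
#'
#' For each voxel and each even order l, the scale factor is
#' s_l = sqrt(mean_ref(E_l) / mean_site(E_l)), the multiplier that maps the
#' site's group-mean SH power onto the reference's. Group means are arithmetic
#' means over the supplied control subjects (15-20 matched controls per site
#' suffice to capture group-level scanner properties). Where the site mean
#' power is zero there is no order-l energy to rescale and s_l is set to 1.
#'
#' @param site_features,reference_features lists of `rish_features` matrices
#'   (one per control subject), all on the same voxel grid.
#' @return A `scale_maps` matrix, voxels x orders.
#' @export
compute_scale_maps <- function(site_features, reference_features) {
  site_mean <- mean_feature(site_features)
  ref_mean <- mean_feature(reference_features)
  if (!identical(dim(site_mean), dim(ref_mean))) {
    stop("site and reference features must share the voxel grid")
  }
  s <- sqrt(ref_mean / site_mean)
  s[site_mean == 0] <- 1
  colnames(s) <- sub("^E", "s", colnames(site_mean))
  structure(s, class = c("scale_maps", "matrix", "array"))
}

mean_feature <- function(features) {
  if (inherits(features, "rish_features")) features <- list(features)
  stopifnot(length(features) >= 1)
  dims <- unique(lapply(features, dim))
  if (length(dims) != 1) stop("feature maps have mismatched voxel counts")
  Reduce(`+`, lapply(features, unclass)) / length(features)
}

#' Apply harmonization scale maps to SH coefficients
#'
#' Multiplies each voxel's order-l coefficients by its scale factor s_l and
#' resynthesizes the signal on the scheme's measurements. b = 0 columns carry
#' the voxel's stored b0 unchanged (only diffusion-weighted signal power is
#' rescaled). With unit maps the output is exactly the SH reconstruction of
#' the input.
#'
#' @param coeffs an `sh_coefficients` object.
#' @param maps a `scale_maps` matrix on the same voxel grid.
#' @param scheme a [gradient_scheme()] on which to resynthesize.
#' @return Numeric matrix, voxels x measurements.
#' @export
apply_harmonization <- function(coeffs, maps, scheme) {
  stopifnot(inherits(coeffs, "sh_coefficients"), inherits(scheme, "gradient_scheme"))
  if (nrow(maps) != nrow(coeffs$coefficients)) {
    stop("scale maps and coefficients are on different voxel grids")
  }
  harmonized <- harmonize_coefficients(coeffs, maps)
  B <- sh_basis(scheme$directions[scheme$dwi, , drop = FALSE], coeffs$lmax)
  out <- matrix(0, nrow(maps), length(scheme$bvalues))
  out[, !scheme$dwi] <- coeffs$b0
  out[, scheme$dwi] <- (harmonized$coefficients %*% t(B)) * coeffs$b0
  rownames(out) <- rownames(coeffs$coefficients)
  out
}

harmonize_coefficients <- function(coeffs, maps) {
  orders <- sh_orders(coeffs$lmax)
  ls <- seq(0, coeffs$lmax, by = 2)
  C <- coeffs$coefficients
  for (k in seq_along(ls)) {
    idx <- orders == ls[k]
    C[, idx] <- C[, idx, drop = FALSE] * maps[, k]
  }
  structure(list(coefficients = C, lmax = coeffs$lmax, b0 = coeffs$b0),
    class = "sh_coefficients"
  )
}
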