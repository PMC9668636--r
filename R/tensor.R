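#' Log-linear diffusion tensor fit and fractional anisotropy
#'
#' Fits the single diffusion tensor per voxel by ordinary least squares on the
#' log signal and returns fractional anisotropy
#' FA = sqrt(3/2) * sqrt(sum_i (lambda_i - mean(lambda))^2) / sqrt(sum_i lambda_i^2)
#' from the fitted eigenvalues, clamped to \[0, 1\].
#'
#' @param signals numeric matrix, voxels x measurements (strictly positive), or
#'   a single signal vector.
#' @param scheme a [gradient_scheme()] with at least six diffusion-weighted
#'   directions and one b = 0 measurement.
#' @return Numeric vector of FA values, one per voxel.
#' @examples
#' sch <- default_scheme(45)
#' sig <- synthesize_tensor_signal(diag(c(1.7e-3, 0.2e-3, 0.2e-3)), sch)
#' fit_tensor_fa(sig, sch)
#' @export
fit_tensor_fa <- function(signals, scheme) {
  ev <- fit_tensor_eigenvalues(signals, scheme)
  fa_from_eigenvalues(ev)
}

#' @describeIn fit_tensor_fa Fitted tensor eigenvalues (voxels x 3, descending).
#' @export
fit_tensor_eigenvalues <- function(signals, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  signals <- as.matrix(signals)
  if (ncol(signals) != length(scheme$bvalues)) {
    stop("`signals` columns must match the scheme's measurements")
  }
  if (any(signals <= 0)) {
    stop("tensor fit requires strictly positive signals (log-linear model)")
  }
  if (sum(scheme$dwi) < 6) stop("tensor fit requires >= 6 diffusion-weighted directions")
  X <- tensor_design(scheme)
  # columns: logS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
  beta <- t(solve(crossprod(X), crossprod(X, t(log(signals)))))
  D6 <- beta[, -1, drop = FALSE]
  ev <- eigvals_sym3(D6)
  rownames(ev) <- rownames(signals)
  ev
}

tensor_design <- function(scheme) {
  g <- scheme$directions
  b <- scheme$bvalues
  cbind(
    1,
    -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3], -2 * b * g[, 2] * g[, 3]
  )
}

#' @describeIn fit_tensor_fa FA from eigenvalue triples (matrix voxels x 3).
#' @param eigenvalues numeric matrix, voxels x 3.
#' @export
fa_from_eigenvalues <- function(eigenvalues) {
  if (is.null(dim(eigenvalues))) eigenvalues <- matrix(eigenvalues, nrow = 1)
  m <- rowMeans(eigenvalues)
  num <- sqrt(rowSums((eigenvalues - m)^2))
  den <- sqrt(rowSums(eigenvalues^2))
  fa <- sqrt(3 / 2) * num / den
  fa[den == 0] <- 0
  pmin(1, pmax(0, fa))
}

#' Synthesize noise-free single-tensor signals
#'
#' Mono-exponential signal S = S0 exp(-b g' D g) for one tensor or a batch of
#' axially symmetric tensors given by axis and eigenvalues.
#'
#' @param tensor 3 x 3 symmetric positive-definite matrix (mm^2/s).
#' @param scheme a [gradient_scheme()].
#' @param s0 b = 0 signal amplitude.
#' @return Signal vector along the scheme's measurements.
#' @export
synthesize_tensor_signal <- function(tensor, scheme, s0 = 1) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  g <- scheme$directions
  q <- rowSums((g %*% tensor) * g)
  s0 * exp(-scheme$bvalues * q)
}

# Batch signals for axially symmetric tensors: D = lambda_perp I +
# (lambda_par - lambda_perp) u u'. axes: n x 3 unit vectors. Returns n x nmeas.
axial_tensor_signals <- function(axes, lambda_par, lambda_perp, scheme) {
  g <- scheme$directions
  proj2 <- (axes %*% t(g))^2 # n x nmeas
  q <- lambda_perp + (lambda_par - lambda_perp) * proj2
  exp(-sweep(q, 2, scheme$bvalues, `*`))
}

# Axially symmetric eigenvalues with mean diffusivity `md` reaching target FA:
# lambda_par = md (1 + 2 delta), lambda_perp = md (1 - delta),
# delta = FA / sqrt(3 - 2 FA^2).
axial_eigenvalues_for_fa <- function(fa, md = 0.7e-3) {
  fa <- pmin(0.99, pmax(0, fa))
  delta <- fa / sqrt(3 - 2 * fa^2)
  list(par = md * (1 + 2 * delta), perp = md * (1 - delta))
}

#' Closed-form eigenvalues of symmetric 3 x 3 matrices (batch)
#'
#' Vectorised trigonometric solution for many symmetric 3 x 3 matrices given
#' as six-column rows (xx, yy, zz, xy, xz, yz); used to avoid per-voxel
#' `eigen()` calls in tensor fitting.
#'
#' @param D6 numeric matrix, n x 6.
#' @return n x 3 matrix of eigenvalues in descending order.
#' @export
eigvals_sym3 <- function(D6) {
  if (is.null(dim(D6))) D6 <- matrix(D6, nrow = 1)
  a <- D6[, 1]; b <- D6[, 2]; c <- D6[, 3]
  d <- D6[, 4]; e <- D6[, 5]; f <- D6[, 6]
  q <- (a + b + c) / 3
  p1 <- d^2 + e^2 + f^2
  p2 <- ((a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1) / 6
  p <- sqrt(pmax(p2, 0))
  # det((D - qI) / p) / 2, guarded for (near-)isotropic matrices
  aa <- a - q; bb <- b - q; cc <- c - q
  detB <- aa * (bb * cc - f^2) - d * (d * cc - f * e) + e * (d * f - bb * e)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  cbind(e1, e2, e3)
}
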