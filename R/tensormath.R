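# Internal tensor algebra on flattened symmetric 3x3 tensors.
#
# Throughout the package a tensor field is an N x 6 numeric matrix with
# columns (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) in mm^2/s, one row per voxel.
# Quadratic forms g' D g expand to w(g) . d with
# w = (gx^2, 2 gx gy, 2 gx gz, gy^2, 2 gy gz, gz^2).

TENSOR_COMP <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")

# design row for one unit gradient direction
design_row <- function(g) {
  c(g[1]^2, 2 * g[1] * g[2], 2 * g[1] * g[3], g[2]^2, 2 * g[2] * g[3], g[3]^2)
}

tensor_to_mat <- function(d) {
  matrix(c(d[1], d[2], d[3],
           d[2], d[4], d[5],
           d[3], d[5], d[6]), 3, 3)
}

mat_to_tensor <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

#' Fractional anisotropy from eigenvalues
#'
#' Standard definition: \eqn{FA = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\bar\lambda)^2} /
#' \sqrt{\sum_i \lambda_i^2}}. An all-zero eigenvalue triple yields FA = 0
#' rather than NaN. Negative eigenvalues are clamped to zero before the
#' formula is applied (the clamp is specific to FA; trace/AD/RD elsewhere use
#' raw eigenvalues) so FA stays in [0, 1].
#'
#' @param l1,l2,l3 numeric vectors of eigenvalues (any order).
#' @return numeric vector of FA values in [0, 1].
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  l1 <- pmax(l1, 0); l2 <- pmax(l2, 0); l3 <- pmax(l3, 0)
  m <- (l1 + l2 + l3) / 3
  num <- (l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- 0
  pmin(fa, 1)
}

# Eigenvalues (lambda2 = lambda3) of an axially symmetric tensor with given
# FA and axial diffusivity. Solves the quadratic
# (1 - 2 f^2) x^2 - 2 x + (1 - f^2) = 0 for x = lambda2/lambda1.
# Valid (positive lambda2) only for f below ~0.7035.
axial_lambdas <- function(fa, ad) {
  if (any(fa < 0) || any(fa >= 1)) {
    stop("FA must lie in [0, 1) for tensor parameterization")
  }
  ratio <- ifelse(
    abs(1 - 2 * fa^2) < 1e-12,
    (1 - fa^2) / 2,
    (1 - fa * sqrt(3 - 2 * fa^2)) / (1 - 2 * fa^2)
  )
  if (any(ratio <= 0)) {
    stop(sprintf(
      "no positive-eigenvalue axially symmetric tensor with FA = %.4g (max ~0.70)",
      max(fa)
    ))
  }
  if (any(ad <= 0)) stop("axial diffusivity must be positive")
  cbind(l1 = ad, l2 = ad * ratio, l3 = ad * ratio)
}

# Vectorized analytic eigenvalues of symmetric 3x3 tensors (rows of an
# N x 6 matrix), descending order. Trigonometric method; near-isotropic
# tensors collapse to the mean eigenvalue.
sym3_eigenvalues <- function(d) {
  dxx <- d[, 1]; dxy <- d[, 2]; dxz <- d[, 3]
  dyy <- d[, 4]; dyz <- d[, 5]; dzz <- d[, 6]
  q <- (dxx + dyy + dzz) / 3
  p1 <- dxy^2 + dxz^2 + dyz^2
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  axx <- dxx - q; ayy <- dyy - q; azz <- dzz - q
  detb <- axx * (ayy * azz - dyz^2) -
    dxy * (dxy * azz - dyz * dxz) +
    dxz * (dxy * dyz - ayy * dxz)
  r <- ifelse(p > 0, detb / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1 = l1, l2 = l2, l3 = l3)
  zero <- p2 == 0
  if (any(zero)) out[zero, ] <- cbind(q, q, q)[zero, ]
  out
}

# rotate a flattened tensor by rotation matrix R: R D R'
rotate_tensor <- function(d, R) {
  mat_to_tensor(R %*% tensor_to_mat(d) %*% t(R))
}
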