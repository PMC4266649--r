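# Diffusion tensor estimation and scalar maps.

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves \eqn{\ln(S_i/S_0) = -b\, g_i' D g_i} for the six unique
#' tensor components by ordinary (unweighted) least squares. \eqn{S_0} is the
#' mean of the b = 0 volumes. Voxels with \eqn{S_0 \le 0} or any
#' diffusion-weighted signal \eqn{\le 0} are marked invalid rather than
#' floor-clamped before the logarithm: a clamp would fabricate plausible but
#' wrong tensors, whereas a validity mask propagates cleanly.
#'
#' @param dwi 4D array grid x n_volumes, b0 volumes first (as produced by
#'   \code{\link{simulate_dwi}} or loaded via \code{\link{read_dwi}}).
#' @param scheme the matching \code{\link{acquisition_scheme}}.
#' @return object of class \code{dti_tensor_fit}: \code{tensors}
#'   (grid x 6 array, mm^2/s), \code{valid} (logical 3D array), \code{s0}
#'   (3D array).
#' @export
fit_tensor <- function(dwi, scheme) {
  d <- dim(dwi)
  if (length(d) != 4) stop("dwi must be a 4D array (grid x volumes)")
  nvol <- d[4]
  ndir <- nrow(scheme$directions)
  if (nvol != ndir + scheme$n_b0) {
    stop(sprintf("dwi has %d volumes but the scheme declares %d (%d dir + %d b0)",
                 nvol, ndir + scheme$n_b0, ndir, scheme$n_b0))
  }
  if (ndir < 6) stop("at least 6 gradient directions are required")

  X <- -scheme$b_value * t(apply(scheme$directions, 1, design_row))
  if (qr(X)$rank < 6) {
    stop("gradient scheme is rank-deficient: directions do not span the 6 tensor components")
  }
  pinv <- X %*% solve(crossprod(X))        # ndir x 6; D = L %*% pinv

  nvox <- prod(d[1:3])
  vols <- matrix(dwi, nvox, nvol)
  s0 <- rowMeans(vols[, seq_len(scheme$n_b0), drop = FALSE])
  S <- vols[, scheme$n_b0 + seq_len(ndir), drop = FALSE]

  valid <- s0 > 0 & matrixStats_all_positive(S)
  D <- matrix(NA_real_, nvox, 6)
  if (any(valid)) {
    L <- log(S[valid, , drop = FALSE] / s0[valid])
    D[valid, ] <- L %*% pinv
  }
  structure(
    list(tensors = array(D, dim = c(d[1:3], 6)),
         valid = array(valid, dim = d[1:3]),
         s0 = array(s0, dim = d[1:3]),
         scheme = scheme,
         voxel_size = attr(dwi, "voxel_size")),
    class = "dti_tensor_fit"
  )
}

# rowwise all-positive without building a huge logical intermediate twice
matrixStats_all_positive <- function(m) {
  out <- rep(TRUE, nrow(m))
  for (j in seq_len(ncol(m))) out <- out & m[, j] > 0
  out
}

#' @export
print.dti_tensor_fit <- function(x, ...) {
  d <- dim(x$valid)
  cat(sprintf("Diffusion tensor fit: %s grid, %d/%d valid voxels\n",
              paste(d, collapse = "x"), sum(x$valid), prod(d)))
  invisible(x)
}

#' Eigendecompose a tensor field
#'
#' Returns eigenvalues in descending order per voxel. With
#' \code{vectors = FALSE} (the default) a vectorized closed-form solver for
#' symmetric 3x3 matrices is used; with \code{vectors = TRUE} each valid voxel
#' is decomposed with \code{\link[base]{eigen}} so that values and principal
#' eigenvectors are mutually consistent to LAPACK accuracy. Negative
#' eigenvalues are retained (and counted) rather than clamped; the FA-specific
#' clamp happens in \code{\link{compute_scalars}}.
#'
#' @param tensors grid x 6 array, or a \code{dti_tensor_fit}.
#' @param valid optional logical mask; defaults to the fit's mask or all-TRUE.
#' @param vectors also return principal eigenvectors.
#' @return list with \code{values} (grid x 3 array, descending),
#'   \code{vectors} (grid x 3 array or NULL), \code{n_negative} (count of
#'   negative eigenvalues on valid voxels), \code{valid}.
#' @export
dti_eigen <- function(tensors, valid = NULL, vectors = FALSE) {
  if (inherits(tensors, "dti_tensor_fit")) {
    if (is.null(valid)) valid <- tensors$valid
    tensors <- tensors$tensors
  }
  d <- dim(tensors)
  if (length(d) != 4 || d[4] != 6) stop("tensors must be a grid x 6 array")
  nvox <- prod(d[1:3])
  if (is.null(valid)) valid <- array(TRUE, dim = d[1:3])
  D <- matrix(tensors, nvox, 6)
  vidx <- which(as.vector(valid) & !is.na(D[, 1]))

  vals <- matrix(NA_real_, nvox, 3)
  vecs <- NULL
  if (vectors) {
    vecs <- matrix(NA_real_, nvox, 3)
    for (i in vidx) {
      e <- eigen(tensor_to_mat(D[i, ]), symmetric = TRUE)
      vals[i, ] <- e$values
      vecs[i, ] <- e$vectors[, 1]
    }
    vecs <- array(vecs, dim = c(d[1:3], 3))
  } else if (length(vidx)) {
    vals[vidx, ] <- sym3_eigenvalues(D[vidx, , drop = FALSE])
  }
  list(values = array(vals, dim = c(d[1:3], 3)),
       vectors = vecs,
       n_negative = sum(vals[vidx, ] < 0),
       valid = valid & !is.na(array(D[, 1], dim = d[1:3])))
}

#' Compute FA, trace, AD and RD maps from eigenvalues
#'
#' FA uses the standard normalized eigenvalue-dispersion formula with negative
#' eigenvalues clamped to zero first (all-zero triples give FA = 0). Trace,
#' AD and RD use the raw eigenvalues: trace = lambda1+lambda2+lambda3,
#' AD = lambda1, RD = (lambda2+lambda3)/2. Keeping trace un-clamped preserves
#' the CSF-exclusion contrast, which is exactly where clamping would bite.
#'
#' @param eig result of \code{\link{dti_eigen}}.
#' @param voxel_size optional numeric 3-vector carried as metadata.
#' @return object of class \code{dti_scalars}: \code{fa}, \code{trace},
#'   \code{ad}, \code{rd} (3D arrays) and \code{valid}.
#' @export
compute_scalars <- function(eig, voxel_size = NULL) {
  v <- eig$values
  d <- dim(v)[1:3]
  l1 <- v[, , , 1]; l2 <- v[, , , 2]; l3 <- v[, , , 3]
  scalars <- list(
    fa = array(fa_from_eigenvalues(l1, l2, l3), dim = d),
    trace = array(l1 + l2 + l3, dim = d),
    ad = array(l1, dim = d),
    rd = array((l2 + l3) / 2, dim = d),
    valid = eig$valid,
    voxel_size = voxel_size
  )
  structure(scalars, class = "dti_scalars")
}

#' Scalar maps from precomputed volumes
#'
#' Entry point for real-data mode: wrap already-computed FA/trace/AD/RD
#' volumes (e.g. from scanner or third-party software) in the container the
#' segmentation consumes, bypassing tensor fitting.
#'
#' @param fa,trace,ad,rd numeric 3D arrays on a shared grid.
#' @param valid optional logical mask; defaults to finite FA.
#' @param voxel_size optional numeric 3-vector.
#' @return a \code{dti_scalars}.
#' @export
subject_scalars <- function(fa, trace, ad, rd, valid = NULL, voxel_size = NULL) {
  dims <- list(dim(fa), dim(trace), dim(ad), dim(rd))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("fa/trace/ad/rd maps must share a grid")
  }
  if (is.null(valid)) valid <- array(is.finite(fa), dim = dim(fa))
  structure(list(fa = fa, trace = trace, ad = ad, rd = rd, valid = valid,
                 voxel_size = voxel_size),
            class = "dti_scalars")
}

#' Fit tensors and compute scalar maps in one step
#'
#' @param dwi 4D DWI array.
#' @param scheme acquisition scheme.
#' @return a \code{dti_scalars}.
#' @export
dwi_to_scalars <- function(dwi, scheme) {
  fit <- fit_tensor(dwi, scheme)
  eig <- dti_eigen(fit)
  compute_scalars(eig, voxel_size = fit$voxel_size)
}

#' @export
print.dti_scalars <- function(x, ...) {
  d <- dim(x$fa)
  ok <- x$valid
  cat(sprintf("DTI scalar maps (%s), %d valid voxels\n",
              paste(d, collapse = "x"), sum(ok)))
  cat(sprintf("  FA range %.3f-%.3f, median trace %.2e mm^2/s\n",
              min(x$fa[ok]), max(x$fa[ok]), stats::median(x$trace[ok])))
  invisible(x)
}
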