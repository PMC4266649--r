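# Synthetic neonatal brain phantom: geometric label template, per-subject
# ground-truth tensor fields, and Rician-noise DWI simulation.
#
# The geometry is deliberately abstract (mirrored rectangular blocks inside a
# grey-matter filler, wrapped in a GM shell and a CSF rim): the downstream
# analysis needs co-registered labels plus realistic scalar contrast, not
# anatomy. Registration is out of scope and every subject shares the template
# grid exactly.

# ---- template geometry -----------------------------------------------------

# choose a slot grid (a, b, c) for n blocks inside a zone, maximizing the
# smallest achievable block edge
choose_slots <- function(n, zone) {
  best <- NULL
  for (a in 1:max(1, n)) for (b in 1:max(1, n)) {
    cc <- ceiling(n / (a * b))
    if (a * b * cc < n) next
    slot <- floor(zone / c(a, b, cc))
    score <- min(slot)
    if (is.null(best) || score > best$score) {
      best <- list(dims = c(a, b, cc), slot = slot, score = score)
    }
  }
  best
}

#' Build the phantom label template
#'
#' Lays out the white-matter regions of \code{region_table} as non-overlapping
#' rectangular blocks, mirrored across the mid-sagittal plane for bilateral
#' regions, inside a grey-matter interior. The interior is wrapped in a
#' 2-voxel GM shell and a 2-voxel CSF rim, so partial-volume mixing occurs at
#' every WM/GM and GM/CSF interface. Label conventions: 0 background (unused
#' by the default geometry), 98 grey matter, 99 CSF, region \code{label_id}s
#' elsewhere.
#'
#' @param region_table data.frame as returned by
#'   \code{\link{neonatal_region_table}}; may be empty.
#' @param grid_shape integer 3-vector of voxel dimensions.
#' @param voxel_size numeric 3-vector, mm.
#' @param max_block maximum block edge length in voxels; blocks take as much
#'   of their slot as allowed, capped here.
#' @return integer 3D array of labels with attributes \code{voxel_size} and
#'   \code{region_table}.
#' @export
build_template <- function(region_table = neonatal_region_table(),
                           grid_shape = c(48L, 48L, 48L),
                           voxel_size = c(1.5625, 1.5625, 3),
                           max_block = 10L) {
  validate_region_table(region_table)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 12)) {
    stop("grid_shape must be three dimensions of at least 12 voxels")
  }
  labels <- array(CSF_LABEL, dim = grid_shape)
  n <- grid_shape
  gm_lo <- c(3L, 3L, 3L); gm_hi <- n - 2L
  labels[gm_lo[1]:gm_hi[1], gm_lo[2]:gm_hi[2], gm_lo[3]:gm_hi[3]] <- GM_LABEL

  if (nrow(region_table) > 0) {
    int_lo <- c(5L, 5L, 5L); int_hi <- n - 4L
    zone_yz <- int_hi[2:3] - int_lo[2:3] + 1L
    width_x <- int_hi[1] - int_lo[1] + 1L
    half <- (width_x - 2L) %/% 2L          # 2-voxel GM gap at the midline
    left_x <- c(int_lo[1], int_lo[1] + half - 1L)

    names_u <- unique(region_table$name)
    pick <- choose_slots(length(names_u), c(half, zone_yz))
    slot <- pick$slot
    block <- pmin(slot - 2L, max_block)
    too_small <- which(block < 3L)
    if (length(too_small)) {
      stop(sprintf(
        "grid too small to place region '%s': slot %s allows block edge %d < 3",
        names_u[1], paste(slot, collapse = "x"), min(block)
      ))
    }
    dims <- pick$dims
    place <- function(lo, len, blk) {        # centered block range in a slot
      start <- lo + (len - blk) %/% 2L
      start:(start + blk - 1L)
    }
    slot_of <- function(k) {                 # k-th slot -> (i, j, l) indices
      k0 <- k - 1L
      c(k0 %% dims[1],
        (k0 %/% dims[1]) %% dims[2],
        k0 %/% (dims[1] * dims[2]))
    }
    for (k in seq_along(names_u)) {
      nm <- names_u[k]
      rows <- region_table[region_table$name == nm, , drop = FALSE]
      s <- slot_of(k)
      xs <- place(left_x[1] + s[1] * slot[1], slot[1], block[1])
      ys <- place(int_lo[2] + s[2] * slot[2], slot[2], block[2])
      zs <- place(int_lo[3] + s[3] * slot[3], slot[3], block[3])
      for (r in seq_len(nrow(rows))) {
        hemi <- rows$hemisphere[r]
        rx <- switch(hemi,
          left = xs,
          right = n[1] + 1L - rev(xs),       # mirror across the midline
          midline = {
            mid <- (n[1] + 1L) / 2
            shift <- as.integer(round(mid - (xs[1] + xs[length(xs)]) / 2))
            xs + shift
          })
        if (min(rx) < int_lo[1] || max(rx) > int_hi[1]) {
          stop(sprintf("grid too small to place region '%s' (%s)", nm, hemi))
        }
        labels[rx, ys, zs] <- rows$label_id[r]
      }
    }
    ids <- region_table$label_id
    counts <- tabulate(labels[labels %in% ids], nbins = max(ids))[ids]
    if (any(counts < 50)) {
      stop(sprintf("grid too small: region '%s' received %d voxels (< 50)",
                   region_table$name[which.min(counts)], min(counts)))
    }
  }
  attr(labels, "voxel_size") <- voxel_size
  attr(labels, "region_table") <- region_table
  labels
}

# logical mask of voxels whose full 6-neighborhood shares their label
# (edge voxels clamp to themselves and so count as interior w.r.t. the edge)
#' Interior (non-boundary) voxel mask of a label volume
#'
#' TRUE where all six face neighbors carry the voxel's own label; the
#' complement is the 1-voxel partial-volume boundary band.
#'
#' @param labels integer 3D label array.
#' @return logical array of the same shape.
#' @export
interior_mask <- function(labels) {
  d <- dim(labels)
  same <- array(TRUE, dim = d)
  idx <- function(n, off) pmin(pmax(seq_len(n) + off, 1L), n)
  for (ax in 1:3) for (off in c(-1L, 1L)) {
    ii <- lapply(d, seq_len)
    ii[[ax]] <- idx(d[ax], off)
    same <- same & (labels == labels[ii[[1]], ii[[2]], ii[[3]]])
  }
  same
}

# ---- subject tensor fields -------------------------------------------------

# effective eigenvalues of a two-population orthogonal crossing mixture
# built from axially symmetric populations with eigenvalue ratio derived
# from population FA f (ad scale cancels in FA)
crossing_eigs <- function(f, cfrac) {
  lam <- axial_lambdas(f, 1)
  a <- lam[1]; b <- lam[2]
  c((1 - cfrac) * a + cfrac * b, (1 - cfrac) * b + cfrac * a, b)
}

# population FA so that the voxel-level crossing mixture attains target FA
calibrate_crossing <- function(target_fa, cfrac) {
  if (target_fa < 1e-12) return(0)
  f_of <- function(f) {
    e <- crossing_eigs(f, cfrac)
    fa_from_eigenvalues(e[1], e[2], e[3]) - target_fa
  }
  upper <- 0.70
  if (f_of(upper) < 0) {
    stop(sprintf(
      "crossing mixture (fraction %.2f) cannot reach FA = %.3f", cfrac, target_fa
    ))
  }
  stats::uniroot(f_of, c(target_fa, upper), tol = 1e-12)$root
}

# CSF: isotropic, diffusivity 3e-3 mm^2/s per axis -> trace 9e-3, well above
# the 6e-3 exclusion cutoff
CSF_LAMBDA <- 3e-3
GM_MD <- 1.1e-3

#' Sample one subject's ground-truth tensor field
#'
#' Fills the template with per-compartment diffusion tensors. Each WM region
#' gets the subject's target FA (region target plus a between-subject offset)
#' and target axial diffusivity exactly in its interior; principal
#' orientations follow the region's \code{orientation_mode}. CSF voxels are
#' isotropic with trace 9e-3 mm^2/s; GM voxels draw FA uniformly from
#' [0.02, 0.12] at mean diffusivity 1.1e-3 mm^2/s. Voxels within one voxel of
#' a compartment border receive the 7-point stencil average of the adjacent
#' pure tensors (partial-volume model).
#'
#' @param template label array from \code{\link{build_template}}.
#' @param region_table matching region table.
#' @param subject_effects optional numeric vector of per-row FA offsets; when
#'   NULL they are drawn as Normal(0, target_fa_sd) under \code{seed}.
#' @param seed integer RNG seed for effects and the GM FA field.
#' @return list with \code{tensors} (array grid x 6, mm^2/s),
#'   \code{subject_fa} (realized per-row target FA), \code{effects}.
#' @export
sample_subject_tensors <- function(template, region_table = attr(template, "region_table"),
                                   subject_effects = NULL, seed = 1) {
  validate_region_table(region_table)
  d <- dim(template)
  nvox <- prod(d)
  set.seed(seed)
  if (is.null(subject_effects)) {
    subject_effects <- stats::rnorm(nrow(region_table), 0, region_table$target_fa_sd)
  }
  subject_fa <- pmin(pmax(region_table$target_fa_mean + subject_effects, 0), 0.68)

  lab <- as.integer(template)
  D <- matrix(0, nvox, 6)

  csf <- lab == CSF_LABEL
  D[csf, c(1, 4, 6)] <- CSF_LAMBDA

  gm <- which(lab == GM_LABEL)
  if (length(gm)) {
    gm_fa <- stats::runif(length(gm), 0.02, 0.12)
    lam <- axial_lambdas(gm_fa, 1)
    scale <- 3 * GM_MD / rowSums(lam)
    D[gm, 1] <- lam[, 1] * scale
    D[gm, 4] <- lam[, 2] * scale
    D[gm, 6] <- lam[, 3] * scale
  }

  coords_y <- NULL
  for (r in seq_len(nrow(region_table))) {
    idx <- which(lab == region_table$label_id[r])
    if (!length(idx)) next
    fa_s <- subject_fa[r]
    ad <- region_table$target_ad_mean[r]
    mode <- region_table$orientation_mode[r]
    if (mode == "uniform-axis") {
      lam <- axial_lambdas(fa_s, ad)
      axis <- (region_table$label_id[r] - 1L) %% 3L  # 0=x, 1=y, 2=z
      diagc <- switch(axis + 1L,
                      c(1, 4, 6),   # lambda1 along x
                      c(4, 1, 6),   # along y
                      c(6, 4, 1))   # along z
      D[idx, diagc[1]] <- lam[1]
      D[idx, diagc[2]] <- lam[2]
      D[idx, diagc[3]] <- lam[3]
    } else if (mode == "smoothly-varying") {
      lam <- axial_lambdas(fa_s, ad)
      a <- lam[1]; b <- lam[2]
      if (is.null(coords_y)) {
        coords_y <- as.integer((seq_len(nvox) - 1L) %/% d[1] %% d[2]) + 1L
      }
      y <- coords_y[idx]
      span <- max(max(y) - min(y), 1L)
      th <- (y - min(y)) / span * (pi / 4)   # axis sweeps 45 deg across region
      ct <- cos(th); st <- sin(th)
      D[idx, 1] <- a * ct^2 + b * st^2
      D[idx, 6] <- a * st^2 + b * ct^2
      D[idx, 3] <- (a - b) * ct * st
      D[idx, 4] <- b
    } else {                                  # crossing
      cfrac <- region_table$crossing_fraction[r]
      f_pop <- calibrate_crossing(fa_s, cfrac)
      e <- crossing_eigs(f_pop, cfrac)
      e <- e * (ad / e[1])                    # rescale so lambda1 = target AD
      D[idx, 1] <- e[1]; D[idx, 4] <- e[2]; D[idx, 6] <- e[3]
    }
  }

  # partial volume: 7-point stencil average at compartment boundaries
  interior <- interior_mask(template)
  if (any(!interior)) {
    acc <- D
    idxseq <- function(n, off) pmin(pmax(seq_len(n) + off, 1L), n)
    for (axd in 1:3) for (off in c(-1L, 1L)) {
      ii <- lapply(d, seq_len)
      ii[[axd]] <- idxseq(d[axd], off)
      shift_lin <- as.vector(array(seq_len(nvox), dim = d)[ii[[1]], ii[[2]], ii[[3]]])
      acc <- acc + D[shift_lin, , drop = FALSE]
    }
    mixed <- acc / 7
    bidx <- which(!as.vector(interior))
    D[bidx, ] <- mixed[bidx, ]
  }

  tens <- array(D, dim = c(d, 6))
  attr(tens, "voxel_size") <- attr(template, "voxel_size")
  list(tensors = tens, subject_fa = subject_fa, effects = subject_effects)
}

# ---- DWI simulation --------------------------------------------------------

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Monoexponential signal model \eqn{S = S_0 \exp(-b\, g' D g)} per gradient
#' direction, with \code{n_b0} unweighted volumes first. Noise is Rician: the
#' magnitude of the noise-free signal perturbed by complex Gaussian noise of
#' channel SD \code{s0 / snr}. \code{snr = Inf} is the noise-free sentinel and
#' returns exact signals.
#'
#' @param tensors array grid x 6 of tensor components (mm^2/s).
#' @param scheme a \code{\link{acquisition_scheme}}.
#' @param s0 unweighted signal amplitude.
#' @param snr signal-to-noise ratio s0/sigma; \code{Inf} for noise-free.
#' @param seed integer seed fixing the noise stream.
#' @return 4D array grid x n_volumes, volumes ordered as \code{scheme$bvals}.
#' @export
simulate_dwi <- function(tensors, scheme = default_scheme(), s0 = 1000,
                         snr = 30, seed = 1) {
  d <- dim(tensors)
  if (length(d) != 4 || d[4] != 6) stop("tensors must be a grid x 6 array")
  nvox <- prod(d[1:3])
  D <- matrix(tensors, nvox, 6)

  ev <- sym3_eigenvalues(D)
  bad <- which(ev[, 3] < -1e-10)
  if (length(bad)) {
    at <- arrayInd(bad[1], d[1:3])
    stop(sprintf("non-positive-semidefinite tensor at voxel [%d, %d, %d]",
                 at[1], at[2], at[3]))
  }

  W <- t(apply(scheme$directions, 1, design_row))   # ndir x 6
  S <- s0 * exp(-scheme$b_value * tcrossprod(D, W)) # nvox x ndir
  vols <- cbind(matrix(s0, nvox, scheme$n_b0), S)

  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be positive (or Inf for noise-free)")
    sigma <- s0 / snr
    set.seed(seed)
    n1 <- matrix(stats::rnorm(length(vols), 0, sigma), nrow(vols))
    n2 <- matrix(stats::rnorm(length(vols), 0, sigma), nrow(vols))
    vols <- sqrt((vols + n1)^2 + n2^2)
  }
  out <- array(vols, dim = c(d[1:3], ncol(vols)))
  attr(out, "voxel_size") <- attr(tensors, "voxel_size")
  out
}

# ---- cohort ----------------------------------------------------------------

#' Simulate a phantom cohort
#'
#' Generates \code{n_subjects} synthetic brains on a shared label template:
#' per subject, a ground-truth tensor field with between-subject regional FA
#' offsets, and a noisy DWI acquisition under \code{scheme}. Fully
#' deterministic for fixed arguments and \code{seed}.
#'
#' @param n_subjects cohort size.
#' @param region_table region definitions (see \code{\link{neonatal_region_table}}).
#' @param grid_shape,voxel_size,max_block template geometry, passed to
#'   \code{\link{build_template}}.
#' @param scheme acquisition scheme.
#' @param s0,snr signal amplitude and SNR for \code{\link{simulate_dwi}}.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param keep_tensors keep ground-truth tensor fields in the object.
#' @return object of class \code{dti_phantom_cohort}.
#' @export
simulate_phantom_cohort <- function(n_subjects = 8,
                                    region_table = neonatal_region_table(),
                                    grid_shape = c(48L, 48L, 48L),
                                    voxel_size = c(1.5625, 1.5625, 3),
                                    max_block = 10L,
                                    scheme = default_scheme(),
                                    s0 = 1000, snr = 30, seed = 1,
                                    keep_tensors = TRUE) {
  template <- build_template(region_table, grid_shape, voxel_size, max_block)
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_subjects),
                      ncol = 2)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    gt <- sample_subject_tensors(template, region_table, seed = sub_seeds[i, 1])
    dwi <- simulate_dwi(gt$tensors, scheme, s0 = s0, snr = snr,
                        seed = sub_seeds[i, 2])
    subjects[[i]] <- list(
      id = sprintf("sub-%03d", i),
      dwi = dwi,
      tensors = if (keep_tensors) gt$tensors else NULL,
      subject_fa = gt$subject_fa
    )
  }
  structure(
    list(template = template, region_table = region_table, scheme = scheme,
         grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         s0 = s0, snr = snr, seed = seed, subjects = subjects),
    class = "dti_phantom_cohort"
  )
}

#' @export
print.dti_phantom_cohort <- function(x, ...) {
  cat("Synthetic neonatal DTI phantom cohort\n")
  cat(sprintf("  subjects: %d   grid: %s   voxel (mm): %s\n",
              length(x$subjects), paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  cat(sprintf("  regions: %d (%d bilateral names)   SNR: %s   seed: %d\n",
              nrow(x$region_table), length(unique(x$region_table$name)),
              format(x$snr), x$seed))
  cat(sprintf("  acquisition: %d directions + %d b0 at b = %g s/mm^2\n",
              nrow(x$scheme$directions), x$scheme$n_b0, x$scheme$b_value))
  invisible(x)
}
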