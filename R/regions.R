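#' Default neonatal white-matter region table
#'
#' Twelve bilateral subcortical white-matter regions spanning the range of
#' maturation seen at near-term age, from the anterior corona radiata (ACR,
#' target FA ~0.15, largely unmyelinated and containing crossing fibers) to
#' the posterior limb of the internal capsule (PLIC, target FA ~0.5, the most
#' mature tract at term). Each region appears twice, once per hemisphere, with
#' its own integer label. Target axial diffusivities are in the neonatal range
#' (1.2--1.9e-3 mm^2/s), with the corpus callosum assigned the highest AD.
#'
#' Columns:
#' \describe{
#'   \item{name}{short region label (ACR, PLIC, ...)}
#'   \item{hemisphere}{"left", "right" or "midline"}
#'   \item{label_id}{unique positive integer used in the label volume}
#'   \item{target_fa_mean}{cohort-mean FA the generator aims for, in [0,1)}
#'   \item{target_fa_sd}{between-subject SD of the regional FA}
#'   \item{target_ad_mean}{axial diffusivity lambda1, mm^2/s}
#'   \item{orientation_mode}{"uniform-axis", "smoothly-varying" or "crossing"}
#'   \item{crossing_fraction}{second-population mixing weight, nonzero only
#'     in crossing mode}
#' }
#'
#' @return a data.frame with 24 rows (12 regions x 2 hemispheres).
#' @export
neonatal_region_table <- function() {
  base <- data.frame(
    name = c("ACR", "EC", "SCR", "PCR", "ALIC", "PTR",
             "SS", "CC-genu", "CC-splenium", "RLC", "CereP", "PLIC"),
    target_fa_mean = c(0.15, 0.18, 0.20, 0.22, 0.24, 0.28,
                       0.30, 0.32, 0.38, 0.40, 0.45, 0.50),
    target_fa_sd = c(0.020, 0.020, 0.020, 0.020, 0.020, 0.020,
                     0.020, 0.025, 0.025, 0.020, 0.020, 0.020),
    target_ad_mean = c(1.45e-3, 1.40e-3, 1.50e-3, 1.50e-3, 1.40e-3, 1.55e-3,
                       1.55e-3, 1.90e-3, 1.85e-3, 1.50e-3, 1.55e-3, 1.60e-3),
    orientation_mode = c("crossing", "uniform-axis", "crossing", "uniform-axis",
                         "uniform-axis", "uniform-axis", "uniform-axis",
                         "smoothly-varying", "smoothly-varying",
                         "uniform-axis", "uniform-axis", "uniform-axis"),
    crossing_fraction = c(0.30, 0, 0.30, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  left <- transform(base, hemisphere = "left", label_id = seq_len(nrow(base)))
  right <- transform(base, hemisphere = "right",
                     label_id = nrow(base) + seq_len(nrow(base)))
  out <- rbind(left, right)
  rownames(out) <- NULL
  out[, c("name", "hemisphere", "label_id", "target_fa_mean", "target_fa_sd",
          "target_ad_mean", "orientation_mode", "crossing_fraction")]
}

# Reserved labels for the non-WM compartments; region label_ids must avoid
# them. Background is 0.
GM_LABEL <- 98L
CSF_LABEL <- 99L

validate_region_table <- function(region_table) {
  req <- c("name", "hemisphere", "label_id", "target_fa_mean", "target_fa_sd",
           "target_ad_mean", "orientation_mode", "crossing_fraction")
  missing <- setdiff(req, names(region_table))
  if (length(missing)) {
    stop("region table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(region_table) == 0) return(invisible(region_table))
  if (anyDuplicated(region_table$label_id)) {
    stop("region label_id values must be unique")
  }
  if (any(region_table$label_id %in% c(0L, GM_LABEL, CSF_LABEL))) {
    stop("region label_id collides with background/GM/CSF labels (0, 98, 99)")
  }
  if (any(region_table$label_id <= 0)) stop("label_id must be positive")
  with(region_table, {
    if (any(target_fa_mean < 0 | target_fa_mean >= 1)) {
      stop("target_fa_mean must lie in [0, 1)")
    }
    if (any(target_fa_mean + 3 * target_fa_sd >= 1)) {
      stop("target_fa_mean + 3*target_fa_sd must stay below 1")
    }
    if (any(target_ad_mean <= 0)) stop("target_ad_mean must be positive")
    if (!all(orientation_mode %in%
             c("uniform-axis", "smoothly-varying", "crossing"))) {
      stop("unknown orientation_mode")
    }
    if (any(crossing_fraction < 0 | crossing_fraction > 1)) {
      stop("crossing_fraction must lie in [0, 1]")
    }
    if (any(crossing_fraction > 0 & orientation_mode != "crossing")) {
      stop("crossing_fraction > 0 requires orientation_mode = 'crossing'")
    }
    if (!all(hemisphere %in% c("left", "right", "midline"))) {
      stop("hemisphere must be left, right or midline")
    }
  })
  invisible(region_table)
}

#' Diffusion acquisition scheme
#'
#' A single-shell scheme: a number of b = 0 volumes followed by
#' diffusion-weighted volumes along unit gradient directions at one b-value.
#'
#' @param directions numeric n x 3 matrix of unit gradient directions.
#' @param b_value diffusion weighting in s/mm^2.
#' @param n_b0 number of unweighted (b = 0) volumes, at least 1.
#' @return an object of class \code{dti_scheme} with elements
#'   \code{directions}, \code{b_value}, \code{n_b0}, \code{bvals} (one entry
#'   per volume, b0 volumes first).
#' @export
acquisition_scheme <- function(directions, b_value = 1000, n_b0 = 3) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3 || nrow(directions) < 1) {
    stop("directions must be a non-empty n x 3 matrix")
  }
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8)) {
    stop("gradient directions must have unit norm (tolerance 1e-8)")
  }
  if (n_b0 < 1) stop("at least one b = 0 volume is required")
  if (b_value <= 0) stop("b_value must be positive")
  structure(
    list(directions = directions, b_value = b_value, n_b0 = as.integer(n_b0),
         bvals = c(rep(0, n_b0), rep(b_value, nrow(directions)))),
    class = "dti_scheme"
  )
}

#' Default 25-direction neonatal acquisition scheme
#'
#' 25 gradient directions distributed by electrostatic repulsion on the
#' sphere, three b = 0 volumes, b = 1000 s/mm^2 -- the direction count and
#' weighting typical of clinical neonatal DTI protocols. The direction set
#' ships with the package as FSL-style bvec/bval text files.
#'
#' @return a \code{dti_scheme}.
#' @export
default_scheme <- function() {
  bv <- read_bvec_bval(
    system.file("extdata", "neonatal25.bvec", package = "dtithresh"),
    system.file("extdata", "neonatal25.bval", package = "dtithresh")
  )
  scheme_from_table(bv$bvecs, bv$bvals)
}

# Build a scheme from FSL-style tables (directions as columns of a 3 x n
# matrix, bvals per volume). b0 volumes may appear anywhere; they are moved
# to the front, which matches how the simulator and fitter index volumes.
scheme_from_table <- function(bvecs, bvals) {
  b0 <- bvals == 0
  if (!any(b0)) stop("gradient table contains no b = 0 volume")
  dwi <- which(!b0)
  if (length(unique(bvals[dwi])) != 1) {
    stop("only single-shell schemes are supported")
  }
  acquisition_scheme(t(bvecs[, dwi, drop = FALSE]),
                     b_value = bvals[dwi][1], n_b0 = sum(b0))
}
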