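# Masking cascade: atlas labels -> trace-based CSF exclusion -> FA
# thresholds -> minimum-voxel rule.

#' Threshold configuration
#'
#' Defaults follow standard practice for neonatal atlas-based segmentation:
#' CSF excluded where trace exceeds 0.006 mm^2/s, white matter retained above
#' each of the FA cutoffs 0.15 / 0.20 / 0.25, and any region-condition cell
#' with fewer than 10 voxels dropped. Both thresholds are strict: a voxel with
#' trace exactly at the cutoff is retained in the base mask, and a voxel with
#' FA exactly at a cutoff is excluded from that FA condition.
#'
#' @param trace_cutoff CSF exclusion cutoff, mm^2/s.
#' @param fa_cutoffs strictly increasing FA cutoffs in (0, 1).
#' @param min_voxels minimum voxels for a cell to be analyzed (>= 1).
#' @return object of class \code{dti_threshold_config}.
#' @export
threshold_config <- function(trace_cutoff = 0.006,
                             fa_cutoffs = c(0.15, 0.20, 0.25),
                             min_voxels = 10L) {
  if (trace_cutoff <= 0) stop("trace_cutoff must be positive")
  if (length(fa_cutoffs) < 1 || any(fa_cutoffs <= 0 | fa_cutoffs >= 1)) {
    stop("fa_cutoffs must lie in (0, 1)")
  }
  if (is.unsorted(fa_cutoffs, strictly = TRUE)) {
    stop("fa_cutoffs must be strictly increasing")
  }
  if (min_voxels < 1) stop("min_voxels must be at least 1")
  structure(
    list(trace_cutoff = trace_cutoff, fa_cutoffs = fa_cutoffs,
         min_voxels = as.integer(min_voxels)),
    class = "dti_threshold_config"
  )
}

#' Condition labels for a threshold configuration
#'
#' The base condition (atlas label minus CSF) followed by one condition per
#' FA cutoff, e.g. \code{"base", "FA>0.15", "FA>0.20", "FA>0.25"}.
#'
#' @param config a \code{\link{threshold_config}}.
#' @return character vector of condition names in analysis order.
#' @export
condition_labels <- function(config) {
  c("base", sprintf("FA>%.2f", config$fa_cutoffs))
}

#' Base (CSF-excluded) region masks
#'
#' For each region: voxels carrying the region's atlas label, valid under the
#' scalar validity mask, and with trace at or below the cutoff (exclusion is
#' strict \code{trace > cutoff}, so ties are retained).
#'
#' @param labels integer label array co-registered with the scalars.
#' @param scalars a \code{dti_scalars} on the same grid.
#' @param region_table region table (name, hemisphere, label_id, ...).
#' @param config a \code{\link{threshold_config}}.
#' @return named list (one entry per region row, named
#'   \code{"<name>|<hemisphere>"}) of integer voxel indices.
#' @export
base_mask <- function(labels, scalars, region_table, config = threshold_config()) {
  if (!identical(dim(labels), dim(scalars$trace))) {
    stop(sprintf("label grid (%s) does not match scalar grid (%s)",
                 paste(dim(labels), collapse = "x"),
                 paste(dim(scalars$trace), collapse = "x")))
  }
  lab <- as.integer(labels)
  keep <- as.vector(scalars$valid) & as.vector(scalars$trace) <= config$trace_cutoff
  out <- vector("list", nrow(region_table))
  names(out) <- paste(region_table$name, region_table$hemisphere, sep = "|")
  for (r in seq_len(nrow(region_table))) {
    idx <- which(lab == region_table$label_id[r])
    if (!length(idx)) {
      warning(sprintf("region '%s' (%s) absent from the label volume",
                      region_table$name[r], region_table$hemisphere[r]))
    }
    out[[r]] <- idx[keep[idx]]
  }
  out
}

#' FA-threshold mask set
#'
#' Applies each FA cutoff (strict \code{FA > t}) to the base masks, producing
#' the nested per-region, per-condition mask set. Nesting
#' \code{mask(t2) subset-of mask(t1) subset-of base} for \code{t2 > t1} holds
#' by construction.
#'
#' @param base named list of base masks from \code{\link{base_mask}}.
#' @param scalars the matching \code{dti_scalars}.
#' @param config a \code{\link{threshold_config}}.
#' @return object of class \code{dti_mask_set}: per region, a named list of
#'   integer voxel-index masks, one per condition.
#' @export
fa_masks <- function(base, scalars, config = threshold_config()) {
  fa <- as.vector(scalars$fa)
  conds <- condition_labels(config)
  out <- lapply(base, function(idx) {
    m <- vector("list", length(conds))
    names(m) <- conds
    m[["base"]] <- idx
    for (k in seq_along(config$fa_cutoffs)) {
      m[[k + 1L]] <- idx[fa[idx] > config$fa_cutoffs[k]]
    }
    m
  })
  structure(out, class = "dti_mask_set", config = config)
}

#' Minimum-voxel exclusion rule
#'
#' Flags every (region, condition) cell whose mask holds fewer than
#' \code{min_voxels} voxels. A cell with exactly \code{min_voxels} voxels is
#' retained ("fewer than" is strict). Flagged cells carry no downstream
#' statistics; the flag is applied independently per subject, region and
#' condition, so a region excluded at one cutoff still contributes at the
#' others.
#'
#' @param masks a \code{dti_mask_set}.
#' @param config a \code{\link{threshold_config}}.
#' @return logical matrix regions x conditions, TRUE where excluded.
#' @export
apply_min_voxel_rule <- function(masks, config = attr(masks, "config")) {
  conds <- condition_labels(config)
  excl <- t(vapply(masks, function(m) {
    vapply(m, length, integer(1)) < config$min_voxels
  }, logical(length(conds))))
  colnames(excl) <- conds
  rownames(excl) <- names(masks)
  excl
}

#' Segment one subject
#'
#' Runs the full masking cascade for one subject: base CSF-excluded masks,
#' FA-threshold masks, and the minimum-voxel exclusion flags.
#'
#' @inheritParams base_mask
#' @return list with \code{masks} (a \code{dti_mask_set}), \code{excluded}
#'   (logical matrix), \code{config}.
#' @export
segment_subject <- function(labels, scalars, region_table,
                            config = threshold_config()) {
  b <- base_mask(labels, scalars, region_table, config)
  m <- fa_masks(b, scalars, config)
  list(masks = m, excluded = apply_min_voxel_rule(m, config), config = config)
}

#' Export a mask set as a label volume
#'
#' One integer volume per condition, carrying each region's label where the
#' condition's mask retains the voxel -- convenient for visual QC in any
#' NIfTI viewer.
#'
#' @param masks a \code{dti_mask_set}.
#' @param region_table matching region table.
#' @param grid_shape dimensions of the original volume.
#' @return named list of integer 3D arrays, one per condition.
#' @export
masks_to_labels <- function(masks, region_table, grid_shape) {
  conds <- names(masks[[1]])
  out <- lapply(conds, function(cond) {
    vol <- array(0L, dim = grid_shape)
    for (r in seq_along(masks)) {
      vol[masks[[r]][[cond]]] <- region_table$label_id[r]
    }
    vol
  })
  names(out) <- conds
  out
}
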