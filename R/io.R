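# Standard-format I/O: NIfTI volumes, FSL gradient tables, CSV/JSON tables,
# and the pipeline runner with its provenance manifest.

#' Write a volume as NIfTI
#'
#' Label volumes are written as 32-bit integers so labels round-trip exactly;
#' scalar volumes as double precision. The voxel size (mm) is stored in the
#' header pixdim / affine.
#'
#' @param vol 3D or 4D numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size numeric 3-vector, mm; taken from the array's
#'   \code{voxel_size} attribute when absent.
#' @param datatype RNifti datatype string; "int32" for labels, "double" for
#'   scalars, or "auto".
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = attr(vol, "voxel_size"),
                         datatype = "double") {
  arr <- array(as.vector(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr)
  if (!is.null(voxel_size)) {
    RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(vol)) - 3))
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @param integer_labels coerce to integer and fail if the stored values are
#'   not whole numbers (for label atlases).
#' @return array with a \code{voxel_size} attribute.
#' @export
read_volume <- function(path, integer_labels = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (integer_labels) {
    if (any(abs(arr - round(arr)) > 1e-6)) {
      stop(sprintf(
        "'%s' holds non-integer values; a label atlas must be an integer volume (re-export with nearest-neighbour resampling)",
        path))
    }
    arr <- array(as.integer(round(arr)), dim = dim(arr))
  }
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  arr
}

#' Read an FSL-style gradient table
#'
#' bvecs: three whitespace-separated rows (x, y, z components per volume);
#' bvals: one row, one value per volume.
#'
#' @param bvec_path,bval_path text file paths.
#' @return list with \code{bvecs} (3 x n matrix) and \code{bvals} (length-n
#'   vector).
#' @export
read_bvec_bval <- function(bvec_path, bval_path) {
  rows <- lapply(readLines(bvec_path), function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != 3) stop("bvec file must contain exactly 3 rows")
  bvecs <- do.call(rbind, rows)
  bvals <- as.numeric(strsplit(trimws(paste(readLines(bval_path),
                                            collapse = " ")), "\\s+")[[1]])
  if (ncol(bvecs) != length(bvals)) {
    stop(sprintf("bvec has %d volumes but bval has %d", ncol(bvecs),
                 length(bvals)))
  }
  list(bvecs = bvecs, bvals = bvals)
}

#' Write an FSL-style gradient table
#'
#' @param scheme a \code{\link{acquisition_scheme}}.
#' @param bvec_path,bval_path output paths.
#' @return invisibly, the two paths.
#' @export
write_bvec_bval <- function(scheme, bvec_path, bval_path) {
  bvecs <- cbind(matrix(0, 3, scheme$n_b0), t(scheme$directions))
  con <- file(bvec_path, "w")
  for (r in 1:3) {
    writeLines(paste(formatC(bvecs[r, ], digits = 8, format = "f"),
                     collapse = " "), con)
  }
  close(con)
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  invisible(c(bvec_path, bval_path))
}

#' Write a phantom cohort to disk
#'
#' Per subject: \code{sub-XXX_dwi.nii.gz}, \code{sub-XXX_labels.nii.gz} and
#' (when kept) the ground-truth tensors \code{sub-XXX_tensor.nii.gz} in
#' 6-component symmetric storage (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz); plus one
#' shared FSL gradient table and a JSON config echo plus manifest.
#'
#' @param cohort a \code{dti_phantom_cohort}.
#' @param dir output directory (created).
#' @return invisibly, the manifest written alongside.
#' @export
write_phantom_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in cohort$subjects) {
    p_dwi <- file.path(dir, paste0(s$id, "_dwi.nii.gz"))
    p_lab <- file.path(dir, paste0(s$id, "_labels.nii.gz"))
    write_volume(s$dwi, p_dwi, cohort$voxel_size)
    write_volume(cohort$template, p_lab, cohort$voxel_size,
                 datatype = "int32")
    files <- c(files, p_dwi, p_lab)
    if (!is.null(s$tensors)) {
      p_ten <- file.path(dir, paste0(s$id, "_tensor.nii.gz"))
      write_volume(s$tensors, p_ten, cohort$voxel_size)
      files <- c(files, p_ten)
    }
  }
  gt <- write_bvec_bval(cohort$scheme, file.path(dir, "dwi.bvec"),
                        file.path(dir, "dwi.bval"))
  files <- c(files, gt)
  utils::write.csv(cohort$region_table, file.path(dir, "region_table.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(dir, "region_table.csv"))
  write_manifest(dir, files, config = list(
    mode = "phantom", n_subjects = length(cohort$subjects),
    grid_shape = cohort$grid_shape, voxel_size = cohort$voxel_size,
    s0 = cohort$s0, snr = cohort$snr, seed = cohort$seed
  ), seed = cohort$seed)
}

#' Load one subject's scalar maps from NIfTI files
#'
#' Real-data entry point: reads co-registered FA, trace, AD and RD volumes.
#'
#' @param fa,trace,ad,rd NIfTI paths.
#' @return a \code{dti_scalars}.
#' @export
read_subject_scalars <- function(fa, trace, ad, rd) {
  vols <- lapply(list(fa = fa, trace = trace, ad = ad, rd = rd), read_volume)
  dims <- lapply(vols, dim)
  for (nm in names(dims)[-1]) {
    if (!identical(dims[[nm]], dims[[1]])) {
      stop(sprintf("scalar map '%s' grid (%s) does not match '%s' (%s)",
                   nm, paste(dims[[nm]], collapse = "x"),
                   "fa", paste(dims[[1]], collapse = "x")))
    }
  }
  subject_scalars(vols$fa, vols$trace, vols$ad, vols$rd,
                  voxel_size = attr(vols$fa, "voxel_size"))
}

#' Read a DWI volume with its gradient table
#'
#' Reorders volumes so b = 0 images come first, matching the package's
#' internal convention, and validates that the 4D extent equals the gradient
#' table length.
#'
#' @param dwi_path 4D NIfTI path.
#' @param bvec_path,bval_path FSL gradient table.
#' @return list with \code{dwi} (4D array, b0 first) and \code{scheme}.
#' @export
read_dwi <- function(dwi_path, bvec_path, bval_path) {
  vol <- read_volume(dwi_path)
  if (length(dim(vol)) != 4) stop("DWI must be a 4D NIfTI volume")
  gt <- read_bvec_bval(bvec_path, bval_path)
  if (dim(vol)[4] != length(gt$bvals)) {
    stop(sprintf("DWI has %d volumes but the gradient table lists %d",
                 dim(vol)[4], length(gt$bvals)))
  }
  ord <- order(gt$bvals != 0)   # stable: b0 volumes first
  vol <- vol[, , , ord, drop = FALSE]
  scheme <- scheme_from_table(gt$bvecs[, ord, drop = FALSE], gt$bvals[ord])
  list(dwi = vol, scheme = scheme)
}

# ---- study outputs ---------------------------------------------------------

#' Write study tables, report and manifest
#'
#' Emits the cohort table, per-measure moment tables, comparison and pairwise
#' tables as CSV, a JSON copy of the cohort table, a Markdown report of the
#' statistical comparisons, and a manifest with the configuration echo, seed
#' and md5 hash of every artifact.
#'
#' @param study a \code{dti_threshold_study}.
#' @param dir output directory (created).
#' @return invisibly, the manifest as a list.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(study$table, "cohort_table.csv")
  for (m in names(study$moments)) {
    wr(study$moments[[m]], sprintf("moments_%s.csv", m))
  }
  wr(study$comparisons, "comparisons.csv")
  if (!is.null(study$pairwise)) wr(study$pairwise, "pairwise.csv")
  pj <- file.path(dir, "cohort_table.json")
  jsonlite::write_json(study$table, pj, dataframe = "rows", digits = NA)
  files <- c(files, pj)
  pr <- file.path(dir, "report.md")
  writeLines(render_report(study), pr)
  files <- c(files, pr)
  write_manifest(dir, files, config = list(
    trace_cutoff = study$config$trace_cutoff,
    fa_cutoffs = study$config$fa_cutoffs,
    min_voxels = study$config$min_voxels,
    family_alpha = study$family_alpha, family_size = study$family_size,
    corrected_alpha = study$alpha, n_perm = study$n_perm
  ), seed = study$seed)
}

render_report <- function(study) {
  conds <- condition_labels(study$config)
  pv <- condition_means(study$moments$percent_volume)[conds]
  cv <- condition_means(study$moments$percent_volume, "cv")[conds]
  lines <- c(
    "# Threshold-sensitivity study report", "",
    sprintf("- subjects: %d; region-sides: %d; conditions: %s",
            length(unique(study$table$subject)),
            nrow(unique(study$table[, c("region", "hemisphere")])),
            paste(conds, collapse = ", ")),
    sprintf("- Bonferroni: alpha %g over %d comparisons -> p < %.5f",
            study$family_alpha, study$family_size, study$alpha), "",
    "## Cohort means", "",
    paste0("- volume retained (% of base): ",
           paste(sprintf("%s %.1f", conds, pv), collapse = "; ")),
    paste0("- CV of regional volume: ",
           paste(sprintf("%s %.2f", conds, cv), collapse = "; ")), "",
    "## Kruskal-Wallis across conditions", ""
  )
  cp <- study$comparisons
  for (i in seq_len(nrow(cp))) {
    lines <- c(lines, if (!is.na(cp$skipped[i])) {
      sprintf("- %s (%s), %s: skipped (%s)", cp$region[i], cp$hemisphere[i],
              cp$measure[i], cp$skipped[i])
    } else {
      sprintf("- %s (%s), %s: H = %.3f, df = %d, p = %.3g%s%s",
              cp$region[i], cp$hemisphere[i], cp$measure[i], cp$H[i],
              cp$df[i], cp$p_chisq[i],
              if (!is.na(cp$p_perm[i]))
                sprintf(" (permutation p = %.3g)", cp$p_perm[i]) else "",
              if (isTRUE(cp$significant[i])) " *" else "")
    })
  }
  lines
}

write_manifest <- function(dir, files, config, seed) {
  manifest <- list(
    package = "dtithresh",
    version = as.character(utils::packageVersion("dtithresh")),
    seed = seed,
    config = config,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full pipeline and write all outputs
#'
#' Synthetic mode generates a phantom cohort and analyzes it; real mode reads
#' per-subject scalar maps plus a co-registered label atlas. Identical
#' configuration and seed produce identical tables; every run writes a
#' manifest with md5 hashes of its artifacts.
#'
#' @param out_dir output directory.
#' @param mode "synthetic" or "real".
#' @param n_subjects,grid_shape,snr,seed phantom settings (synthetic mode).
#' @param scalar_files real mode: list with one entry per subject, each a
#'   named list of paths \code{fa}, \code{trace}, \code{ad}, \code{rd}.
#' @param label_file real mode: path to the co-registered integer label
#'   atlas.
#' @param region_table region table; defaults to the 12-region neonatal set.
#' @param config a \code{\link{threshold_config}}.
#' @param family_alpha,family_size Bonferroni settings.
#' @param write_phantom also write the generated phantom volumes (synthetic
#'   mode).
#' @return the \code{dti_threshold_study}, invisibly.
#' @export
run_threshold_pipeline <- function(out_dir, mode = c("synthetic", "real"),
                                   n_subjects = 8,
                                   grid_shape = c(48L, 48L, 48L),
                                   snr = 30, seed = 1,
                                   scalar_files = NULL, label_file = NULL,
                                   region_table = neonatal_region_table(),
                                   config = threshold_config(),
                                   family_alpha = 0.05, family_size = NULL,
                                   write_phantom = FALSE) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    cohort <- simulate_phantom_cohort(n_subjects = n_subjects,
                                      region_table = region_table,
                                      grid_shape = grid_shape,
                                      snr = snr, seed = seed)
    if (write_phantom) {
      write_phantom_cohort(cohort, file.path(out_dir, "phantom"))
    }
    study <- threshold_study(cohort, config = config,
                             family_alpha = family_alpha,
                             family_size = family_size, seed = seed)
  } else {
    if (is.null(scalar_files) || is.null(label_file)) {
      stop("real mode requires scalar_files and label_file")
    }
    labels <- read_volume(label_file, integer_labels = TRUE)
    subjects <- lapply(seq_along(scalar_files), function(i) {
      sf <- scalar_files[[i]]
      sc <- read_subject_scalars(sf$fa, sf$trace, sf$ad, sf$rd)
      if (!identical(dim(labels), dim(sc$fa))) {
        stop(sprintf(
          "label atlas '%s' grid (%s) does not match subject %d scalars (%s)",
          label_file, paste(dim(labels), collapse = "x"), i,
          paste(dim(sc$fa), collapse = "x")))
      }
      list(id = if (!is.null(names(scalar_files))) names(scalar_files)[i]
                else sprintf("sub-%03d", i),
           scalars = sc)
    })
    study <- threshold_study(subjects, labels = labels,
                             region_table = region_table, config = config,
                             family_alpha = family_alpha,
                             family_size = family_size, seed = seed)
  }
  write_study(study, out_dir)
  invisible(study)
}
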