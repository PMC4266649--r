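# Per subject x region x condition voxel counts, percent-of-base volumes,
# and mean FA/AD/RD.

#' Summarize one subject's regions under every condition
#'
#' For each region and condition: voxel count, volume as a percent of the
#' subject's CSF-excluded base mask (100 for the base condition by
#' definition), the raw atlas-label voxel count as a diagnostic denominator,
#' and unweighted voxel means of FA, AD and RD. Cells failing the
#' minimum-voxel rule, and regions whose base mask is empty, are flagged
#' excluded and carry NA means.
#'
#' @param segmentation result of \code{\link{segment_subject}}.
#' @param scalars the subject's \code{dti_scalars}.
#' @param labels the label volume (for the raw-label diagnostic count).
#' @param region_table matching region table.
#' @param subject_id identifier recorded in the output.
#' @return data.frame, one row per region x condition.
#' @export
summarize_subject <- function(segmentation, scalars, labels, region_table,
                              subject_id = "sub-001") {
  masks <- segmentation$masks
  excl <- segmentation$excluded
  conds <- names(masks[[1]])
  fa <- as.vector(scalars$fa); ad <- as.vector(scalars$ad)
  rd <- as.vector(scalars$rd)
  lab <- as.integer(labels)
  raw_counts <- vapply(region_table$label_id, function(id) sum(lab == id),
                       integer(1))
  rows <- vector("list", length(masks) * length(conds))
  k <- 0L
  for (r in seq_along(masks)) {
    n_base <- length(masks[[r]][["base"]])
    for (cond in conds) {
      idx <- masks[[r]][[cond]]
      n <- length(idx)
      excluded <- excl[r, cond] || n_base == 0L
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject = subject_id,
        region = region_table$name[r],
        hemisphere = region_table$hemisphere[r],
        condition = cond,
        n_voxels = n,
        n_base = n_base,
        n_label = raw_counts[r],
        percent_volume = if (n_base > 0) 100 * n / n_base else NA_real_,
        percent_of_label = if (raw_counts[r] > 0) 100 * n / raw_counts[r] else NA_real_,
        mean_fa = if (!excluded && n > 0) mean(fa[idx]) else NA_real_,
        mean_ad = if (!excluded && n > 0) mean(ad[idx]) else NA_real_,
        mean_rd = if (!excluded && n > 0) mean(rd[idx]) else NA_real_,
        excluded = excluded,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bind per-subject summaries into a cohort table
#'
#' Long format: one row per (subject, region, hemisphere, condition), with
#' excluded cells present and flagged. Duplicate cells are an integrity
#' error.
#'
#' @param summaries list of data.frames from \code{\link{summarize_subject}},
#'   or a single already-bound data.frame.
#' @return data.frame with a stable column schema.
#' @export
cohort_table <- function(summaries) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  cols <- c("subject", "region", "hemisphere", "condition", "n_voxels",
            "n_base", "n_label", "percent_volume", "percent_of_label",
            "mean_fa", "mean_ad", "mean_rd", "excluded")
  if (length(summaries) == 0) {
    out <- as.data.frame(
      setNames(
        list(character(), character(), character(), character(), integer(),
             integer(), integer(), numeric(), numeric(), numeric(), numeric(),
             numeric(), logical()),
        cols
      ),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  out <- do.call(rbind, summaries)
  missing <- setdiff(cols, names(out))
  if (length(missing)) stop("summaries lack columns: ", paste(missing, collapse = ", "))
  out <- out[, cols]
  key <- paste(out$subject, out$region, out$hemisphere, out$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, region, hemisphere, condition) cells in cohort table")
  }
  rownames(out) <- NULL
  out
}

#' Pivot a cohort statistic into a region x condition grid
#'
#' Figure-ready wide table of "mean [lo, hi]" strings, or a numeric matrix of
#' means, across conditions.
#'
#' @param moments output of \code{\link{cohort_moments}}.
#' @param what "formatted" for mean [CI] strings, "mean" for numbers.
#' @param digits significant digits for formatting.
#' @return data.frame with one row per region-hemisphere.
#' @export
pivot_moments <- function(moments, what = c("formatted", "mean"), digits = 3) {
  what <- match.arg(what)
  key <- paste(moments$region, moments$hemisphere, sep = " ")
  conds <- unique(moments$condition)
  rows <- unique(key)
  m <- matrix(if (what == "mean") NA_real_ else NA_character_,
              length(rows), length(conds), dimnames = list(rows, conds))
  for (i in seq_len(nrow(moments))) {
    v <- if (what == "mean") {
      moments$mean[i]
    } else if (is.na(moments$ci95_lo[i])) {
      sprintf("%s", signif(moments$mean[i], digits))
    } else {
      sprintf("%s [%s, %s]", signif(moments$mean[i], digits),
              signif(moments$ci95_lo[i], digits), signif(moments$ci95_hi[i], digits))
    }
    m[key[i], moments$condition[i]] <- v
  }
  out <- data.frame(region = rows, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
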