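# End-to-end threshold-sensitivity study: segmentation + metrics + cohort
# statistics, packaged as a classed result object.

#' Run a threshold-sensitivity study
#'
#' The central analysis of the package: given a cohort of subjects with
#' co-registered scalar maps and an integer label atlas (or a synthetic
#' phantom cohort, whose DWI volumes are tensor-fitted first), apply the
#' masking cascade at every threshold condition, tabulate per-subject
#' regional volumes and scalar means, and compute across-subject moments,
#' coefficients of variation, and region-wise Kruskal-Wallis comparisons of
#' FA/AD/RD across conditions with Bonferroni control.
#'
#' @param x a \code{dti_phantom_cohort}, a list of subjects (each a list with
#'   elements \code{scalars} -- a \code{dti_scalars} -- and optionally
#'   \code{labels} and \code{id}), or an already-built cohort table
#'   (data.frame).
#' @param ... passed to methods.
#' @return an object of class \code{dti_threshold_study}; see
#'   \code{\link{print.dti_threshold_study}},
#'   \code{\link{summary.dti_threshold_study}} and
#'   \code{\link{plot.dti_threshold_study}}.
#' @export
threshold_study <- function(x, ...) UseMethod("threshold_study")

#' @rdname threshold_study
#' @param config a \code{\link{threshold_config}}.
#' @param family_alpha family-wise error rate for the Bonferroni correction.
#' @param family_size number of comparisons in the Bonferroni family;
#'   defaults to the number of distinct region names (left/right homologues
#'   count once, mirroring a 12-region analysis set).
#' @param n_perm Monte-Carlo resamples for small-sample permutation p-values.
#' @param seed RNG seed for the permutation streams.
#' @export
threshold_study.dti_phantom_cohort <- function(x, config = threshold_config(),
                                               family_alpha = 0.05,
                                               family_size = NULL,
                                               n_perm = 10000, seed = 1, ...) {
  subjects <- lapply(x$subjects, function(s) {
    list(id = s$id, scalars = dwi_to_scalars(s$dwi, x$scheme),
         labels = x$template)
  })
  threshold_study_from_subjects(subjects, x$template, x$region_table, config,
                                family_alpha, family_size, n_perm, seed)
}

#' @rdname threshold_study
#' @param labels integer label array shared by all subjects (ignored for
#'   subjects carrying their own \code{labels}).
#' @param region_table region table (name, hemisphere, label_id).
#' @export
threshold_study.list <- function(x, labels = NULL, region_table,
                                 config = threshold_config(),
                                 family_alpha = 0.05, family_size = NULL,
                                 n_perm = 10000, seed = 1, ...) {
  threshold_study_from_subjects(x, labels, region_table, config,
                                family_alpha, family_size, n_perm, seed)
}

#' @rdname threshold_study
#' @export
threshold_study.data.frame <- function(x, family_alpha = 0.05,
                                       family_size = NULL, n_perm = 10000,
                                       seed = 1, config = threshold_config(),
                                       ...) {
  threshold_study_from_table(x, config, family_alpha, family_size,
                             n_perm, seed)
}

threshold_study_from_subjects <- function(subjects, labels, region_table,
                                          config, family_alpha, family_size,
                                          n_perm, seed) {
  validate_region_table(region_table)
  summaries <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    lab <- if (!is.null(s$labels)) s$labels else labels
    if (is.null(lab)) stop("no label volume supplied for subject ", i)
    if (!identical(dim(lab), dim(s$scalars$fa))) {
      stop(sprintf("subject %s: label grid does not match scalar grid",
                   if (!is.null(s$id)) s$id else i))
    }
    seg <- segment_subject(lab, s$scalars, region_table, config)
    summarize_subject(seg, s$scalars, lab, region_table,
                      subject_id = if (!is.null(s$id)) s$id
                                   else sprintf("sub-%03d", i))
  })
  tab <- cohort_table(summaries)
  out <- threshold_study_from_table(tab, config, family_alpha, family_size,
                                    n_perm, seed)
  out$region_table <- region_table
  out
}

threshold_study_from_table <- function(table, config, family_alpha,
                                       family_size, n_perm, seed) {
  conds <- condition_labels(config)
  if (!all(table$condition %in% conds)) {
    stop("cohort table conditions do not match the threshold configuration")
  }
  if (is.null(family_size)) family_size <- length(unique(table$region))
  alpha <- bonferroni_alpha(family_alpha, family_size)

  measures <- c("percent_volume", "n_voxels", "mean_fa", "mean_ad", "mean_rd")
  moments <- lapply(measures, function(m) cohort_moments(table, m))
  names(moments) <- measures

  cells <- unique(table[, c("region", "hemisphere")])
  comp_rows <- list(); pw_rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- table[table$region == cells$region[i] &
                 table$hemisphere == cells$hemisphere[i], , drop = FALSE]
    for (m in c("mean_fa", "mean_ad", "mean_rd")) {
      groups <- lapply(conds, function(cc) {
        v <- sub[[m]][sub$condition == cc & !sub$excluded]
        v[!is.na(v)]
      })
      names(groups) <- conds
      empty <- lengths(groups) == 0
      if (any(empty)) {
        comp_rows[[length(comp_rows) + 1]] <- data.frame(
          region = cells$region[i], hemisphere = cells$hemisphere[i],
          measure = m, H = NA_real_, df = NA_integer_, p_chisq = NA_real_,
          p_perm = NA_real_, significant = NA,
          skipped = paste("empty condition:",
                          paste(conds[empty], collapse = ", ")),
          stringsAsFactors = FALSE
        )
        next
      }
      kt <- kruskal_wallis(groups, n_perm = n_perm, seed = seed)
      comp_rows[[length(comp_rows) + 1]] <- data.frame(
        region = cells$region[i], hemisphere = cells$hemisphere[i],
        measure = m, H = kt$statistic, df = kt$df, p_chisq = kt$p_chisq,
        p_perm = kt$p_perm, significant = kt$p_chisq < alpha,
        skipped = NA_character_, stringsAsFactors = FALSE
      )
      pw <- pairwise_adjacent(groups, alpha = alpha, n_perm = n_perm,
                              seed = seed)
      pw$region <- cells$region[i]
      pw$hemisphere <- cells$hemisphere[i]
      pw$measure <- m
      pw_rows[[length(pw_rows) + 1]] <- pw
    }
  }
  comparisons <- do.call(rbind, comp_rows)
  pairwise <- if (length(pw_rows)) do.call(rbind, pw_rows) else NULL
  rownames(comparisons) <- NULL
  if (!is.null(pairwise)) {
    pairwise <- pairwise[, c("region", "hemisphere", "measure", "contrast",
                             "H", "df", "p_chisq", "p_perm", "significant")]
    rownames(pairwise) <- NULL
  }

  structure(
    list(table = table, moments = moments, comparisons = comparisons,
         pairwise = pairwise, alpha = alpha, family_alpha = family_alpha,
         family_size = family_size, config = config, n_perm = n_perm,
         seed = seed, region_table = NULL),
    class = "dti_threshold_study"
  )
}

# cohort-level means of a moments column across regions, one per condition
condition_means <- function(moments, col = "mean") {
  vapply(split(moments[[col]], moments$condition),
         mean, numeric(1), na.rm = TRUE)
}

#' @export
print.dti_threshold_study <- function(x, ...) {
  conds <- condition_labels(x$config)
  cat("DTI threshold-sensitivity study\n")
  cat(sprintf("  subjects: %d   regions: %d   conditions: %s\n",
              length(unique(x$table$subject)),
              nrow(unique(x$table[, c("region", "hemisphere")])),
              paste(conds, collapse = ", ")))
  pv <- condition_means(x$moments$percent_volume)[conds]
  cat("  cohort-mean volume retained (% of CSF-excluded base):\n")
  cat(sprintf("    %s\n", paste(sprintf("%s: %.1f", conds, pv),
                                collapse = "   ")))
  cv <- condition_means(x$moments$percent_volume, "cv")[conds]
  cat("  mean CV of regional volume across subjects:\n")
  cat(sprintf("    %s\n", paste(sprintf("%s: %.2f", conds, cv),
                                collapse = "   ")))
  ok <- !is.na(x$comparisons$significant)
  cat(sprintf("  Kruskal-Wallis across conditions at alpha = %.5f (%g/%d):\n",
              x$alpha, x$family_alpha, x$family_size))
  for (m in c("mean_fa", "mean_ad", "mean_rd")) {
    sel <- ok & x$comparisons$measure == m
    cat(sprintf("    %s: %d/%d region-sides significant\n", m,
                sum(x$comparisons$significant[sel]), sum(sel)))
  }
  invisible(x)
}

#' Summarize a threshold study
#'
#' @param object a \code{dti_threshold_study}.
#' @param measure which measure's region x condition grid to show.
#' @param ... unused.
#' @return invisibly, the pivoted moments table that is printed.
#' @export
summary.dti_threshold_study <- function(object, measure = "percent_volume",
                                        ...) {
  print(object)
  piv <- pivot_moments(object$moments[[measure]])
  cat(sprintf("\n%s by region (mean [95%% CI]):\n", measure))
  print(piv, right = FALSE)
  invisible(piv)
}

#' Plot a threshold study
#'
#' Grouped bars per region (left/right adjacent) across threshold
#' conditions, for the cohort mean of the chosen measure or its CV.
#'
#' @param x a \code{dti_threshold_study}.
#' @param measure measure to plot.
#' @param what "mean" or "cv".
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.dti_threshold_study <- function(x, measure = "percent_volume",
                                     what = c("mean", "cv"), ...) {
  what <- match.arg(what)
  mo <- x$moments[[measure]]
  conds <- condition_labels(x$config)
  key <- paste(mo$region, substr(mo$hemisphere, 1, 1))
  regions <- unique(key)
  m <- matrix(NA_real_, length(conds), length(regions),
              dimnames = list(conds, regions))
  for (i in seq_len(nrow(mo))) m[mo$condition[i], key[i]] <- mo[[what]][i]
  cols <- grDevices::hcl.colors(length(conds), "Blues3", rev = TRUE)
  graphics::barplot(m, beside = TRUE, col = cols, las = 2,
                    ylab = if (what == "mean") measure
                           else paste("CV of", measure),
                    legend.text = conds,
                    args.legend = list(x = "topright", bty = "n"), ...)
  invisible(m)
}
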