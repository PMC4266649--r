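# Across-subject statistics per region x condition, and region-wise
# nonparametric comparison across threshold conditions.

#' Across-subject moments per region and condition
#'
#' For one measure (e.g. \code{percent_volume} or \code{mean_fa}): number of
#' contributing subjects, mean, sample SD (n-1 denominator), coefficient of
#' variation CV = SD/mean (reported only when the mean is positive), and a
#' Student-t 95\% confidence interval with n-1 degrees of freedom. Cells with
#' a single contributing subject report the mean only. Excluded cells and NA
#' values do not contribute.
#'
#' @param table cohort table from \code{\link{cohort_table}}.
#' @param measure column to summarize: one of \code{percent_volume},
#'   \code{n_voxels}, \code{mean_fa}, \code{mean_ad}, \code{mean_rd}.
#' @param conf.level confidence level for the interval.
#' @return data.frame with one row per region x hemisphere x condition.
#' @export
cohort_moments <- function(table, measure = "percent_volume",
                           conf.level = 0.95) {
  stopifnot(measure %in% c("percent_volume", "n_voxels", "mean_fa",
                           "mean_ad", "mean_rd"))
  keep <- !table$excluded & !is.na(table[[measure]])
  tab <- table[keep, , drop = FALSE]
  grp <- interaction(tab$region, tab$hemisphere, tab$condition,
                     drop = TRUE, sep = "\r")
  parts <- split(seq_len(nrow(tab)), grp)
  rows <- lapply(parts, function(ridx) {
    x <- tab[[measure]][ridx]
    first <- ridx[1]
    n <- length(x)
    mu <- mean(x)
    s <- if (n >= 2) stats::sd(x) else NA_real_
    half <- if (n >= 2) stats::qt(1 - (1 - conf.level) / 2, n - 1) * s / sqrt(n)
            else NA_real_
    data.frame(
      region = tab$region[first], hemisphere = tab$hemisphere[first],
      condition = tab$condition[first], measure = measure,
      n_subjects = n, mean = mu, sd = s,
      cv = if (!is.na(s) && mu > 0) s / mu else NA_real_,
      ci95_lo = mu - half, ci95_hi = mu + half,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$region, out$hemisphere, out$condition), ]
}

# Tie-corrected Kruskal-Wallis H statistic; drives the Monte-Carlo
# permutation null and the tie-correction diagnostics.
kw_h_statistic <- function(x, g, tie_correct = TRUE) {
  r <- rank(x)
  n <- length(x)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  if (tie_correct) {
    t <- table(x)
    corr <- 1 - sum(t^3 - t) / (n^3 - n)
    if (corr > 0) h <- h / corr
  }
  unname(h)
}

#' Kruskal-Wallis comparison across conditions
#'
#' Rank-based k-group test with tie correction; the H statistic, degrees of
#' freedom and chi-square p-value come from \code{\link[stats]{kruskal.test}}.
#' When the pooled sample is small (total n at or below
#' \code{exact_threshold}) a seeded Monte-Carlo permutation p-value over
#' \code{n_perm} random relabelings of the tie-corrected H is reported
#' alongside, since the chi-square approximation is weakest exactly there.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @param n_perm Monte-Carlo resamples for the permutation p-value.
#' @param exact_threshold largest total n for which the permutation p-value
#'   is computed.
#' @param seed RNG seed for the permutation stream.
#' @return object of class \code{kw_test}: \code{statistic}, \code{df},
#'   \code{p_chisq}, \code{p_perm} (NA when not computed), \code{n_perm},
#'   \code{n_total}.
#' @export
kruskal_wallis <- function(groups, n_perm = 10000, exact_threshold = 30,
                           seed = 1) {
  if (length(groups) < 2) stop("at least two groups are required")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  h <- unname(kt$statistic)
  if (is.nan(h)) h <- 0     # all observations tied: no evidence of difference
  p_chisq <- if (is.nan(kt$p.value)) 1 else kt$p.value
  p_perm <- NA_real_
  if (n_perm >= 1 && length(x) <= exact_threshold) {
    # ranks and the tie-correction factor are permutation-invariant, so the
    # null only needs group rank-sums of permuted rank vectors
    set.seed(seed)
    n <- length(x)
    r <- rank(x)
    tt <- table(x)
    corr <- 1 - sum(tt^3 - tt) / (n^3 - n)
    if (corr <= 0) corr <- 1
    ns <- tabulate(g)
    h_obs <- kw_h_statistic(x, g)
    perms <- replicate(n_perm, sample.int(n))
    Rm <- matrix(r[perms], n, n_perm)
    s <- rowsum(Rm, as.integer(g))
    hb <- (12 / (n * (n + 1)) * colSums(s^2 / ns) - 3 * (n + 1)) / corr
    p_perm <- (sum(hb >= h_obs - 1e-12) + 1) / (n_perm + 1)
  }
  structure(
    list(statistic = h, df = unname(kt$parameter), p_chisq = p_chisq,
         p_perm = p_perm, n_perm = if (is.na(p_perm)) 0L else n_perm,
         n_total = length(x)),
    class = "kw_test"
  )
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p(chi-square) = %.4g",
              x$statistic, x$df, x$p_chisq))
  if (!is.na(x$p_perm)) {
    cat(sprintf(", p(permutation, %d resamples) = %.4g", x$n_perm, x$p_perm))
  }
  cat("\n")
  invisible(x)
}

#' Bonferroni-corrected significance cutoff
#'
#' \code{family_alpha / n_comparisons}, e.g. 0.05/12 = 0.0041667 for a
#' 12-region family. The exact fraction is used as the working cutoff;
#' rounding to presentation precision (0.00417) is left to reporting.
#'
#' @param family_alpha family-wise error rate in (0, 1).
#' @param n_comparisons number of comparisons, at least 1.
#' @return the corrected alpha.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_comparisons = 12) {
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must lie in (0, 1)")
  }
  if (n_comparisons < 1) stop("n_comparisons must be at least 1")
  family_alpha / n_comparisons
}

#' Adjacent-condition pairwise contrasts
#'
#' Two-group rank tests (Kruskal-Wallis with k = 2, equivalent to a
#' rank-sum test) for each pair of adjacent conditions, flagged significant
#' at the supplied corrected alpha (strict \code{p < alpha}).
#'
#' @param groups named list of per-condition value vectors, in condition
#'   order.
#' @param alpha corrected significance cutoff.
#' @param ... passed to \code{\link{kruskal_wallis}}.
#' @return data.frame with one row per adjacent pair: the contrast label,
#'   H, p-values and significance flag.
#' @export
pairwise_adjacent <- function(groups, alpha = bonferroni_alpha(), ...) {
  if (length(groups) < 2) stop("need at least two conditions")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("cond", seq_along(groups))
  rows <- lapply(seq_len(length(groups) - 1), function(i) {
    kt <- kruskal_wallis(groups[c(i, i + 1)], ...)
    data.frame(
      contrast = paste(nm[i], "vs", nm[i + 1]),
      H = kt$statistic, df = kt$df, p_chisq = kt$p_chisq,
      p_perm = kt$p_perm,
      significant = kt$p_chisq < alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
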