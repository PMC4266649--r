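test_that("cohort moments match hand computation and trivial cases", {
  tab <- data.frame(
    subject = c("a", "b", "c", "a", "b"),
    region = "R", hemisphere = "left",
    condition = c("base", "base", "base", "FA>0.15", "FA>0.15"),
    percent_volume = c(10, 10, 10, 8, 12),
    excluded = FALSE, stringsAsFactors = FALSE
  )
  mo <- cohort_moments(tab, "percent_volume")
  b <- mo[mo$condition == "base", ]
  expect_equal(b$mean, 10)
  expect_equal(b$sd, 0)
  expect_equal(b$cv, 0)
  expect_equal(c(b$ci95_lo, b$ci95_hi), c(10, 10))
  f <- mo[mo$condition == "FA>0.15", ]
  expect_equal(f$mean, 10)
  expect_equal(f$sd, sqrt(8), tolerance = 1e-12)      # sd({8,12}) = 2.828...
  expect_equal(f$cv, sqrt(8) / 10, tolerance = 1e-12)
  # t-based CI with 1 df
  half <- qt(0.975, 1) * sqrt(8) / sqrt(2)
  expect_equal(f$ci95_lo, 10 - half, tolerance = 1e-12)

  # single contributing subject: mean only
  tab1 <- tab[1, ]
  mo1 <- cohort_moments(tab1, "percent_volume")
  expect_equal(mo1$mean, 10)
  expect_true(is.na(mo1$sd) && is.na(mo1$cv) && is.na(mo1$ci95_lo))
})

test_that("cohort moments equal a brute-force recomputation on the phantom table", {
  st <- tiny_study()
  for (measure in c("percent_volume", "mean_fa", "mean_rd")) {
    mo <- st$moments[[measure]]
    for (i in seq_len(nrow(mo))) {
      bf <- moments_bruteforce(st$table, mo$region[i], mo$hemisphere[i],
                               mo$condition[i], measure)
      expect_equal(mo$n_subjects[i], bf$n)
      expect_equal(mo$mean[i], bf$mean, tolerance = 1e-12)
      expect_equal(mo$sd[i], bf$sd, tolerance = 1e-12)
      expect_equal(mo$cv[i], bf$cv, tolerance = 1e-12)
      expect_equal(mo$ci95_lo[i], bf$lo, tolerance = 1e-12)
      expect_equal(mo$ci95_hi[i], bf$hi, tolerance = 1e-12)
    }
  }
})

test_that("CV is invariant under positive rescaling", {
  set.seed(51)
  for (k in 1:10) {
    x <- runif(8, 1, 100)
    cscale <- runif(1, 0.01, 50)
    tab <- data.frame(subject = letters[1:8], region = "R",
                      hemisphere = "left", condition = "base",
                      percent_volume = x, excluded = FALSE,
                      stringsAsFactors = FALSE)
    tab2 <- tab; tab2$percent_volume <- x * cscale
    cv1 <- cohort_moments(tab, "percent_volume")$cv
    cv2 <- cohort_moments(tab2, "percent_volume")$cv
    expect_equal(cv1, cv2, tolerance = 1e-12)
  }
})

test_that("identical groups give H = 0 and p = 1", {
  g <- rep(list(c(1, 2, 3)), 4)
  kt <- kruskal_wallis(g, n_perm = 500, seed = 1)
  expect_equal(kt$df, 3)
  expect_lt(kt$statistic, 1e-10)
  expect_equal(kt$p_chisq, 1, tolerance = 1e-12)
  # fully tied data: kruskal.test yields NaN, reported as no evidence
  g2 <- list(c(5, 5), c(5, 5))
  kt2 <- kruskal_wallis(g2, n_perm = 100, seed = 1)
  expect_equal(kt2$statistic, 0)
  expect_equal(kt2$p_chisq, 1)
})

test_that("H matches kruskal.test and the exhaustive permutation distribution", {
  groups <- list(c(1, 2, 3), c(4, 5, 6))
  ex <- kw_exhaustive(groups)
  expect_length(ex$stats, choose(6, 3))          # all 20 splits
  kt <- kruskal_wallis(groups, n_perm = 20000, seed = 7)
  expect_equal(kt$statistic, ex$h_obs, tolerance = 1e-12)
  expect_equal(ex$p_exact, 2 / 20)               # both extreme splits
  se <- sqrt(ex$p_exact * (1 - ex$p_exact) / 20000)
  expect_lt(abs(kt$p_perm - ex$p_exact), 3 * se + 2 / 20001)
  # internal statistic agrees with the stats:: implementation
  x <- unlist(groups); g <- factor(rep(1:2, each = 3))
  expect_equal(dtithresh:::kw_h_statistic(x, g),
               unname(stats::kruskal.test(x, g)$statistic), tolerance = 1e-12)
})

test_that("tie correction inflates H on tie-heavy data", {
  x <- c(1, 1, 1, 2, 1, 2, 2, 2)
  g <- factor(rep(1:2, each = 4))
  h_tie <- dtithresh:::kw_h_statistic(x, g, tie_correct = TRUE)
  h_raw <- dtithresh:::kw_h_statistic(x, g, tie_correct = FALSE)
  expect_gt(h_tie, h_raw)
  expect_equal(h_tie, unname(stats::kruskal.test(x, g)$statistic),
               tolerance = 1e-12)
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration", {
  set.seed(61)
  cases <- list(
    list(sizes = c(2, 3, 3), ties = FALSE),
    list(sizes = c(4, 4), ties = TRUE),
    list(sizes = c(2, 2, 2, 2), ties = FALSE)
  )
  for (cs in cases) {
    vals <- if (cs$ties) sample(1:3, sum(cs$sizes), replace = TRUE)
            else rnorm(sum(cs$sizes))
    groups <- split(vals, rep(seq_along(cs$sizes), cs$sizes))
    ex <- kw_exhaustive(groups)
    kt <- kruskal_wallis(groups, n_perm = 20000, seed = 17)
    expect_equal(kt$statistic, ex$h_obs, tolerance = 1e-10)
    se <- sqrt(max(ex$p_exact * (1 - ex$p_exact), 1e-4) / 20000)
    expect_lt(abs(kt$p_perm - ex$p_exact), 3 * se + 2 / 20001)
  }
})

test_that("empty groups are rejected and the permutation p respects the size gate", {
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
  big <- kruskal_wallis(list(rnorm(20), rnorm(20)), n_perm = 100, seed = 1)
  expect_true(is.na(big$p_perm))                  # n = 40 > 30: chi-square only
})

test_that("Bonferroni correction divides the family alpha", {
  expect_equal(signif(bonferroni_alpha(0.05, 12), 3), 0.00417)
  expect_equal(bonferroni_alpha(0.05, 12), 0.05 / 12)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 4), 0.0025)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
  expect_error(bonferroni_alpha(1.5, 12), "0, 1")
})

test_that("adjacent pairwise contrasts flag shifted but not identical groups", {
  same <- list(base = 1:6, t1 = 1:6)
  pw <- pairwise_adjacent(same, alpha = 0.05, n_perm = 500, seed = 1)
  expect_false(pw$significant)
  shifted <- list(a = 1:10, b = 11:20)
  pw2 <- pairwise_adjacent(shifted, alpha = 0.05, n_perm = 2000, seed = 1)
  expect_true(pw2$significant)
  # rank-sum oracle: two-group Kruskal-Wallis is equivalent to Wilcoxon
  w <- stats::wilcox.test(1:10, 11:20, exact = FALSE, correct = FALSE)
  expect_equal(pw2$p_chisq, w$p.value, tolerance = 1e-6)
  four <- list(base = 1:5, t1 = 1:5 + 1, t2 = 1:5 + 2, t3 = 1:5 + 30)
  pw4 <- pairwise_adjacent(four, alpha = 0.05, n_perm = 500, seed = 1)
  expect_equal(nrow(pw4), 3)
  expect_equal(pw4$contrast,
               c("base vs t1", "t1 vs t2", "t2 vs t3"))
})
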