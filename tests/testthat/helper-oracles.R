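# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# FA of an axially symmetric tensor, closed form: (l1 - l2)/sqrt(l1^2 + 2 l2^2)
fa_axial_oracle <- function(l1, l2) (l1 - l2) / sqrt(l1^2 + 2 * l2^2)

# general-formula FA written out longhand
fa_formula_oracle <- function(lam) {
  lam <- pmax(lam, 0)
  lbar <- mean(lam)
  sqrt(3 / 2) * sqrt(sum((lam - lbar)^2)) / sqrt(sum(lam^2))
}

# random symmetric positive-definite tensor in the diffusion range
random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  S <- crossprod(A) + diag(3) * 0.1
  S <- S / max(abs(S)) * 1.5e-3
  c(S[1, 1], S[1, 2], S[1, 3], S[2, 2], S[2, 3], S[3, 3])
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
}

# one-pass brute-force recomputation of cohort moments for a single
# (region, hemisphere, condition, measure) cell
moments_bruteforce <- function(table, region, hemisphere, condition, measure) {
  sel <- table$region == region & table$hemisphere == hemisphere &
    table$condition == condition & !table$excluded &
    !is.na(table[[measure]])
  x <- table[[measure]][sel]
  n <- length(x)
  mu <- sum(x) / n
  s <- if (n >= 2) sqrt(sum((x - mu)^2) / (n - 1)) else NA_real_
  half <- if (n >= 2) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
  list(n = n, mean = mu, sd = s,
       cv = if (!is.na(s) && mu > 0) s / mu else NA_real_,
       lo = mu - half, hi = mu + half)
}

# exhaustive permutation distribution of the tie-corrected Kruskal-Wallis
# statistic: every distinct assignment of the pooled values to the group
# sizes, by recursive index selection
kw_exhaustive <- function(groups) {
  sizes <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  stats <- numeric(0)
  assign_rec <- function(remaining, sizes_left, labels) {
    if (length(sizes_left) == 1) {
      g <- labels
      g[remaining] <- length(sizes)   # last group takes the remainder
      stats <<- c(stats, dtithresh:::kw_h_statistic(x, factor(g)))
      return(invisible())
    }
    k <- length(sizes) - length(sizes_left) + 1
    picks <- utils::combn(remaining, sizes_left[1], simplify = FALSE)
    for (p in picks) {
      lab2 <- labels
      lab2[p] <- k
      assign_rec(setdiff(remaining, p), sizes_left[-1], lab2)
    }
  }
  assign_rec(seq_len(n), sizes, rep(NA_integer_, n))
  h_obs <- dtithresh:::kw_h_statistic(
    x, factor(rep(seq_along(groups), sizes)))
  list(h_obs = h_obs, stats = stats,
       p_exact = mean(stats >= h_obs - 1e-12))
}
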