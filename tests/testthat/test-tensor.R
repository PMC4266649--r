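test_that("noise-free signals invert to the exact tensor", {
  set.seed(21)
  tens <- array(0, dim = c(4, 4, 2, 6))
  for (i in seq_len(prod(dim(tens)[1:3]))) {
    at <- arrayInd(i, dim(tens)[1:3])
    tens[at[1], at[2], at[3], ] <- random_spd_tensor()
  }
  scheme <- default_scheme()
  dwi <- simulate_dwi(tens, scheme, snr = Inf)
  fit <- fit_tensor(dwi, scheme)
  expect_true(all(fit$valid))
  expect_lt(max(abs(fit$tensors - tens)), 1e-10)
})

test_that("signals equal to S0 fit a zero tensor; bad signals invalidate the voxel", {
  scheme <- default_scheme()
  nvol <- nrow(scheme$directions) + scheme$n_b0
  dwi <- array(800, dim = c(3, 3, 3, nvol))
  fit <- fit_tensor(dwi, scheme)
  expect_true(all(fit$valid))
  expect_equal(max(abs(fit$tensors)), 0)
  dwi[2, 2, 2, 5] <- -1        # one negative diffusion-weighted sample
  dwi[1, 1, 1, 1:scheme$n_b0] <- 0   # S0 = 0
  fit <- fit_tensor(dwi, scheme)
  expect_false(fit$valid[2, 2, 2])
  expect_false(fit$valid[1, 1, 1])
  expect_true(all(is.na(fit$tensors[2, 2, 2, ])))
  expect_equal(sum(!fit$valid), 2)
})

test_that("rank-deficient gradient schemes are rejected", {
  dirs <- rbind(diag(3), diag(3))     # 6 axis-aligned directions: rank 3
  scheme <- acquisition_scheme(dirs, n_b0 = 1)
  dwi <- array(100, dim = c(2, 2, 2, 7))
  expect_error(fit_tensor(dwi, scheme), "rank-deficient")
})

test_that("volume count must match the scheme", {
  scheme <- default_scheme()
  dwi <- array(100, dim = c(2, 2, 2, 5))
  expect_error(fit_tensor(dwi, scheme), "28")
})

test_that("eigendecomposition matches closed forms and round-trips", {
  tens <- array(0, dim = c(1, 1, 2, 6))
  tens[1, 1, 1, ] <- c(3e-3, 0, 0, 2e-3, 0, 1e-3)  # diag(3,2,1)e-3
  tens[1, 1, 2, ] <- c(1e-3, 0, 0, 1e-3, 0, 1e-3)  # isotropic
  eig <- dti_eigen(tens)
  expect_equal(eig$values[1, 1, 1, ], c(3e-3, 2e-3, 1e-3), tolerance = 1e-12)
  expect_equal(eig$values[1, 1, 2, ], rep(1e-3, 3), tolerance = 1e-12)

  set.seed(31)
  for (k in 1:20) {
    d <- random_spd_tensor()
    tt <- array(d, dim = c(1, 1, 1, 6))
    e <- dti_eigen(tt, vectors = TRUE)
    # reconstruction oracle via full eigen decomposition of the same matrix
    M <- dtithresh:::tensor_to_mat(d)
    ed <- eigen(M, symmetric = TRUE)
    recon <- ed$vectors %*% diag(ed$values) %*% t(ed$vectors)
    expect_lt(max(abs(recon - M)), 1e-12)
    expect_equal(e$values[1, 1, 1, ], ed$values, tolerance = 1e-10)
    # analytic (vectorized) eigenvalues agree with LAPACK
    ea <- dti_eigen(tt, vectors = FALSE)
    expect_equal(ea$values[1, 1, 1, ], ed$values, tolerance = 1e-9)
    # principal eigenvector matches up to sign
    v <- e$vectors[1, 1, 1, ]
    expect_equal(abs(sum(v * ed$vectors[, 1])), 1, tolerance = 1e-8)
  }
})

test_that("negative eigenvalues are retained and counted", {
  tens <- array(c(-1e-4, 0, 0, 2e-3, 0, 1e-3), dim = c(1, 1, 1, 6))
  eig <- dti_eigen(tens)
  expect_equal(eig$n_negative, 1)
  expect_equal(min(eig$values), -1e-4, tolerance = 1e-12)
})

test_that("scalar maps follow the standard definitions", {
  vals <- rbind(
    c(1e-3, 1e-3, 1e-3),
    c(1, 0, 0),
    c(1.6e-3, 0.6e-3, 0.6e-3),
    c(0, 0, 0),
    c(1e-3, -1e-4, -2e-4)
  )
  eig <- list(values = array(vals, dim = c(nrow(vals), 1, 1, 3)),
              valid = array(TRUE, dim = c(nrow(vals), 1, 1)))
  sc <- compute_scalars(eig)
  expect_equal(sc$fa[1, 1, 1], 0)
  expect_equal(sc$trace[1, 1, 1], 3e-3)
  expect_equal(sc$ad[1, 1, 1], 1e-3)
  expect_equal(sc$rd[1, 1, 1], 1e-3)
  expect_equal(sc$fa[2, 1, 1], 1)
  # independent closed-form oracle for the axially symmetric case
  expect_equal(sc$fa[3, 1, 1], fa_axial_oracle(1.6e-3, 0.6e-3),
               tolerance = 1e-12)
  expect_equal(sc$fa[3, 1, 1], fa_formula_oracle(c(1.6e-3, 0.6e-3, 0.6e-3)),
               tolerance = 1e-12)
  expect_equal(round(sc$fa[3, 1, 1], 2), 0.55)
  expect_equal(sc$fa[4, 1, 1], 0)         # all-zero: defined as 0, not NaN
  # negative eigenvalues: clamped for FA only; raw for trace/AD/RD
  expect_equal(sc$fa[5, 1, 1], fa_formula_oracle(c(1e-3, 0, 0)))
  expect_equal(sc$trace[5, 1, 1], 1e-3 - 3e-4)
  expect_equal(sc$rd[5, 1, 1], -1.5e-4)
  expect_true(all(sc$fa >= 0 & sc$fa <= 1))
})

test_that("FA is rotation- and scale-invariant; trace/AD/RD scale linearly", {
  set.seed(41)
  for (k in 1:20) {
    d <- random_spd_tensor()
    R <- random_rotation()
    dr <- dtithresh:::rotate_tensor(d, R)
    both <- array(rbind(d, dr), dim = c(2, 1, 1, 6))
    sc <- compute_scalars(dti_eigen(both))
    expect_lt(abs(sc$fa[1, 1, 1] - sc$fa[2, 1, 1]), 1e-10)
    c_scale <- runif(1, 0.5, 3)
    scaled <- array(d * c_scale, dim = c(1, 1, 1, 6))
    s1 <- compute_scalars(dti_eigen(array(d, dim = c(1, 1, 1, 6))))
    s2 <- compute_scalars(dti_eigen(scaled))
    expect_lt(abs(s2$fa - s1$fa), 1e-10)
    expect_equal(s2$trace[1], c_scale * s1$trace[1], tolerance = 1e-10)
    expect_equal(s2$ad[1], c_scale * s1$ad[1], tolerance = 1e-10)
    expect_equal(s2$rd[1], c_scale * s1$rd[1], tolerance = 1e-10)
  }
})

test_that("trace equals the eigenvalue sum to machine precision", {
  coh <- tiny_cohort()
  s <- coh$subjects[[1]]
  eig <- dti_eigen(s$tensors)
  sc <- compute_scalars(eig)
  v <- eig$values
  expect_lt(max(abs(sc$trace - (v[, , , 1] + v[, , , 2] + v[, , , 3]))), 1e-12)
})

test_that("noise-free phantom round trip reproduces ground-truth scalars", {
  rt <- small_region_table()
  tpl <- build_template(rt, grid_shape = c(24, 24, 24))
  gt <- sample_subject_tensors(tpl, rt, seed = 13)
  dwi <- simulate_dwi(gt$tensors, snr = Inf)
  sc_fit <- dwi_to_scalars(dwi, default_scheme())
  sc_true <- compute_scalars(dti_eigen(gt$tensors))
  expect_lt(max(abs(sc_fit$fa - sc_true$fa)), 1e-8)
  expect_lt(max(abs(sc_fit$trace - sc_true$trace)), 1e-8)
  expect_lt(max(abs(sc_fit$ad - sc_true$ad)), 1e-8)
  expect_lt(max(abs(sc_fit$rd - sc_true$rd)), 1e-8)
})
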