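test_that("default template declares every label and sizes regions adequately", {
  rt <- neonatal_region_table()
  tpl <- build_template(rt)
  labs <- sort(unique(as.vector(tpl)))
  expect_setequal(labs, c(rt$label_id, 98L, 99L))
  expect_length(setdiff(labs, 0L), 26)          # 12 x 2 WM + GM + CSF
  counts <- vapply(rt$label_id, function(id) sum(tpl == id), integer(1))
  expect_true(all(counts >= 50))
  # bilateral mirroring: left and right homologues have equal voxel counts
  left <- counts[rt$hemisphere == "left"]
  right <- counts[rt$hemisphere == "right"]
  expect_equal(left, right)
})

test_that("empty region table yields only background/GM/CSF labels", {
  tpl <- build_template(neonatal_region_table()[0, ], grid_shape = c(16, 16, 16))
  expect_true(all(as.vector(tpl) %in% c(0L, 98L, 99L)))
})

test_that("template building is deterministic and rejects undersized grids", {
  rt <- neonatal_region_table()
  expect_identical(build_template(rt), build_template(rt))
  err <- tryCatch(build_template(rt, grid_shape = c(14, 14, 14)),
                  error = conditionMessage)
  expect_match(err, "grid too small")
  expect_match(err, rt$name[1], fixed = TRUE)   # names the unplaceable region
})

test_that("noise-free WM voxels hit the subject target FA and AD exactly", {
  rt <- small_region_table()
  tpl <- build_template(rt, grid_shape = c(32, 32, 32))
  gt <- sample_subject_tensors(tpl, rt, subject_effects = rep(0, nrow(rt)),
                               seed = 2)
  eig <- dti_eigen(gt$tensors)
  sc <- compute_scalars(eig)
  interior <- interior_mask(tpl)
  for (r in seq_len(nrow(rt))) {
    idx <- tpl == rt$label_id[r] & interior
    expect_true(all(abs(sc$fa[idx] - rt$target_fa_mean[r]) < 1e-6),
                label = paste("FA in", rt$name[r], rt$hemisphere[r]))
    expect_true(all(abs(sc$ad[idx] - rt$target_ad_mean[r]) < 1e-9),
                label = paste("AD in", rt$name[r], rt$hemisphere[r]))
  }
})

test_that("an FA target of zero yields an isotropic tensor", {
  rt <- small_region_table()[1:2, ]
  rt$target_fa_mean <- 0
  rt$target_fa_sd <- 0
  rt$orientation_mode <- "uniform-axis"
  rt$crossing_fraction <- 0
  tpl <- build_template(rt, grid_shape = c(24, 24, 24))
  gt <- sample_subject_tensors(tpl, rt, subject_effects = c(0, 0), seed = 1)
  idx <- which(tpl == 1L & interior_mask(tpl))[1]
  at <- arrayInd(idx, dim(tpl))
  d <- gt$tensors[at[1], at[2], at[3], ]
  expect_equal(d[c(1, 4, 6)], rep(rt$target_ad_mean[1], 3), tolerance = 1e-12)
  expect_equal(d[c(2, 3, 5)], rep(0, 3))
})

test_that("CSF and GM compartments have the required scalar contrast", {
  coh <- tiny_cohort()
  tpl <- coh$template
  interior <- interior_mask(tpl)
  for (s in coh$subjects) {
    eig <- dti_eigen(s$tensors)
    sc <- compute_scalars(eig)
    expect_true(all(sc$trace[tpl == 99L & interior] > 0.006))
    expect_true(all(sc$fa[tpl == 98L & interior] < 0.15))
  }
})

test_that("crossing regions are calibrated to the target FA", {
  rt <- small_region_table()
  tpl <- build_template(rt, grid_shape = c(32, 32, 32))
  gt <- sample_subject_tensors(tpl, rt, subject_effects = rep(0, nrow(rt)),
                               seed = 4)
  sc <- compute_scalars(dti_eigen(gt$tensors))
  idx <- tpl == 1L & interior_mask(tpl)        # crossing-mode region
  expect_true(all(abs(sc$fa[idx] - 0.15) < 1e-6))
  # the mixture is genuinely two-population: middle eigenvalue exceeds the
  # smallest (an axially symmetric tensor would have them equal)
  at <- arrayInd(which(idx)[1], dim(tpl))
  ev <- sort(dti_eigen(gt$tensors)$values[at[1], at[2], at[3], ],
             decreasing = TRUE)
  expect_gt(ev[2], ev[3] + 1e-8)
})

test_that("partial-volume boundary voxels mix adjacent compartments", {
  coh <- tiny_cohort()
  tpl <- coh$template
  rt <- coh$region_table
  s <- coh$subjects[[1]]
  sc <- compute_scalars(dti_eigen(s$tensors))
  interior <- interior_mask(tpl)
  hi <- rt$label_id[rt$name == "HIGHFA" & rt$hemisphere == "left"]
  fa_interior <- mean(sc$fa[tpl == hi & interior])
  fa_boundary <- mean(sc$fa[tpl == hi & !interior])
  expect_lt(fa_boundary, fa_interior)           # GM mixing drags FA down
})

test_that("cohort generation is bit-identical under a fixed seed", {
  rt <- small_region_table()
  a <- simulate_phantom_cohort(n_subjects = 2, region_table = rt,
                               grid_shape = c(24, 24, 24), seed = 5)
  b <- simulate_phantom_cohort(n_subjects = 2, region_table = rt,
                               grid_shape = c(24, 24, 24), seed = 5)
  expect_identical(a$subjects[[1]]$dwi, b$subjects[[1]]$dwi)
  expect_identical(a$subjects[[2]]$tensors, b$subjects[[2]]$tensors)
  d <- simulate_phantom_cohort(n_subjects = 2, region_table = rt,
                               grid_shape = c(24, 24, 24), seed = 6)
  expect_false(identical(a$subjects[[1]]$dwi, d$subjects[[1]]$dwi))
})

test_that("noise-free signals follow the monoexponential closed form", {
  tens <- array(0, dim = c(2, 2, 2, 6))
  tens[, , , 1] <- 1e-3; tens[, , , 4] <- 1e-3; tens[, , , 6] <- 1e-3
  scheme <- default_scheme()
  dwi <- simulate_dwi(tens, scheme, s0 = 500, snr = Inf)
  b0 <- dwi[, , , seq_len(scheme$n_b0)]
  expect_true(all(b0 == 500))
  dirs <- dwi[, , , scheme$n_b0 + seq_len(nrow(scheme$directions))]
  # b * trace/3 = 1000 * 1e-3; stored directions carry 8-decimal precision,
  # so |g|^2 = 1 within ~2e-9 and the ratio holds to that order
  expect_equal(as.vector(dirs) / 500, rep(exp(-1), length(dirs)),
               tolerance = 1e-7)
})

test_that("simulation is seeded-deterministic and noise is at the requested level", {
  tens <- array(0, dim = c(25, 25, 20, 6))
  tens[, , , 1] <- 1e-3; tens[, , , 4] <- 1e-3; tens[, , , 6] <- 1e-3
  scheme <- default_scheme()
  a <- simulate_dwi(tens, scheme, snr = 20, seed = 9)
  b <- simulate_dwi(tens, scheme, snr = 20, seed = 9)
  expect_identical(a, b)
  # empirical SNR over >= 1e4 voxels of a b0 volume
  b0 <- a[, , , 1]
  expect_gte(length(b0), 1e4)
  snr_emp <- mean(b0) / sd(b0)
  expect_lt(abs(snr_emp - 20) / 20, 0.10)
})

test_that("non-positive-semidefinite tensors abort simulation naming the voxel", {
  tens <- array(0, dim = c(3, 3, 3, 6))
  tens[, , , 1] <- 1e-3; tens[, , , 4] <- 1e-3; tens[, , , 6] <- 1e-3
  tens[2, 3, 1, 1] <- -2e-3
  err <- tryCatch(simulate_dwi(tens, default_scheme(), snr = Inf),
                  error = conditionMessage)
  expect_match(err, "\\[2, 3, 1\\]")
})

test_that("acquisition schemes enforce unit directions and at least one b0", {
  expect_error(acquisition_scheme(matrix(c(1, 1, 0), 1, 3)), "unit norm")
  expect_error(acquisition_scheme(matrix(c(1, 0, 0), 1, 3), n_b0 = 0), "b = 0")
  sch <- default_scheme()
  expect_equal(nrow(sch$directions), 25)
  expect_equal(sch$n_b0, 3L)
  expect_equal(sch$b_value, 1000)
  expect_true(all(abs(sqrt(rowSums(sch$directions^2)) - 1) < 1e-8))
})
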