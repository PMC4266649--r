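# Shared fixtures: a small 3-region phantom cohort, cached so several test
# files can reuse it without regenerating.

small_region_table <- function() {
  data.frame(
    name = rep(c("LOWFA", "MIDFA", "HIGHFA"), each = 2),
    hemisphere = rep(c("left", "right"), 3),
    label_id = 1:6,
    target_fa_mean = rep(c(0.15, 0.30, 0.50), each = 2),
    target_fa_sd = rep(0.02, 6),
    target_ad_mean = rep(c(1.45e-3, 1.55e-3, 1.60e-3), each = 2),
    orientation_mode = rep(c("crossing", "uniform-axis", "uniform-axis"),
                           each = 2),
    crossing_fraction = rep(c(0.30, 0, 0), each = 2),
    stringsAsFactors = FALSE
  )
}

.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_phantom_cohort(
      n_subjects = 4, region_table = small_region_table(),
      grid_shape = c(32L, 32L, 32L), seed = 11
    )
  }
  .fixture_env$cohort
}

tiny_scalars <- function() {
  if (is.null(.fixture_env$scalars)) {
    coh <- tiny_cohort()
    .fixture_env$scalars <- lapply(coh$subjects, function(s) {
      dwi_to_scalars(s$dwi, coh$scheme)
    })
  }
  .fixture_env$scalars
}

tiny_study <- function() {
  if (is.null(.fixture_env$study)) {
    coh <- tiny_cohort()
    subjects <- Map(function(s, sc) list(id = s$id, scalars = sc),
                    coh$subjects, tiny_scalars())
    .fixture_env$study <- threshold_study(
      subjects, labels = coh$template, region_table = coh$region_table,
      n_perm = 2000, seed = 3
    )
  }
  .fixture_env$study
}
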