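test_that("cohort specs are validated", {
  expect_error(cohort_spec(), "master_seed")
  expect_error(cohort_spec(n_subjects = 1, master_seed = 1), ">= 2")
  expect_error(cohort_spec(n_parcels = 7, master_seed = 1), ">= 8")
  expect_error(cohort_spec(n_timepoints = 8, n_parcels = 8, master_seed = 1),
               "exceed")
  expect_error(cohort_spec(master_seed = 1,
                           loading_multipliers = c(Bogus = 3)), "unknown")
  s <- cohort_spec(master_seed = 5)
  expect_s3_class(s, "efnet_cohort_spec")
  expect_equal(s$n_runs, 4L)
})

test_that("the same master seed reproduces the cohort bitwise", {
  s <- cohort_spec(n_subjects = 3, mesh_subdivision = 2, n_timepoints = 30,
                   master_seed = 99)
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_spec(n_subjects = 3, mesh_subdivision = 2,
                                    n_timepoints = 30, master_seed = 100))
  expect_false(identical(c1$subjects[[1]]$fc, c3$subjects[[1]]$fc))
})

test_that("zero variability knobs collapse every subject onto the template", {
  co <- generate_cohort(cohort_spec(n_subjects = 3, mesh_subdivision = 2,
                                    n_timepoints = 30,
                                    amplitude_spread = 0, sigma_spread = 0,
                                    focus_jitter_sd = 0, master_seed = 7))
  for (sub in co$subjects) {
    expect_equal(sub$params$amplitude_factor, 1)
    expect_equal(sub$params$sigma_factor, 1)
    for (tg in names(sub$efield)) {
      expect_identical(as.numeric(sub$efield[[tg]]),
                       as.numeric(co$template_efield[[tg]]))
    }
  }
})

test_that("subjects draw from distinct RNG streams", {
  seeds_fc <- vapply(1:40, function(s) stream_seed(1234, s, "fc"), integer(1))
  seeds_pm <- vapply(1:40, function(s) stream_seed(1234, s, "params"),
                     integer(1))
  expect_equal(anyDuplicated(c(seeds_fc, seeds_pm)), 0L)
  # different master seeds shift every stream
  expect_false(any(seeds_fc == vapply(1:40, function(s)
    stream_seed(4321, s, "fc"), integer(1))))
})

test_that("stored run connectomes average to the subject connectome", {
  co <- generate_cohort(cohort_spec(n_subjects = 2, mesh_subdivision = 2,
                                    n_timepoints = 30, n_runs = 3,
                                    master_seed = 21), keep_runs = TRUE)
  sub <- co$subjects[[1]]
  expect_length(sub$fc_runs, 3L)
  expect_identical(average_fc_runs(sub$fc_runs), sub$fc)
  for (r in sub$fc_runs) check_connectome(r)
})

test_that("subject and group connectomes satisfy the connectome contract", {
  # raw runs are PSD (Gram structure); Fisher-z averages keep symmetry,
  # unit diagonal and range but carry no PSD guarantee
  co <- small_cohort(master_seed = 22, n_subjects = 3)
  for (m in c(lapply(co$subjects, `[[`, "fc"), list(co$group_fc))) {
    expect_silent(check_connectome(m))
  }
})

test_that("averaging run time series instead of run FC is supported", {
  s1 <- cohort_spec(n_subjects = 2, mesh_subdivision = 2, n_timepoints = 30,
                    average_order = "timeseries", master_seed = 31)
  co <- generate_cohort(s1)
  expect_silent(check_connectome(co$subjects[[1]]$fc))
  s2 <- cohort_spec(n_subjects = 2, mesh_subdivision = 2, n_timepoints = 30,
                    average_order = "fc", master_seed = 31)
  co2 <- generate_cohort(s2)
  # same draws, different combination rule: matrices differ but agree broadly
  expect_false(identical(co$subjects[[1]]$fc, co2$subjects[[1]]$fc))
  expect_gt(cor(co$subjects[[1]]$fc[upper.tri(co$subjects[[1]]$fc)],
                co2$subjects[[1]]$fc[upper.tri(co2$subjects[[1]]$fc)]), 0.5)
})

test_that("default study conditions give nonempty 0.9 V/m seeds everywhere", {
  # scaled-down check of the packaged defaults' calibration: every subject's
  # field exceeds threshold at both targets, and areas fall in a plausible
  # band around the configured means
  co <- generate_cohort(cohort_spec(n_subjects = 8, mesh_subdivision = 3,
                                    n_timepoints = 30, master_seed = 41))
  areas <- sapply(co$subjects, function(sub) {
    c(extract_seed(sub$efield$dlpfc, co$mesh)$area_mm2,
      extract_seed(sub$efield$ofc, co$mesh)$area_mm2)
  })
  expect_true(all(areas > 0))
  expect_true(all(areas[1, ] > areas[2, ] * 0.5))  # dlPFC fields run larger
})

test_that("YAML configs define cohort specs with strict keys", {
  cfg <- file.path(withr::local_tempdir(), "cohort.yaml")
  writeLines(c("n_subjects: 5", "mesh_subdivision: 2", "n_timepoints: 40",
               "master_seed: 11", "shared_fc_stream: true",
               "loading_multipliers:", "  VAN: 3.0"), cfg)
  s <- cohort_spec_from_yaml(cfg)
  expect_equal(s$n_subjects, 5L)
  expect_true(s$shared_fc_stream)
  expect_equal(s$loading_multipliers, c(VAN = 3))
  writeLines(c("master_seed: 1", "n_subject: 5"), cfg)   # typo'd key
  expect_error(cohort_spec_from_yaml(cfg), "unknown config key")
  writeLines("n_subjects: 5", cfg)
  expect_error(cohort_spec_from_yaml(cfg), "master_seed")
})
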