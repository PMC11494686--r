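test_that("zero-gain modulation is the identity", {
  sch <- small_scheme()
  run <- timeseries_run(matrix(rnorm(100 * 10), 100, 10), 0.8,
                        scheme_labels(sch),
                        design = build_task_design("object_location"),
                        task = "object_location")
  out2 <- apply_task_modulation(run, list(
    effect_spec(roi_set("v1", "V1", scheme = sch), "object_location",
                gain = 0)), sch)
  expect_identical(out2$values, run$values)
})

test_that("modulation is confined to targeted regions and phase", {
  coh <- noiseless_effect_cohort()
  sch <- roi_scheme()
  spec <- coh$spec
  # rebuild the same cohort without effects: untouched regions identical
  spec0 <- spec; spec0$effects <- list()
  coh0 <- simulate_cohort(spec0)
  run1 <- coh$runs[[1]][["object_location"]]
  run0 <- coh0$runs[[1]][["object_location"]]
  scene_idx <- roi_indices(memory_roi_sets(sch)$scene, sch)
  other <- setdiff(seq_len(sch$n_regions), scene_idx)
  expect_identical(run1$values[, other], run0$values[, other])
  expect_false(identical(run1$values[, scene_idx], run0$values[, scene_idx]))
})

test_that("doubling the gain doubles the added component's RMSSD", {
  sch <- small_scheme()
  base <- timeseries_run(matrix(0, 696, 10), 0.8, scheme_labels(sch),
                         design = build_task_design("object_location"),
                         task = "object_location")
  mk <- function(g) apply_task_modulation(base, list(
    effect_spec(roi_set("v1", "V1", scheme = sch), "object_location",
                phase = "storage", gain = g)), sch)
  r1 <- rmssd(mk(1)$values[, 1])
  r2 <- rmssd(mk(2)$values[, 1])
  expect_gt(r1, 0)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})

test_that("a right-hemisphere effect yields strictly positive laterality", {
  sch <- roi_scheme()
  # strongly damped noiseless background (a = -1): initial transients die
  # within the burn-in, so untargeted regions are numerically silent
  spec <- cohort_spec(sch, n_participants = 2, tasks = "object_location",
                      network = make_ground_truth_network(sch$n_regions, 0,
                                                          seed = 1),
                      hopf = hopf_params(a = -1, sigma = 0),
                      effects = list(effect_spec("scene", "object_location",
                                                 "storage",
                                                 hemisphere = "R")),
                      seed = 9, subject_gain_jitter_sd = 0,
                      subject_coupling_jitter_sd = 0)
  coh <- simulate_cohort(spec)
  act <- compute_activation(coh, "object_location", "storage")
  lat <- laterality(act, sch)
  scene_labs <- memory_roi_sets(sch)$scene$labels
  expect_true(all(lat$values[, scene_labs] > 0))
  non_scene <- setdiff(colnames(lat$values), scene_labs)
  expect_true(all(abs(lat$values[, non_scene]) < 1e-10))
})

test_that("cohort files have 696 rows and reproducible digests", {
  sch <- small_scheme()
  spec <- cohort_spec(sch, n_participants = 2, tasks = "object_location",
                      effects = list(), seed = 5)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  m1 <- generate_cohort(spec, d1)
  m2 <- generate_cohort(spec, d2)
  expect_identical(m1$md5, m2$md5)
  ts_files <- grep("_ts\\.tsv$", m1$file, value = TRUE)
  expect_length(ts_files, 2L)
  vals <- read_numeric_tsv(file.path(d1, ts_files[1]))
  expect_equal(nrow(vals), 696L)
  expect_equal(ncol(vals), sch$n_regions)
  # loading reproduces the in-memory cohort to write precision
  coh_mem <- simulate_cohort(spec)
  coh_dsk <- read_cohort(d1, sch)
  expect_equal(coh_dsk$runs[[1]][["object_location"]]$values,
               coh_mem$runs[[1]][["object_location"]]$values,
               tolerance = 1e-9)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort generation is a pure function of (spec, seed)", {
  sch <- small_scheme()
  spec <- cohort_spec(sch, n_participants = 2, tasks = "word_pair",
                      seed = 8, effects = list())
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$runs[[2]][["word_pair"]]$values,
                   b$runs[[2]][["word_pair"]]$values)
  spec2 <- spec; spec2$seed <- 9L
  c2 <- simulate_cohort(spec2)
  expect_false(identical(a$runs[[2]][["word_pair"]]$values,
                         c2$runs[[2]][["word_pair"]]$values))
})
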