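# Shared fixtures, built in code and cached for the test run.
fix_env <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = fix_env)) assign(name, build(), envir = fix_env)
  get(name, envir = fix_env)
}

# 10-region scheme (5 label pairs) for desk-scale network experiments.
small_scheme <- function() {
  get_fixture("small_scheme", function()
    reduced_scheme(c("V1", "V2", "V3", "V4", "FFC")))
}

# Scheme containing every a-priori ROI label plus a few visual regions
# (36 pairs, 72 regions) so battery and laterality tests resolve.
roi_scheme <- function() {
  get_fixture("roi_scheme", function() {
    labs <- unique(unlist(hopfec:::canonical_roi_labels()))
    reduced_scheme(c(labs, "V1", "V2", "V3", "V4", "FFC", "PIT"))
  })
}

# A noiseless 1-task cohort with a storage-only scene effect: the
# sharpest possible probe of effect confinement and phase selectivity.
noiseless_effect_cohort <- function() {
  get_fixture("noiseless_effect_cohort", function() {
    sch <- roi_scheme()
    spec <- cohort_spec(sch, n_participants = 3, tasks = "object_location",
                        network = make_ground_truth_network(sch$n_regions,
                                                            0, seed = 1),
                        hopf = hopf_params(sigma = 0),
                        effects = list(effect_spec("scene", "object_location",
                                                   "storage")),
                        seed = 42, subject_gain_jitter_sd = 0,
                        subject_coupling_jitter_sd = 0)
    simulate_cohort(spec)
  })
}

# Small noisy cohort over the full ROI scheme, all three tasks, default
# effect structure: the work-horse for activation/battery tests.
noisy_roi_cohort <- function() {
  get_fixture("noisy_roi_cohort", function() {
    sch <- roi_scheme()
    spec <- cohort_spec(sch, n_participants = 8, seed = 7)
    simulate_cohort(spec)
  })
}

offdiag <- function(m) m[row(m) != col(m)]

# Fabricated activation tables (participants x regions, i.i.d. noise)
# for t-test behaviour that does not depend on the generative model.
null_tables <- function(scheme, n = 23, seed = 1, effect = NULL) {
  set.seed(seed)
  tabs <- list()
  for (task in c("object_location", "reward_location", "word_pair")) {
    for (phase in c("storage", "recall")) {
      vals <- matrix(abs(rnorm(n * scheme$n_regions, 10, 2)),
                     n, scheme$n_regions)
      colnames(vals) <- scheme_labels(scheme)
      if (!is.null(effect) && task == effect$task && phase == effect$phase)
        vals[, effect$idx] <- vals[, effect$idx] + effect$delta
      tabs[[task]][[phase]] <- activation_table(vals, task, phase)
    }
  }
  tabs
}
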