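#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style difference of gammas (response peak ~5-6 s, undershoot
#' ~16 s, 1:6 undershoot ratio), sampled on a given grid and normalised
#' to unit peak.
#'
#' @param t Time grid in seconds.
#' @return Numeric vector of kernel values.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Specify a paradigm-locked activation effect
#'
#' An effect adds, to the targeted ROI / task / phase / hemisphere only, a
#' response equal to the 5-s image boxcar convolved with the double-gamma
#' HRF, scaled by `base_amplitude * gain` (times a per-subject jitter when
#' generated through a cohort).
#'
#' @param roi ROI set name (resolved via [memory_roi_sets()]) or a
#'   `"roi_set"` object.
#' @param task Task id the effect applies to.
#' @param phase `"storage"`, `"recall"` or `"both"`.
#' @param hemisphere `"both"`, `"L"` or `"R"`.
#' @param gain Dimensionless multiplier (>= 0).
#' @param base_amplitude Response amplitude in signal units.
#' @return An `"effect_spec"` object.
#' @export
effect_spec <- function(roi, task, phase = c("both", "storage", "recall"),
                        hemisphere = c("both", "L", "R"), gain = 1,
                        base_amplitude = 0.05) {
  phase <- match.arg(phase)
  hemisphere <- match.arg(hemisphere)
  stopifnot(gain >= 0, base_amplitude >= 0)
  structure(list(roi = roi, task = task, phase = phase,
                 hemisphere = hemisphere, gain = gain,
                 base_amplitude = base_amplitude),
            class = "effect_spec")
}

# Paradigm regressor: image boxcar of the phase's trials convolved with
# the HRF, on the acquisition sample grid (midpoint convention).
paradigm_regressor <- function(design, acq, phase) {
  conds <- switch(phase,
                  storage = "encoding_image",
                  recall = "retrieval_image",
                  both = c("encoding_image", "retrieval_image"),
                  stop("unknown phase: ", phase))
  mid <- (seq_len(acq$n_samples) - 0.5) * acq$TR
  ev <- design$events[design$events$condition %in% conds, , drop = FALSE]
  box <- rep(0, acq$n_samples)
  for (k in seq_len(nrow(ev)))
    box[mid >= ev$onset[k] & mid < ev$onset[k] + ev$duration[k]] <- 1
  kern <- hrf_double_gamma(seq(0, 32, by = acq$TR))
  out <- stats::convolve(box, rev(kern), type = "open")[seq_len(acq$n_samples)]
  out
}

resolve_effect_roi <- function(effect, scheme) {
  roi <- effect$roi
  if (is.character(roi)) {
    sets <- canonical_roi_labels()
    if (!roi %in% names(sets))
      stop("unknown effect ROI: ", roi)
    labs <- intersect(sets[[roi]], scheme$regions$label)
    if (!length(labs))
      stop("effect ROI '", roi, "' has no labels in the active scheme")
    roi <- roi_set(roi, labs, scheme = scheme)
  }
  roi_indices(roi, scheme, hemisphere = effect$hemisphere)
}

#' Add paradigm-locked responses to a simulated run
#'
#' Non-targeted regions are returned bit-identical; targeted regions get
#' the HRF-convolved image-boxcar response added with amplitude
#' `base_amplitude * gain * jitter`, where the per-subject jitter is
#' log-normal with the given SD (seeded).
#'
#' @param run A `"timeseries_run"` (see [timeseries_run()]).
#' @param effects List of `"effect_spec"` objects.
#' @param scheme Parcellation scheme resolving the effect ROIs.
#' @param seed Seed for the jitter draw.
#' @param jitter_sd SD of `log(jitter)` (default 0: no jitter).
#' @return The modulated `"timeseries_run"`.
#' @export
apply_task_modulation <- function(run, effects, scheme, seed = 1L,
                                  jitter_sd = 0) {
  vals <- run$values
  acq <- acquisition_params(run$TR, nrow(vals))
  set.seed(seed)
  for (e in effects) {
    if (!identical(e$task, run$meta$task)) next
    idx <- resolve_effect_roi(e, scheme)
    jit <- if (jitter_sd > 0) exp(rnorm(1, 0, jitter_sd)) else 1
    reg <- paradigm_regressor(run$design, acq, e$phase)
    add <- reg * e$base_amplitude * e$gain * jit
    vals[, idx] <- vals[, idx] + add
  }
  run$values <- vals
  run
}

#' Construct a timeseries run container
#'
#' The unit flowing through preprocessing: a time x region matrix with
#' its TR, region labels and participant/task metadata.
#'
#' @param values Time x region numeric matrix.
#' @param TR Repetition time (s).
#' @param labels Region labels in column order.
#' @param design Optional `"run_design"` attached to the run.
#' @param participant,task Optional ids stored in `meta`.
#' @return A `"timeseries_run"` object.
#' @export
timeseries_run <- function(values, TR, labels = colnames(values),
                           design = NULL, participant = NA, task = NA) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("non-finite values in timeseries")
  colnames(values) <- labels
  structure(list(values = values, TR = TR, labels = labels, design = design,
                 meta = list(participant = participant, task = task)),
            class = "timeseries_run")
}

#' Cohort specification for synthetic generation
#'
#' Defaults emulate the study conditions: 23 participants, three
#' episodic-memory tasks, one 696-sample acquisition per task at
#' TR = 0.8 s containing three encoding/baseline/retrieval cycles.
#'
#' @param scheme Parcellation scheme for the cohort.
#' @param n_participants Default 23.
#' @param tasks Task ids (default all three).
#' @param network `"ground_truth_network"`; default a density-0.3 random
#'   network on the scheme, seeded from `seed`.
#' @param hopf `"hopf_params"`.
#' @param effects List of `"effect_spec"`; default
#'   [default_effect_specs()].
#' @param acq `"acq_params"` (default 696 samples at 0.8 s).
#' @param seed Cohort master seed.
#' @param subject_gain_jitter_sd,subject_coupling_jitter_sd SDs of the
#'   log-normal per-subject multiplicative jitter on effect gains and on
#'   coupling entries (defaults 0.1).
#' @return A `"cohort_spec"` object.
#' @export
cohort_spec <- function(scheme, n_participants = 23L,
                        tasks = memory_tasks(), network = NULL,
                        hopf = hopf_params(), effects = NULL,
                        acq = acquisition_params(), seed = 1L,
                        subject_gain_jitter_sd = 0.1,
                        subject_coupling_jitter_sd = 0.1) {
  stopifnot(n_participants >= 2)
  if (is.null(network))
    network <- make_ground_truth_network(scheme$n_regions, 0.3, 0.1,
                                         seed = derive_seed(seed, 101L))
  if (is.null(effects)) effects <- default_effect_specs()
  if (network$n_regions != scheme$n_regions)
    stop("network size does not match scheme")
  structure(list(scheme = scheme, n_participants = as.integer(n_participants),
                 tasks = tasks, network = network, hopf = hopf,
                 effects = effects, acq = acq, seed = as.integer(seed),
                 subject_gain_jitter_sd = subject_gain_jitter_sd,
                 subject_coupling_jitter_sd = subject_coupling_jitter_sd),
            class = "cohort_spec")
}

#' Default task/ROI/phase/hemisphere effect structure
#'
#' The qualitative activation structure the synthetic cohorts emulate:
#' scene-stream responses in both location tasks (storage and recall),
#' semantic and left-lateralised Broca responses in the word-pair task
#' during storage, reward-system responses in the reward-location task
#' during storage, and intraparietal responses in both location tasks.
#'
#' @param base_amplitude Response amplitude in signal units (default 0.05,
#'   about one SD of the background Hopf fluctuation at the default noise
#'   level).
#' @return List of `"effect_spec"` objects.
#' @export
default_effect_specs <- function(base_amplitude = 0.05) {
  specs <- list()
  for (tk in c("object_location", "reward_location")) {
    specs <- c(specs, list(
      effect_spec("scene", tk, "both", "both", 1, base_amplitude),
      effect_spec("intraparietal", tk, "both", "both", 0.8, base_amplitude)))
  }
  c(specs, list(
    effect_spec("semantic", "word_pair", "storage", "both", 1,
                base_amplitude),
    effect_spec("broca", "word_pair", "storage", "L", 1, base_amplitude),
    effect_spec("reward", "reward_location", "storage", "both", 0.8,
                base_amplitude)))
}

# Per-participant coupling: multiplicative log-normal jitter on C_true.
participant_coupling <- function(spec, p) {
  C <- spec$network$C_true
  sdl <- spec$subject_coupling_jitter_sd
  if (sdl > 0) {
    set.seed(derive_seed(spec$seed, p, 7L))
    C <- pmin(C * matrix(exp(rnorm(length(C), 0, sdl)), nrow(C)), 0.2)
    diag(C) <- 0
  }
  C
}

#' Simulate a cohort in memory
#'
#' Runs the full generative model — per-participant jittered coupling,
#' coupled Hopf integration, paradigm-locked modulation — and returns the
#' runs as a list (no files written). A pure function of `(spec, seed)`.
#'
#' @param spec A `"cohort_spec"`.
#' @return A `"cohort"` object: list with `spec` and `runs`, where
#'   `runs[[participant]][[task]]` is a `"timeseries_run"`.
#' @export
simulate_cohort <- function(spec) {
  labels <- scheme_labels(spec$scheme)
  runs <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    Cp <- participant_coupling(spec, p)
    preruns <- list()
    for (k in seq_along(spec$tasks)) {
      task <- spec$tasks[k]
      design <- build_task_design(task)
      vals <- simulate_hopf(Cp, spec$hopf, spec$acq,
                            seed = derive_seed(spec$seed, p, k))
      colnames(vals) <- labels
      run <- timeseries_run(vals, spec$acq$TR, labels, design = design,
                            participant = p, task = task)
      run <- apply_task_modulation(run, spec$effects, spec$scheme,
                                   seed = derive_seed(spec$seed, p, k, 99L),
                                   jitter_sd = spec$subject_gain_jitter_sd)
      preruns[[task]] <- run
    }
    runs[[p]] <- preruns
  }
  structure(list(spec = spec, runs = runs), class = "cohort")
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per participant x task: a 696 x n_regions timeseries TSV, a
#' BIDS-style events TSV and a JSON sidecar (TR, task, participant, seed),
#' plus a manifest listing every file with its md5 digest. The manifest is
#' written last, so a partial write leaves no manifest. Identical
#' spec + seed produce byte-identical files.
#'
#' @param spec A `"cohort_spec"`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame (invisibly), columns `file`, `md5`.
#' @export
generate_cohort <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(spec)
  files <- character(0)
  for (p in seq_len(spec$n_participants)) {
    for (task in spec$tasks) {
      run <- cohort$runs[[p]][[task]]
      stub <- sprintf("sub-%02d_task-%s", p, task)
      ts_path <- file.path(out_dir, paste0(stub, "_ts.tsv"))
      write_numeric_tsv(run$values, ts_path)
      ev_path <- file.path(out_dir, paste0(stub, "_events.tsv"))
      write_events_tsv(run$design, ev_path)
      sc_path <- file.path(out_dir, paste0(stub, ".json"))
      jsonlite::write_json(list(TR = spec$acq$TR, task = task,
                                participant = p, seed = spec$seed),
                           sc_path, auto_unbox = TRUE, digits = NA)
      files <- c(files, ts_path, ev_path, sc_path)
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = vapply(files, file_digest, ""),
                         row.names = NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}

#' Load a cohort directory written by [generate_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @param scheme Parcellation scheme the files are expected to follow.
#' @return A `"cohort"` object (runs only; no generative spec).
#' @export
read_cohort <- function(dir, scheme) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  sc_files <- grep("\\.json$", manifest$file, value = TRUE)
  sc_files <- setdiff(sc_files, "manifest.json")
  runs <- list()
  n_max <- 0L
  for (sc in sc_files) {
    meta <- jsonlite::read_json(file.path(dir, sc), simplifyVector = TRUE)
    stub <- sub("\\.json$", "", sc)
    ts_path <- file.path(dir, paste0(stub, "_ts.tsv"))
    if (!file.exists(ts_path)) stop("missing timeseries file: ", ts_path)
    vals <- read_numeric_tsv(ts_path)
    if (!identical(colnames(vals), scheme_labels(scheme)))
      stop("region labels in ", ts_path, " do not match the scheme")
    design <- build_task_design(meta$task)
    p <- as.integer(meta$participant)
    run <- timeseries_run(vals, meta$TR, colnames(vals), design = design,
                          participant = p, task = meta$task)
    if (p > n_max) n_max <- p
    while (length(runs) < p) runs[[length(runs) + 1L]] <- list()
    runs[[p]][[meta$task]] <- run
  }
  structure(list(spec = NULL, runs = runs), class = "cohort")
}
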