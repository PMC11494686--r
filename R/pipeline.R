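# Stage logging: timestamped notes on seeds/digests, silenced unless
# log_level is "info" or finer.
log_note <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

write_sidecar <- function(path, cfg, extra = list()) {
  meta <- c(list(config_digest = config_digest(cfg), seed = cfg$seed),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

cohort_dir <- function(cfg) file.path(cfg$out_dir, "cohort")
activation_dir <- function(cfg) file.path(cfg$out_dir, "activation")

config_cohort_spec <- function(cfg, scheme) {
  net <- make_ground_truth_network(scheme$n_regions, cfg$cohort$density,
                                   cfg$cohort$strength_scale,
                                   seed = derive_seed(cfg$seed, 101L))
  cohort_spec(scheme,
              n_participants = cfg$cohort$n_participants,
              network = net,
              effects = default_effect_specs(cfg$cohort$base_amplitude),
              acq = acquisition_params(cfg$acquisition$TR,
                                       cfg$acquisition$n_samples),
              seed = cfg$seed,
              subject_gain_jitter_sd = cfg$cohort$subject_gain_jitter_sd,
              subject_coupling_jitter_sd =
                cfg$cohort$subject_coupling_jitter_sd)
}

band_from_cfg <- function(b) bandpass_spec(b$low, b$high, b$order)

#' Run one pipeline stage
#'
#' The file-based pipeline: `simulate` writes a synthetic cohort;
#' `activation` computes the six activation tables (3 tasks x 2 phases);
#' `gec` estimates the group EC per task; `stats` runs the contrast
#' battery; `report` writes per-region activation, laterality and
#' EC-asymmetry summaries. Every artifact carries a JSON sidecar with the
#' config digest and seed; reruns with unchanged config and seed are
#' byte-identical. Missing upstream artifacts raise an error naming the
#' path.
#'
#' @param command One of `"simulate"`, `"activation"`, `"gec"`,
#'   `"stats"`, `"report"`.
#' @param config A `"pipeline_config"` from [load_config()].
#' @return Character vector of written artifact paths, invisibly.
#' @export
run_command <- function(command = c("simulate", "activation", "gec",
                                    "stats", "report"),
                        config = load_config()) {
  command <- match.arg(command)
  switch(command,
         simulate = pipeline_simulate(config),
         activation = pipeline_activation(config),
         gec = pipeline_gec(config),
         stats = pipeline_stats(config),
         report = pipeline_report(config))
}

#' @rdname run_command
#' @export
pipeline_simulate <- function(config) {
  scheme <- config_scheme(config)
  spec <- config_cohort_spec(config, scheme)
  log_note(config, "simulate: ", spec$n_participants, " participants x ",
           length(spec$tasks), " tasks, seed ", config$seed)
  man <- generate_cohort(spec, cohort_dir(config))
  invisible(file.path(cohort_dir(config), man$file))
}

load_cohort_checked <- function(config, scheme) {
  dir <- cohort_dir(config)
  if (!file.exists(file.path(dir, "manifest.json")))
    stop("missing upstream cohort artifact: ",
         file.path(dir, "manifest.json"), " (run 'simulate' first)")
  read_cohort(dir, scheme)
}

activation_path <- function(cfg, task, phase)
  file.path(activation_dir(cfg), paste0("act_", task, "_", phase, ".tsv"))

#' @rdname run_command
#' @export
pipeline_activation <- function(config) {
  scheme <- config_scheme(config)
  cohort <- load_cohort_checked(config, scheme)
  dir.create(activation_dir(config), recursive = TRUE, showWarnings = FALSE)
  band <- band_from_cfg(config$activation_band)
  out <- character(0)
  for (task in memory_tasks()) {
    for (phase in c("storage", "recall")) {
      tab <- compute_activation(cohort, task, phase, band)
      path <- activation_path(config, task, phase)
      write_numeric_tsv(tab$values, path)
      write_sidecar(path, config, list(task = task, phase = phase))
      out <- c(out, path)
      log_note(config, "activation: wrote ", path)
    }
  }
  invisible(out)
}

read_activation_tables <- function(config) {
  tables <- list()
  missing_files <- character(0)
  for (task in memory_tasks()) {
    for (phase in c("storage", "recall")) {
      path <- activation_path(config, task, phase)
      if (!file.exists(path)) { missing_files <- c(missing_files, path); next }
      vals <- read_numeric_tsv(path)
      tables[[task]][[phase]] <- activation_table(vals, task, phase)
    }
  }
  if (length(missing_files))
    stop("missing upstream activation artifact(s): ",
         paste(missing_files, collapse = ", "), " (run 'activation' first)")
  tables
}

#' @rdname run_command
#' @export
pipeline_gec <- function(config) {
  scheme <- config_scheme(config)
  cohort <- load_cohort_checked(config, scheme)
  gdir <- file.path(config$out_dir, "gec")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  cfg_gec <- gec_config(tau_seconds = config$gec$tau_seconds,
                        TR = config$acquisition$TR,
                        epsilon = config$gec$epsilon,
                        max_iter = config$gec$max_iter,
                        patience = config$gec$patience,
                        clip_max = config$gec$clip_max,
                        sim_length_samples = config$gec$sim_length_samples,
                        seed = config$seed,
                        reverse_for_fmri = config$gec$reverse_for_fmri)
  band <- band_from_cfg(config$fc_band)
  out <- character(0)
  for (task in memory_tasks()) {
    conn <- cohort_connectivity(cohort, task, band = band,
                                lag_samples = cfg_gec$lag_samples,
                                hemisphere = config$gec$hemisphere)
    fit <- group_gec(conn$fc, conn$lagfc, config = cfg_gec)
    path <- file.path(gdir, paste0("ec_", task, ".tsv"))
    write_matrix_tsv(coef(fit), path,
                     meta = list(reversed = fit$reversed,
                                 band = unclass(band),
                                 lag_samples = cfg_gec$lag_samples,
                                 config_digest = config_digest(config),
                                 seed = config$seed,
                                 task = task))
    diag_path <- file.path(gdir, paste0("ec_", task, "_diagnostics.tsv"))
    write_numeric_tsv(cbind(iteration = seq_along(fit$diagnostics),
                            error = fit$diagnostics), diag_path)
    out <- c(out, path, diag_path)
    log_note(config, "gec: wrote ", path, " (best iter ", fit$best_iter, ")")
  }
  invisible(out)
}

#' @rdname run_command
#' @export
pipeline_stats <- function(config) {
  scheme <- config_scheme(config)
  tables <- read_activation_tables(config)
  battery <- default_contrast_battery(config$battery$alpha)
  report <- run_contrast_battery(tables, battery, scheme)
  path <- file.path(config$out_dir, "contrast_battery.tsv")
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, config)
  log_note(config, "stats: wrote ", path)
  invisible(path)
}

#' @rdname run_command
#' @export
pipeline_report <- function(config) {
  scheme <- config_scheme(config)
  tables <- read_activation_tables(config)
  rdir <- file.path(config$out_dir, "report")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  # per-region mean activation and laterality, per task x phase
  for (task in names(tables)) {
    for (phase in names(tables[[task]])) {
      tab <- tables[[task]][[phase]]
      hm <- hemisphere_mean(tab, scheme)
      lat <- laterality(tab, scheme)
      summ <- data.frame(label = colnames(hm),
                         mean_activation = colMeans(hm),
                         laterality_r_minus_l = colMeans(lat$values))
      path <- file.path(rdir, paste0("summary_", task, "_", phase, ".tsv"))
      write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
      write_sidecar(path, config,
                    list(task = task, phase = phase,
                         grand_mean_activation = lat$grand_mean))
      out <- c(out, path)
    }
  }
  # EC asymmetry summaries when GEC artifacts exist
  gdir <- file.path(config$out_dir, "gec")
  for (task in memory_tasks()) {
    ec_path <- file.path(gdir, paste0("ec_", task, ".tsv"))
    if (!file.exists(ec_path)) next
    ec <- read_matrix_tsv(ec_path)
    D <- directional_difference(ec$values)
    path <- file.path(rdir, paste0("ec_asymmetry_", task, ".tsv"))
    write_matrix_tsv(D, path, meta = list(task = task,
                                          config_digest =
                                            config_digest(config)))
    out <- c(out, path)
  }
  log_note(config, "report: wrote ", length(out), " summary tables")
  invisible(out)
}
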