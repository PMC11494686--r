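# Documented defaults for every config key. Nested lists mirror the
# YAML/JSON structure.
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "hopfec_out",
    scheme = NULL,            # NULL = packaged 360-region table
    log_level = "info",
    acquisition = list(TR = 0.8, n_samples = 696L),
    activation_band = list(low = 0.05, high = 0.15, order = 2L),
    fc_band = list(low = 0.008, high = 0.08, order = 2L),
    gec = list(tau_seconds = 2.0, epsilon = 0.02, max_iter = 200L,
               patience = 30L, clip_max = 0.2, sim_length_samples = 2784L,
               reverse_for_fmri = TRUE, hemisphere = "L"),
    cohort = list(n_participants = 23L, density = 0.3,
                  strength_scale = 0.1, base_amplitude = 0.05,
                  subject_gain_jitter_sd = 0.1,
                  subject_coupling_jitter_sd = 0.1),
    battery = list(alpha = 0.02))
}

merge_config <- function(defaults, user, path, problems) {
  unknown <- setdiff(names(user), names(defaults))
  for (k in unknown)
    problems$msgs <- c(problems$msgs,
                       paste0("unknown config key: ", path, k))
  for (k in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) {
        problems$msgs <- c(problems$msgs,
                           paste0(path, k, " must be a mapping"))
      } else {
        defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                      paste0(path, k, "."), problems)
      }
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) config, fills every omitted key with its
#' documented default, rejects unknown keys (typo safety), and validates
#' parameter ranges; validation reports every problem found, not just
#' the first.
#'
#' @param path Config file path, or `NULL` for the pure defaults.
#' @return A validated `"pipeline_config"` list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  problems <- new.env()
  problems$msgs <- character(0)
  cfg <- merge_config(default_config(), user, "", problems)
  # range checks
  chk <- function(ok, msg) if (!isTRUE(ok))
    problems$msgs <- c(problems$msgs, msg)
  chk(cfg$acquisition$TR > 0, "acquisition.TR must be > 0")
  chk(cfg$acquisition$n_samples >= 2, "acquisition.n_samples must be >= 2")
  nyq <- 1 / (2 * cfg$acquisition$TR)
  for (b in c("activation_band", "fc_band")) {
    lo <- cfg[[b]]$low; hi <- cfg[[b]]$high
    chk(lo >= 0 && lo < hi, paste0(b, ": must satisfy 0 <= low < high (low=",
                                   lo, ", high=", hi, ")"))
    chk(hi < nyq, paste0(b, ".high must be below the Nyquist frequency ",
                         nyq, " Hz"))
  }
  chk(cfg$gec$epsilon > 0, "gec.epsilon must be > 0")
  chk(cfg$gec$max_iter >= 1, "gec.max_iter must be >= 1")
  chk(cfg$gec$clip_max > 0, "gec.clip_max must be > 0")
  chk(cfg$gec$hemisphere %in% c("L", "R", "both"),
      "gec.hemisphere must be L, R or both")
  chk(cfg$cohort$n_participants >= 2, "cohort.n_participants must be >= 2")
  chk(cfg$cohort$density >= 0 && cfg$cohort$density <= 1,
      "cohort.density must be in [0, 1]")
  chk(cfg$battery$alpha > 0 && cfg$battery$alpha < 1,
      "battery.alpha must be in (0, 1)")
  if (!is.null(cfg$scheme))
    chk(file.exists(cfg$scheme),
        paste0("scheme file does not exist: ", cfg$scheme))
  if (length(problems$msgs))
    stop("invalid configuration:\n  ",
         paste(problems$msgs, collapse = "\n  "))
  structure(cfg, class = "pipeline_config")
}

config_scheme <- function(cfg) load_parcellation(cfg$scheme)

config_digest <- function(cfg) object_digest(unclass(cfg))
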