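#' Functional connectivity (Pearson, band-limited)
#'
#' Band-pass filters the run (slow FC band 0.008-0.08 Hz by default) and
#' returns the region x region Pearson correlation matrix.
#'
#' @param ts A `"timeseries_run"` or time x region matrix.
#' @param band A `"bandpass_spec"` or `NULL` to correlate the series as
#'   given.
#' @param TR Sampling interval (taken from the run if omitted).
#' @return An `"fc_matrix"` object: `values` (symmetric, unit diagonal),
#'   `band`, `labels`.
#' @export
functional_connectivity <- function(ts, band = fc_band(), TR = NULL) {
  vals <- if (inherits(ts, "timeseries_run")) ts$values else as.matrix(ts)
  if (!is.null(band)) vals <- bandpass(ts, band, TR = TR)
  if (inherits(vals, "timeseries_run")) vals <- vals$values
  if (nrow(vals) < 3) stop("need at least 3 samples for correlation")
  sds <- apply(vals, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(vals)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- cor(vals)
  structure(list(values = r, band = band, labels = colnames(vals)),
            class = "fc_matrix")
}

#' Time-lagged functional connectivity
#'
#' Entry (i, j) is the Pearson correlation of region i's signal with
#' region j's signal delayed by `lag_samples`:
#' `cor(x_i(1..T-lag), x_j(1+lag..T))`. Generally non-symmetric; the
#' asymmetry carries directional information.
#'
#' @param ts A `"timeseries_run"` or time x region matrix (assumed
#'   already band-limited as desired).
#' @param lag_samples Integer lag, `1 <= lag < T - 2` (0 allowed for the
#'   degenerate zero-shift case).
#' @param tau_seconds Optional nominal delay recorded in the result.
#' @return A `"lagged_fc"` object: `values`, `lag_samples`,
#'   `tau_seconds`, `labels`.
#' @export
lagged_fc <- function(ts, lag_samples, tau_seconds = NULL) {
  vals <- if (inherits(ts, "timeseries_run")) ts$values else as.matrix(ts)
  T_n <- nrow(vals)
  lag_samples <- as.integer(lag_samples)
  if (lag_samples < 0 || lag_samples >= T_n - 2)
    stop("lag_samples out of range [0, T - 3]")
  a <- vals[seq_len(T_n - lag_samples), , drop = FALSE]
  b <- vals[(1 + lag_samples):T_n, , drop = FALSE]
  r <- cor(a, b)
  structure(list(values = r, lag_samples = lag_samples,
                 tau_seconds = tau_seconds, labels = colnames(vals)),
            class = "lagged_fc")
}

#' Fisher-z average of correlation matrices
#'
#' Entry-wise `tanh(mean(atanh(r)))`; unit diagonals are preserved.
#'
#' @param mats List of correlation matrices (or `fc_matrix`/`lagged_fc`
#'   objects).
#' @return Averaged matrix of the same dimension.
#' @export
fisher_z_mean <- function(mats) {
  get_vals <- function(m) if (is.list(m)) m$values else m
  vals <- lapply(mats, get_vals)
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), TRUE)))
    stop("matrices have inconsistent dimensions")
  z <- lapply(vals, function(v) atanh(pmin(pmax(v, -1 + 1e-15), 1 - 1e-15)))
  avg <- tanh(Reduce(`+`, z) / length(z))
  # exact +/-1 entries (e.g. diagonals) survive the clamp as +/-1
  exact <- Reduce(`&`, lapply(vals, function(v) abs(v) >= 1 - 1e-12))
  if (any(exact)) avg[exact] <- vals[[1]][exact]
  dimnames(avg) <- dimnames(vals[[1]])
  avg
}

# Subset a run to one hemisphere by the _L/_R label suffix.
hemisphere_subset <- function(run, hemisphere) {
  if (hemisphere == "both") return(run)
  keep <- grepl(paste0("_", hemisphere, "$"), run$labels)
  if (!any(keep)) stop("no regions with suffix _", hemisphere)
  run$values <- run$values[, keep, drop = FALSE]
  run$labels <- run$labels[keep]
  run
}

#' Per-participant FC and lagged FC for a cohort
#'
#' Band-passes each run in the FC band, then computes the Pearson FC and
#' the tau-lagged FC per participant, optionally restricted to one
#' hemisphere (EC matrices are conventionally reported per hemisphere).
#'
#' @param cohort A `"cohort"` object.
#' @param task Task id.
#' @param band FC band (default 0.008-0.08 Hz).
#' @param lag_samples Integer lag for the lagged FC (default 3 samples,
#'   i.e. 2.4 s at TR 0.8: the integer realisation of tau = 2 s).
#' @param hemisphere `"both"`, `"L"` or `"R"`.
#' @return List with `fc` and `lagfc` (per-participant lists) and
#'   `labels`.
#' @export
cohort_connectivity <- function(cohort, task, band = fc_band(),
                                lag_samples = 3L, hemisphere = "both") {
  fc <- list(); lagfc <- list()
  for (p in seq_along(cohort$runs)) {
    run <- cohort$runs[[p]][[task]]
    if (is.null(run))
      stop("cohort is missing participant ", p, " for task ", task)
    run <- hemisphere_subset(run, hemisphere)
    filt <- if (is.null(band)) run else bandpass(run, band)
    fc[[p]] <- functional_connectivity(filt, band = NULL)
    fc[[p]]$band <- band
    lagfc[[p]] <- lagged_fc(filt, lag_samples)
  }
  list(fc = fc, lagfc = lagfc, labels = fc[[1]]$labels)
}
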