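#' Band-pass filter specification
#'
#' Two bands are used throughout: the activation band around the 0.1-Hz
#' paradigm fundamental (10-s trials: 5-s image + 5-s blank), realised as
#' 0.05-0.15 Hz, and the slow FC band 0.008-0.08 Hz.
#'
#' @param low,high Band edges in Hz; `0 <= low < high < Nyquist`.
#' @param order Butterworth order (default 2).
#' @param zero_phase Apply forward-backward (default `TRUE`), so filtering
#'   introduces no lag and phase masks stay aligned.
#' @return A `"bandpass_spec"` object.
#' @export
bandpass_spec <- function(low, high, order = 2L, zero_phase = TRUE) {
  if (low < 0 || low >= high) stop("band edges must satisfy 0 <= low < high")
  structure(list(low = low, high = high, order = as.integer(order),
                 zero_phase = zero_phase),
            class = "bandpass_spec")
}

#' @rdname bandpass_spec
#' @export
activation_band <- function() bandpass_spec(0.05, 0.15)

#' @rdname bandpass_spec
#' @export
fc_band <- function() bandpass_spec(0.008, 0.08)

#' Average vertex-level signals within regions
#'
#' @param vertex_values Time x vertex numeric matrix.
#' @param vertex_to_region Character/factor vector, one region per vertex.
#' @param region_order Optional region order of the output columns
#'   (default: order of first appearance).
#' @return Time x region matrix of per-timepoint unweighted vertex means.
#' @export
average_within_regions <- function(vertex_values, vertex_to_region,
                                   region_order = NULL) {
  vertex_values <- as.matrix(vertex_values)
  if (ncol(vertex_values) != length(vertex_to_region))
    stop("one region assignment per vertex is required")
  if (anyNA(vertex_to_region)) stop("unmapped vertex (NA region)")
  regions <- if (is.null(region_order)) unique(vertex_to_region)
             else region_order
  absent <- setdiff(regions, vertex_to_region)
  if (length(absent))
    stop("region(s) with no vertices: ", paste(absent, collapse = ", "))
  out <- matrix(NA_real_, nrow(vertex_values), length(regions),
                dimnames = list(NULL, regions))
  for (r in regions)
    out[, r] <- rowMeans(vertex_values[, vertex_to_region == r,
                                       drop = FALSE])
  out
}

#' Remove the per-region least-squares line
#'
#' @param ts A `"timeseries_run"` or time x region matrix.
#' @return Same type as the input, linearly detrended per column.
#' @export
detrend_linear <- function(ts) {
  vals <- if (inherits(ts, "timeseries_run")) ts$values else as.matrix(ts)
  if (nrow(vals) < 3) stop("detrending needs at least 3 samples")
  t_idx <- seq_len(nrow(vals))
  X <- cbind(1, t_idx)
  beta <- solve(crossprod(X), crossprod(X, vals))
  out <- vals - X %*% beta
  if (inherits(ts, "timeseries_run")) { ts$values <- out; ts } else out
}

#' Butterworth band-pass filtering
#'
#' Second-order (by default) Butterworth band-pass applied independently
#' per region, forward-backward for zero phase.
#'
#' @param ts A `"timeseries_run"` or time x region matrix.
#' @param spec A `"bandpass_spec"`.
#' @param TR Sampling interval (taken from the run if omitted).
#' @return Same type as the input, filtered.
#' @export
bandpass <- function(ts, spec, TR = NULL) {
  vals <- if (inherits(ts, "timeseries_run")) ts$values else as.matrix(ts)
  if (is.null(TR)) {
    if (!inherits(ts, "timeseries_run"))
      stop("TR must be given for a bare matrix")
    TR <- ts$TR
  }
  nyq <- 1 / (2 * TR)
  if (spec$high >= nyq)
    stop("high edge ", spec$high, " Hz is not below the Nyquist frequency ",
         nyq, " Hz")
  W <- c(spec$low, spec$high) / nyq
  bf <- signal::butter(spec$order, W, type = "pass")
  fun <- if (spec$zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- apply(vals, 2, fun)
  dimnames(out) <- dimnames(vals)
  if (inherits(ts, "timeseries_run")) { ts$values <- out; ts } else out
}

#' Average the three task cycles into one cycle template
#'
#' The three 180-s encoding/baseline/retrieval cycles of an acquisition
#' are congruent; this returns their sample-wise mean (225 samples at
#' TR = 0.8 s) per region.
#'
#' @param ts A `"timeseries_run"` with an attached design, or a matrix
#'   (then `design` and `TR` are required).
#' @param design A `"run_design"` with 3 equal-length cycles.
#' @param TR Sampling interval.
#' @return A `"timeseries_run"` holding the one-cycle template; its
#'   `meta$n_cycles` records the number of averaged segments.
#' @export
average_cycles <- function(ts, design = NULL, TR = NULL) {
  if (inherits(ts, "timeseries_run")) {
    if (is.null(design)) design <- ts$design
    if (is.null(TR)) TR <- ts$TR
    vals <- ts$values
  } else vals <- as.matrix(ts)
  if (is.null(design) || is.null(TR)) stop("design and TR are required")
  acq <- acquisition_params(TR, nrow(vals))
  b <- cycle_sample_bounds(design, acq)
  segs <- lapply(1:3, function(cyc) vals[b[cyc, 1]:b[cyc, 2], , drop = FALSE])
  avg <- (segs[[1]] + segs[[2]] + segs[[3]]) / 3
  out <- timeseries_run(avg, TR, colnames(vals), design = design,
                        participant = if (inherits(ts, "timeseries_run"))
                          ts$meta$participant else NA,
                        task = if (inherits(ts, "timeseries_run"))
                          ts$meta$task else NA)
  out$meta$n_cycles <- 3L
  out$meta$cycle_start <- b[1, 1]
  out
}

# Phase mask restricted to one cycle of the averaged template, as indices
# relative to the template's first sample.
template_phase_indices <- function(design, acq, phase) {
  m <- phase_mask(design, acq, phase)
  b <- cycle_sample_bounds(design, acq)
  idx <- which(m[b[1, 1]:b[1, 2]])
  if (!length(idx)) stop("phase '", phase, "' has no samples in a cycle")
  idx
}
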