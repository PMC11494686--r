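#' Root mean square successive difference
#'
#' The activation measure for the 0.1-Hz block paradigm:
#' `sqrt(mean((x[t+1] - x[t])^2))`. Nonnegative and scale-equivariant
#' (`rmssd(c * x) = |c| * rmssd(x)`).
#'
#' @param x Numeric vector with at least 2 samples.
#' @return Nonnegative scalar.
#' @examples
#' rmssd(c(1, -1, 1, -1))  # 2
#' @export
rmssd <- function(x) {
  if (length(x) < 2) stop("rmssd needs at least 2 samples")
  sqrt(mean(diff(x)^2))
}

#' Activation table container
#' @param values Participant x region matrix of RMSSD values.
#' @param task,phase Identifiers.
#' @param region_labels Column labels.
#' @return An `"activation_table"` object.
#' @export
activation_table <- function(values, task, phase,
                             region_labels = colnames(values)) {
  values <- as.matrix(values)
  if (any(values < 0) || !all(is.finite(values)))
    stop("activation values must be finite and nonnegative")
  colnames(values) <- region_labels
  structure(list(values = values, task = task, phase = phase,
                 region_labels = region_labels),
            class = "activation_table")
}

# One run -> per-region RMSSD vector for one phase:
# detrend -> band-pass -> cycle-average -> phase mask -> RMSSD.
run_activation <- function(run, phase, band = activation_band()) {
  pre <- detrend_linear(run)
  pre <- bandpass(pre, band)
  tmpl <- average_cycles(pre)
  acq <- acquisition_params(run$TR, nrow(run$values))
  idx <- template_phase_indices(run$design, acq, phase)
  apply(tmpl$values[idx, , drop = FALSE], 2, rmssd)
}

#' Compute RMSSD activation for a cohort
#'
#' Per participant and region: detrend, band-pass in the activation band,
#' average the three cycles, mask the phase, and take the RMSSD.
#'
#' @param cohort A `"cohort"` object ([simulate_cohort()] /
#'   [read_cohort()]).
#' @param task Task id.
#' @param phase `"storage"` or `"recall"`.
#' @param band Activation band (default [activation_band()]).
#' @return An `"activation_table"` (participants x regions).
#' @export
compute_activation <- function(cohort, task, phase = c("storage", "recall"),
                               band = activation_band()) {
  phase <- match.arg(phase)
  rows <- lapply(seq_along(cohort$runs), function(p) {
    run <- cohort$runs[[p]][[task]]
    if (is.null(run))
      stop("cohort is missing participant ", p, " for task ", task)
    run_activation(run, phase, band)
  })
  vals <- do.call(rbind, rows)
  rownames(vals) <- NULL
  activation_table(vals, task, phase)
}

# Split full labels like "V1_L" into label/hemisphere pairs via scheme.
pair_indices <- function(scheme, table_labels) {
  full <- scheme_labels(scheme)
  if (!all(table_labels %in% full))
    stop("table labels do not resolve in the scheme")
  r <- scheme$regions
  base <- r$label[match(table_labels, full)]
  hemi <- r$hemisphere[match(table_labels, full)]
  labs <- unique(base)
  li <- match(paste0(labs, "_L"), table_labels)
  ri <- match(paste0(labs, "_R"), table_labels)
  if (anyNA(li) || anyNA(ri))
    stop("unpaired label(s): ",
         paste(labs[is.na(li) | is.na(ri)], collapse = ", "))
  list(labels = labs, left = li, right = ri)
}

#' Hemisphere mean of an activation table
#'
#' @param table An `"activation_table"` over a full (paired) scheme.
#' @param scheme The matching `"parcellation"`.
#' @return Participant x (n/2) matrix, `(L + R) / 2` per paired label.
#' @export
hemisphere_mean <- function(table, scheme) {
  p <- pair_indices(scheme, table$region_labels)
  out <- (table$values[, p$left, drop = FALSE] +
            table$values[, p$right, drop = FALSE]) / 2
  colnames(out) <- p$labels
  out
}

#' Right-minus-left laterality of an activation table
#'
#' @inheritParams hemisphere_mean
#' @return List with `values` (participant x (n/2) matrix of R - L) and
#'   `grand_mean` (mean activation over all participants and regions,
#'   the baseline around which laterality is conventionally plotted).
#' @export
laterality <- function(table, scheme) {
  p <- pair_indices(scheme, table$region_labels)
  out <- table$values[, p$right, drop = FALSE] -
    table$values[, p$left, drop = FALSE]
  colnames(out) <- p$labels
  list(values = out, grand_mean = mean(table$values))
}
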