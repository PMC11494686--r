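#' Acquisition parameters
#'
#' @param TR Repetition time in seconds (default 0.8).
#' @param n_samples Samples per acquisition (default 696, i.e. 556.8 s).
#' @return An `"acq_params"` object.
#' @export
acquisition_params <- function(TR = 0.8, n_samples = 696L) {
  stopifnot(TR > 0, n_samples >= 2)
  structure(list(TR = TR, n_samples = as.integer(n_samples)),
            class = "acq_params")
}

memory_tasks <- function() c("object_location", "reward_location", "word_pair")

#' Build the episodic-memory block design for one task acquisition
#'
#' The fixed 550-s template: 10 s fixation, then three cycles, each an
#' 80-s encoding block (eight 10-s trials: 5-s image + 5-s blank), a 10-s
#' counting-backwards baseline, an 80-s retrieval block (eight trials),
#' and a second 10-s baseline. 24 encoding and 24 retrieval trials total.
#'
#' @param task One of `"object_location"`, `"reward_location"`,
#'   `"word_pair"`.
#' @return A `"run_design"` object: list with `task`, `events`
#'   (data frame: onset, duration, condition, cycle, trial) and
#'   `total_duration` (550).
#' @examples
#' d <- build_task_design("object_location")
#' sum(d$events$duration)  # 550
#' @export
build_task_design <- function(task = c("object_location", "reward_location",
                                       "word_pair")) {
  task <- match.arg(task)
  ev <- list(data.frame(onset = 0, duration = 10, condition = "fixation",
                        cycle = 0L, trial = 0L))
  t0 <- 10
  for (cyc in 1:3) {
    for (tr in 1:8) {
      ev <- c(ev, list(
        data.frame(onset = t0, duration = 5, condition = "encoding_image",
                   cycle = cyc, trial = tr),
        data.frame(onset = t0 + 5, duration = 5, condition = "encoding_blank",
                   cycle = cyc, trial = tr)))
      t0 <- t0 + 10
    }
    ev <- c(ev, list(data.frame(onset = t0, duration = 10,
                                condition = "baseline_count",
                                cycle = cyc, trial = 0L)))
    t0 <- t0 + 10
    for (tr in 1:8) {
      ev <- c(ev, list(
        data.frame(onset = t0, duration = 5, condition = "retrieval_image",
                   cycle = cyc, trial = tr),
        data.frame(onset = t0 + 5, duration = 5,
                   condition = "retrieval_blank", cycle = cyc, trial = tr)))
      t0 <- t0 + 10
    }
    ev <- c(ev, list(data.frame(onset = t0, duration = 10,
                                condition = "baseline_count",
                                cycle = cyc, trial = 0L)))
    t0 <- t0 + 10
  }
  events <- do.call(rbind, ev)
  structure(list(task = task, events = events, total_duration = t0),
            class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat("Block design for task '", x$task, "': ", nrow(x$events),
      " events, ", x$total_duration, " s\n", sep = "")
  invisible(x)
}

phase_conditions <- function(phase) {
  switch(phase,
         storage  = c("encoding_image", "encoding_blank"),
         recall   = c("retrieval_image", "retrieval_blank"),
         baseline = "baseline_count",
         fixation = "fixation",
         stop("unknown phase: ", phase))
}

#' Per-sample phase membership mask
#'
#' A sample belongs to a phase iff its acquisition midpoint time,
#' `(i - 0.5) * TR`, falls inside an event of that phase (onset inclusive,
#' offset exclusive). Samples after the design end (prompt-time padding)
#' belong to no phase. The midpoint rule resolves the non-integer
#' event/sample boundaries of the 10-s blocks at TR = 0.8 s
#' deterministically.
#'
#' @param design A `"run_design"`.
#' @param acq An `"acq_params"`; must cover the design duration.
#' @param phase One of `"storage"`, `"recall"`, `"baseline"`, `"fixation"`.
#' @return Logical vector of length `acq$n_samples`.
#' @export
phase_mask <- function(design, acq, phase = c("storage", "recall",
                                              "baseline", "fixation")) {
  phase <- match.arg(phase)
  if (acq$n_samples * acq$TR < design$total_duration)
    stop("acquisition does not cover the design duration")
  conds <- phase_conditions(phase)
  mid <- (seq_len(acq$n_samples) - 0.5) * acq$TR
  ev <- design$events[design$events$condition %in% conds, , drop = FALSE]
  mask <- rep(FALSE, acq$n_samples)
  for (k in seq_len(nrow(ev)))
    mask <- mask | (mid >= ev$onset[k] & mid < ev$onset[k] + ev$duration[k])
  mask
}

#' Sample ranges of the three task cycles
#'
#' Each cycle is a contiguous 180-s block after the 10-s fixation; samples
#' are assigned by the midpoint rule, giving three equal integer-length
#' segments (225 samples at TR 0.8).
#'
#' @inheritParams phase_mask
#' @return 3 x 2 integer matrix of first/last sample indices.
#' @export
cycle_sample_bounds <- function(design, acq) {
  mid <- (seq_len(acq$n_samples) - 0.5) * acq$TR
  cyc_dur <- (design$total_duration - 10) / 3
  bounds <- matrix(NA_integer_, 3, 2,
                   dimnames = list(paste0("cycle", 1:3), c("first", "last")))
  for (cyc in 1:3) {
    lo <- 10 + (cyc - 1) * cyc_dur
    idx <- which(mid >= lo & mid < lo + cyc_dur)
    bounds[cyc, ] <- range(idx)
  }
  len <- bounds[, 2] - bounds[, 1] + 1L
  if (length(unique(len)) != 1L)
    stop("cycle lengths unequal in samples: ", paste(len, collapse = ", "))
  bounds
}

#' Write / read a BIDS-style events table
#'
#' @param design A `"run_design"` (for writing).
#' @param path File path of the TSV.
#' @return `read_events_tsv` returns the events data frame.
#' @export
write_events_tsv <- function(design, path) {
  ev <- design$events
  names(ev)[names(ev) == "condition"] <- "trial_type"
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.table(path, header = TRUE, sep = "\t")
  names(ev)[names(ev) == "trial_type"] <- "condition"
  ev
}
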