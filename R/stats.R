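#' Per-participant ROI mean activation
#'
#' @param table An `"activation_table"`.
#' @param roi A `"roi_set"` or ROI name resolved via [memory_roi_sets()].
#' @param scheme The matching `"parcellation"`.
#' @param hemisphere Optional scope override.
#' @return Numeric vector, one unweighted mean over the ROI's region
#'   columns per participant.
#' @export
roi_mean <- function(table, roi, scheme, hemisphere = NULL) {
  if (is.character(roi)) roi <- memory_roi_sets(scheme)[[roi]]
  idx <- roi_indices(roi, scheme, hemisphere = hemisphere)
  rowMeans(table$values[, idx, drop = FALSE])
}

#' Paired t-test between two per-participant vectors
#'
#' Standard paired t on the differences `d = a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, df `n - 1`, two-tailed p. Degenerate
#' inputs follow the conventions: zero-variance differences with nonzero
#' mean give `t = +/-Inf, p = 0`; all-zero differences give
#' `t = 0, p = 1`.
#'
#' @param a,b Equal-length finite numeric vectors (n >= 2).
#' @param alpha Two-tailed significance criterion (default 0.02, the
#'   a-priori level for the pre-specified contrasts).
#' @return A `"paired_t_result"`: list with `t`, `df`, `p`, `mean_a`,
#'   `mean_b`, `n`, `significant`.
#' @export
paired_t <- function(a, b, alpha = 0.02) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite values in paired_t input")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  # same degeneracy guard as t.test: stderr below rounding noise
  if (s == 0 || s / sqrt(n) < 10 * .Machine$double.eps * abs(m)) {
    if (m == 0) { tval <- 0; p <- 1 }
    else { tval <- sign(m) * Inf; p <- 0 }
  } else {
    tt <- t.test(a, b, paired = TRUE)
    tval <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(t = tval, df = n - 1L, p = p, mean_a = mean(a),
                 mean_b = mean(b), n = n, significant = p < alpha),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t: t = %.3f, df = %d, p = %.4g (%ssignificant)\n",
              x$t, x$df, x$p, if (x$significant) "" else "not "))
  invisible(x)
}

#' Specify an a-priori contrast
#'
#' @param roi ROI name (resolved via [memory_roi_sets()]) or `"roi_set"`.
#' @param kind `"task_vs_task"` (one phase, two tasks) or
#'   `"storage_vs_recall"` (one task, both phases).
#' @param task_a First task; for `task_vs_task`, `task_b` may be a task
#'   id or `"others"` (mean of the remaining tasks) or a vector of tasks
#'   whose ROI means are averaged.
#' @param task_b Second side of a task contrast.
#' @param phase Phase of a task contrast (`"storage"` or `"recall"`).
#' @param alpha Two-tailed criterion (default 0.02).
#' @param hemisphere_scope `"both"`, `"L"` or `"R"`.
#' @return A `"contrast_spec"` object.
#' @export
contrast_spec <- function(roi, kind = c("task_vs_task", "storage_vs_recall"),
                          task_a, task_b = NULL, phase = "storage",
                          alpha = 0.02, hemisphere_scope = "both") {
  kind <- match.arg(kind)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(roi = roi, kind = kind, task_a = task_a, task_b = task_b,
                 phase = phase, alpha = alpha,
                 hemisphere_scope = match.arg(hemisphere_scope,
                                              c("both", "L", "R"))),
            class = "contrast_spec")
}

#' The packaged a-priori contrast battery
#'
#' The pre-specified hypothesis tests: scene-stream ROI higher in
#' object-location than word-pair (storage and recall); semantic ROI
#' higher in word-pair than the mean of the other tasks (storage); Broca
#' ROI (left) higher in word-pair than object-location (storage); reward
#' ROI higher in reward-location than object-location (storage);
#' intraparietal ROI higher in the location tasks than word-pair
#' (storage); and storage-versus-recall for the semantic, Broca and
#' reward ROIs.
#'
#' @param alpha Two-tailed criterion applied to every contrast
#'   (default 0.02).
#' @return List of `"contrast_spec"` objects.
#' @export
default_contrast_battery <- function(alpha = 0.02) {
  list(
    contrast_spec("scene", "task_vs_task", "object_location", "word_pair",
                  phase = "storage", alpha = alpha),
    contrast_spec("scene", "task_vs_task", "object_location", "word_pair",
                  phase = "recall", alpha = alpha),
    contrast_spec("semantic", "task_vs_task", "word_pair", "others",
                  phase = "storage", alpha = alpha),
    contrast_spec("broca", "task_vs_task", "word_pair", "object_location",
                  phase = "storage", alpha = alpha,
                  hemisphere_scope = "L"),
    contrast_spec("reward", "task_vs_task", "reward_location",
                  "object_location", phase = "storage", alpha = alpha),
    contrast_spec("intraparietal", "task_vs_task",
                  c("object_location", "reward_location"), "word_pair",
                  phase = "storage", alpha = alpha),
    contrast_spec("semantic", "storage_vs_recall", "word_pair",
                  alpha = alpha),
    contrast_spec("broca", "storage_vs_recall", "word_pair", alpha = alpha,
                  hemisphere_scope = "L"),
    contrast_spec("reward", "storage_vs_recall", "reward_location",
                  alpha = alpha))
}

# tables: named list tables[[task]][[phase]] of activation_table objects.
battery_side <- function(tables, tasks, phase, roi, scheme, hemisphere) {
  vs <- lapply(tasks, function(tk) {
    tab <- tables[[tk]][[phase]]
    if (is.null(tab)) stop("missing activation table for task '", tk,
                           "', phase '", phase, "'")
    roi_mean(tab, roi, scheme,
             hemisphere = if (hemisphere == "both") NULL else hemisphere)
  })
  Reduce(`+`, vs) / length(vs)
}

#' Run the a-priori contrast battery
#'
#' @param tables Nested list `tables[[task]][[phase]]` of
#'   `"activation_table"` objects (as produced by
#'   [pipeline_activation()] or assembled by hand).
#' @param specs List of `"contrast_spec"` (default the packaged battery).
#' @param scheme The `"parcellation"` resolving the ROIs.
#' @return Data frame with one row per contrast: roi, contrast, t, df, p,
#'   significant. No multiplicity correction beyond the per-contrast
#'   a-priori alpha is applied.
#' @export
run_contrast_battery <- function(tables, specs = default_contrast_battery(),
                                 scheme = load_parcellation()) {
  if (!length(specs))
    return(data.frame(roi = character(0), contrast = character(0),
                      t = numeric(0), df = integer(0), p = numeric(0),
                      significant = logical(0)))
  rows <- lapply(specs, function(sp) {
    if (sp$kind == "task_vs_task") {
      all_tasks <- names(tables)
      tb <- sp$task_b
      if (identical(tb, "others")) tb <- setdiff(all_tasks, sp$task_a)
      a <- battery_side(tables, sp$task_a, sp$phase, sp$roi, scheme,
                        sp$hemisphere_scope)
      b <- battery_side(tables, tb, sp$phase, sp$roi, scheme,
                        sp$hemisphere_scope)
      lab <- sprintf("%s: %s vs %s (%s)", roi_label(sp$roi),
                     paste(sp$task_a, collapse = "+"),
                     paste(tb, collapse = "+"), sp$phase)
    } else {
      a <- battery_side(tables, sp$task_a, "storage", sp$roi, scheme,
                        sp$hemisphere_scope)
      b <- battery_side(tables, sp$task_a, "recall", sp$roi, scheme,
                        sp$hemisphere_scope)
      lab <- sprintf("%s: storage vs recall (%s)", roi_label(sp$roi),
                     paste(sp$task_a, collapse = "+"))
    }
    res <- paired_t(a, b, alpha = sp$alpha)
    data.frame(roi = roi_label(sp$roi), contrast = lab, t = res$t,
               df = res$df, p = res$p, significant = res$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

roi_label <- function(roi) if (is.character(roi)) roi else roi$name
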