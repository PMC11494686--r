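#' Methods for fitted GEC objects
#'
#' A `"gec"` object behaves like a fitted model: `coef` returns the
#' directed coupling matrix (read column to row), `fitted` the simulated
#' FC at the best iterate, `residuals` the empirical-minus-simulated FC,
#' `simulate` draws new timeseries from the fitted model, and `plot`
#' draws the coupling heat map.
#'
#' @param object,x A `"gec"` object.
#' @param ... Unused.
#' @name gec-methods
NULL

#' @rdname gec-methods
#' @export
print.gec <- function(x, ...) {
  n <- nrow(x$values)
  cat("Generative effective connectivity fit\n")
  cat(sprintf("  regions: %d   orientation: column -> row   reversed: %s\n",
              n, x$reversed))
  cat(sprintf("  iterations run: %d   best iteration: %d   fit error: %.5g\n",
              length(x$diagnostics), x$best_iter, x$best_err))
  cat(sprintf("  coupling range: [%.4g, %.4g] (cap %.3g)\n",
              min(x$values), max(x$values), x$config$clip_max))
  invisible(x)
}

#' @rdname gec-methods
#' @export
summary.gec <- function(object, ...) {
  off <- object$values[row(object$values) != col(object$values)]
  s <- list(n_regions = nrow(object$values),
            reversed = object$reversed,
            iterations = length(object$diagnostics),
            best_iter = object$best_iter,
            best_err = object$best_err,
            mean_coupling = mean(off),
            max_coupling = max(off),
            nonzero_frac = mean(off > 0),
            at_cap_frac = mean(off >= object$config$clip_max - 1e-12),
            fc_fit_cor = cor(object$fc_emp[upper.tri(object$fc_emp)],
                             object$fc_sim[upper.tri(object$fc_sim)]))
  class(s) <- "summary.gec"
  s
}

#' @export
print.summary.gec <- function(x, ...) {
  cat("GEC fit summary\n")
  cat(sprintf("  %d regions, %d iterations (best %d), error %.5g\n",
              x$n_regions, x$iterations, x$best_iter, x$best_err))
  cat(sprintf("  off-diagonal coupling: mean %.4g, max %.4g, %.0f%% nonzero, %.0f%% at cap\n",
              x$mean_coupling, x$max_coupling, 100 * x$nonzero_frac,
              100 * x$at_cap_frac))
  cat(sprintf("  empirical vs simulated FC correlation: %.3f\n",
              x$fc_fit_cor))
  cat(sprintf("  directionality reversed for fMRI: %s\n", x$reversed))
  invisible(x)
}

#' @rdname gec-methods
#' @export
coef.gec <- function(object, ...) object$values

#' @rdname gec-methods
#' @export
fitted.gec <- function(object, ...) object$fc_sim

#' @rdname gec-methods
#' @export
residuals.gec <- function(object, ...) object$fc_emp - object$fc_sim

#' @rdname gec-methods
#' @param nsim Number of simulated runs.
#' @param seed Seed for the draws.
#' @param acq `"acq_params"` of each simulated run.
#' @export
simulate.gec <- function(object, nsim = 1, seed = 1L,
                         acq = acquisition_params(), ...) {
  # coupling as used generatively: undo the reporting reversal if set
  C <- if (object$reversed) t(object$values) else object$values
  out <- lapply(seq_len(nsim), function(k)
    simulate_hopf(C, object$hopf, acq, seed = derive_seed(seed, k),
                  burn_in = object$config$burn_in))
  if (nsim == 1) out[[1]] else out
}

#' @rdname gec-methods
#' @param main Plot title.
#' @export
plot.gec <- function(x, main = "Effective connectivity (column to row)",
                     ...) {
  v <- x$values
  n <- nrow(v)
  graphics::image(seq_len(n), seq_len(n), t(v)[, n:1],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "from (column)", ylab = "to (row)",
                  main = main, ...)
  if (!is.null(x$labels) && n <= 40) {
    graphics::axis(1, at = seq_len(n), labels = x$labels, las = 2,
                   cex.axis = 0.6)
    graphics::axis(2, at = seq_len(n), labels = rev(x$labels), las = 2,
                   cex.axis = 0.6)
  }
  graphics::box()
  invisible(x)
}
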