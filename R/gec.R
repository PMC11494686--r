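#' GEC fitting configuration
#'
#' Hyperparameters of the generative-effective-connectivity fit. The
#' nominal measurement delay tau is 2 s; at TR = 0.8 s the integer lag is
#' `round away from zero(tau / TR) = 3` samples (2.4 s). Coupling
#' estimates are clipped to `[0, 0.2]`.
#'
#' @param tau_seconds Nominal delay (default 2).
#' @param TR Sampling interval of the empirical series (default 0.8).
#' @param lag_samples Integer lag; default derived from `tau_seconds`.
#' @param epsilon Gradient step on the coupling updates (default 0.02;
#'   chosen by ground-truth recovery calibration, see the vignette).
#' @param max_iter Maximum fitting iterations (default 200).
#' @param patience Iterations without improvement before stopping
#'   (default 30; the per-iteration error is itself stochastic, so short
#'   patience stops far from convergence).
#' @param clip_min,clip_max Coupling bounds (defaults 0 and 0.2).
#' @param sim_length_samples Samples simulated per iteration (default
#'   2784 = 4 acquisitions; longer simulations reduce gradient noise).
#' @param seed Master seed; each iteration's simulation is re-seeded
#'   deterministically from `(seed, iteration)`.
#' @param reverse_for_fmri Apply the fMRI directionality reversal to the
#'   returned matrix (default `TRUE`; see [reverse_directionality()]).
#' @param burn_in Discarded transient per simulation, seconds.
#' @return A `"gec_config"` object.
#' @export
gec_config <- function(tau_seconds = 2.0, TR = 0.8, lag_samples = NULL,
                       epsilon = 0.02, max_iter = 200L, patience = 30L,
                       clip_min = 0, clip_max = 0.2,
                       sim_length_samples = 2784L, seed = 1L,
                       reverse_for_fmri = TRUE, burn_in = 60) {
  if (is.null(lag_samples)) {
    # round half away from zero: tau = 2 s at TR 0.8 -> 2.5 -> 3 samples
    x <- tau_seconds / TR
    lag_samples <- as.integer(trunc(x) + sign(x) * (abs(x - trunc(x)) >= 0.5))
  }
  stopifnot(epsilon > 0, clip_min < clip_max, max_iter >= 1,
            sim_length_samples >= 10, lag_samples >= 1)
  structure(list(tau_seconds = tau_seconds, TR = TR,
                 lag_samples = as.integer(lag_samples), epsilon = epsilon,
                 max_iter = as.integer(max_iter),
                 patience = as.integer(patience), clip_min = clip_min,
                 clip_max = clip_max,
                 sim_length_samples = as.integer(sim_length_samples),
                 seed = as.integer(seed),
                 reverse_for_fmri = isTRUE(reverse_for_fmri),
                 burn_in = burn_in),
            class = "gec_config")
}

#' Fit generative effective connectivity
#'
#' Iteratively adjusts a directed coupling matrix C (oriented column to
#' row) of the whole-brain Hopf model so that the model's simulated FC
#' and tau-lagged FC match the empirical ones:
#' \deqn{C_{ij} \leftarrow C_{ij} + \epsilon [(FC^{emp} - FC^{sim})_{ij}
#'   + (FC_\tau^{emp} - FC_\tau^{sim})_{ij}]}
#' for `i != j`, clipped to `[clip_min, clip_max]` after each update.
#' The fit error is `MSE(FC) + MSE(lagged FC)`; the matrix achieving the
#' minimum error is returned. If `reverse_for_fmri` is set, the fMRI
#' directionality reversal is applied before returning.
#'
#' @param fc_emp Empirical `"fc_matrix"`. Its band (if any) is also
#'   applied to each simulated series so model and data are compared in
#'   the same band.
#' @param lagfc_emp Empirical `"lagged_fc"` at the config's lag.
#' @param hopf `"hopf_params"` of the generative model.
#' @param config A `"gec_config"`.
#' @return An object of class `"gec"`; see [coef.gec()] and friends.
#'   Components include `values` (the EC matrix), `reversed`,
#'   `diagnostics` (per-iteration error), `best_iter`, `fc_emp`,
#'   `fc_sim`, `lagfc_emp`, `lagfc_sim`, `hopf`, `config`, `labels`.
#' @examples
#' \donttest{
#' net <- make_ground_truth_network(5, 0.4, seed = 1)
#' ts <- simulate_hopf(net, hopf_params(), acquisition_params(), seed = 2)
#' fc <- functional_connectivity(ts, band = NULL, TR = 0.8)
#' lfc <- lagged_fc(ts, 3)
#' fit <- fit_gec(fc, lfc, config = gec_config(max_iter = 20))
#' }
#' @export
fit_gec <- function(fc_emp, lagfc_emp, hopf = hopf_params(),
                    config = gec_config()) {
  if (!identical(dim(fc_emp$values), dim(lagfc_emp$values)))
    stop("FC and lagged-FC dimensions differ")
  if (!is.null(fc_emp$labels) && !is.null(lagfc_emp$labels) &&
      !identical(fc_emp$labels, lagfc_emp$labels))
    stop("FC and lagged-FC labels differ")
  n <- nrow(fc_emp$values)
  labels <- fc_emp$labels
  acq <- acquisition_params(config$TR, config$sim_length_samples)
  C <- matrix(0, n, n)
  best <- list(err = Inf, C = C, iter = 0L, fc = NULL, lagfc = NULL)
  errs <- numeric(0)
  stall <- 0L
  for (iter in seq_len(config$max_iter)) {
    sim <- simulate_hopf(C, hopf, acq,
                         seed = derive_seed(config$seed, iter),
                         burn_in = config$burn_in)
    if (!is.null(fc_emp$band))
      sim <- bandpass(sim, fc_emp$band, TR = config$TR)
    if (!all(is.finite(sim)))
      stop("non-finite simulated series at iteration ", iter)
    fc_sim <- cor(sim)
    lag_sim <- lagged_fc(sim, config$lag_samples)$values
    if (!all(is.finite(fc_sim)) || !all(is.finite(lag_sim)))
      stop("non-finite simulated statistics at iteration ", iter)
    d_fc <- fc_emp$values - fc_sim
    d_lag <- lagfc_emp$values - lag_sim
    err <- mean(d_fc^2) + mean(d_lag^2)
    errs <- c(errs, err)
    if (err < best$err) {
      best <- list(err = err, C = C, iter = iter, fc = fc_sim,
                   lagfc = lag_sim)
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= config$patience) break
    # The lagged-FC difference enters transposed so that the entry
    # driving C[i, j] (coupling j -> i, column to row) is the lag
    # statistic in which region j leads region i; orientation validated
    # by ground-truth recovery (see the methods vignette).
    C <- C + config$epsilon * (d_fc + t(d_lag))
    diag(C) <- 0
    C <- pmin(pmax(C, config$clip_min), config$clip_max)
  }
  values <- best$C
  dimnames(values) <- list(labels, labels)
  reversed <- FALSE
  fit <- structure(list(values = values, reversed = reversed,
                        diagnostics = errs, best_iter = best$iter,
                        best_err = best$err, fc_emp = fc_emp$values,
                        fc_sim = best$fc, lagfc_emp = lagfc_emp$values,
                        lagfc_sim = best$lagfc, hopf = hopf,
                        config = config, labels = labels),
                   class = "gec")
  if (config$reverse_for_fmri) fit <- reverse_directionality(fit)
  fit
}

#' Reverse the directionality of an EC estimate
#'
#' For slow fMRI with tau on the order of seconds, the fitted directed
#' influences are interpreted in the reversed direction; this transposes
#' the matrix (entry (r, c) swaps with (c, r)), toggles the `reversed`
#' flag and keeps the column-to-row reading convention. An involution.
#'
#' @param ec A `"gec"` object (or any list with `values` and `reversed`).
#' @return The reversed object.
#' @export
reverse_directionality <- function(ec) {
  ec$values <- t(ec$values)
  ec$reversed <- !isTRUE(ec$reversed)
  ec
}

#' Directional difference of an EC matrix
#'
#' `D = C - t(C)`: positive entries mean stronger coupling from the
#' column region to the row region than the reverse. Antisymmetric by
#' construction.
#'
#' @param ec A `"gec"` object or a bare matrix.
#' @return Antisymmetric matrix of the same dimension.
#' @export
directional_difference <- function(ec) {
  v <- if (is.list(ec)) ec$values else as.matrix(ec)
  v - t(v)
}

#' Group-level GEC
#'
#' Fisher-z-averages the participants' FC and lagged-FC matrices, then
#' fits the GEC on the averages (the group estimate used for split-half
#' reliability).
#'
#' @param fc_list,lagfc_list Per-participant lists of `"fc_matrix"` /
#'   `"lagged_fc"` objects with identical labels.
#' @param hopf,config As in [fit_gec()].
#' @return A `"gec"` object.
#' @export
group_gec <- function(fc_list, lagfc_list, hopf = hopf_params(),
                      config = gec_config()) {
  if (length(fc_list) < 2) stop("need at least 2 participants")
  labs <- lapply(fc_list, `[[`, "labels")
  if (!all(vapply(labs, identical, TRUE, labs[[1]])))
    stop("inconsistent labels across participants")
  fc_avg <- fc_list[[1]]
  fc_avg$values <- fisher_z_mean(fc_list)
  lag_avg <- lagfc_list[[1]]
  lag_avg$values <- fisher_z_mean(lagfc_list)
  fit_gec(fc_avg, lag_avg, hopf = hopf, config = config)
}

#' Split-half reliability of the group EC
#'
#' Randomly splits the participants into halves of sizes `floor(n/2)` and
#' `ceiling(n/2)` (23 participants split 11 / 12), estimates the group
#' GEC in each half with the same configuration (hence the same
#' orientation), and returns the Pearson correlation of the vectorised
#' off-diagonal entries.
#'
#' @param fc_list,lagfc_list Per-participant connectivity lists.
#' @param hopf,config As in [fit_gec()].
#' @param split_seed Seed of the random split.
#' @return List with `r` (the correlation), `halves` (participant index
#'   split) and the two `"gec"` fits.
#' @export
split_half_reliability <- function(fc_list, lagfc_list,
                                   hopf = hopf_params(),
                                   config = gec_config(), split_seed = 1L) {
  n <- length(fc_list)
  if (n < 4) stop("need at least 4 participants for a split-half estimate")
  set.seed(split_seed)
  idx <- sample(n)
  h1 <- sort(idx[seq_len(n %/% 2)])
  h2 <- sort(idx[(n %/% 2 + 1):n])
  cfg1 <- config; cfg1$seed <- derive_seed(config$seed, 1L)
  cfg2 <- config; cfg2$seed <- derive_seed(config$seed, 2L)
  g1 <- group_gec(fc_list[h1], lagfc_list[h1], hopf, cfg1)
  g2 <- group_gec(fc_list[h2], lagfc_list[h2], hopf, cfg2)
  off <- upper.tri(g1$values) | lower.tri(g1$values)
  r <- cor(g1$values[off], g2$values[off])
  list(r = r, halves = list(h1, h2), fit1 = g1, fit2 = g2)
}
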