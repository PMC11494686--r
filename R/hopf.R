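#' Hopf model parameters
#'
#' Parameters of the coupled Hopf normal-form (Stuart-Landau) oscillator
#' model used both to generate synthetic BOLD and inside GEC fitting.
#' Each region sits near a Hopf bifurcation: for bifurcation parameter
#' `a > 0` the noiseless node settles on a limit cycle of amplitude
#' `sqrt(a)`; for `a < 0` it is a stable focus driven by noise.
#'
#' @param a Bifurcation parameter, scalar or per-region (default -0.02).
#' @param f Intrinsic oscillation frequency in Hz (default 0.05; the
#'   angular frequency is `2 * pi * f`). Scalar or per-region.
#' @param G Global coupling scale (default 1).
#' @param sigma Noise standard deviation in signal units (default 0.01).
#' @param dt Euler-Maruyama integration step in seconds (default 0.1).
#' @return A `"hopf_params"` object.
#' @export
hopf_params <- function(a = -0.02, f = 0.05, G = 1.0, sigma = 0.01,
                        dt = 0.1) {
  stopifnot(dt > 0, sigma >= 0, G >= 0, all(f > 0))
  structure(list(a = a, omega = 2 * pi * f, G = G, sigma = sigma, dt = dt),
            class = "hopf_params")
}

#' Random ground-truth coupling network
#'
#' Draws a directed coupling matrix (orientation column to row) for
#' synthetic cohorts: each off-diagonal entry is nonzero with probability
#' `density`, with magnitude `|N(0, strength_scale)|` clipped into
#' `[0, 0.2]` — the same cap the GEC estimator enforces.
#'
#' @param n Number of regions (>= 2).
#' @param density Edge probability in `[0, 1]`.
#' @param strength_scale SD of the half-normal magnitude draw (default 0.1).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A `"ground_truth_network"` object with `C_true` (n x n) and
#'   `n_regions`.
#' @export
make_ground_truth_network <- function(n, density, strength_scale = 0.1,
                                      seed = 1L) {
  stopifnot(n >= 2, strength_scale >= 0)
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  set.seed(seed)
  edge <- matrix(rbinom(n * n, 1, density), n, n)
  mag <- matrix(abs(rnorm(n * n, 0, strength_scale)), n, n)
  C <- pmin(edge * mag, 0.2)
  diag(C) <- 0
  structure(list(C_true = C, n_regions = n), class = "ground_truth_network")
}

#' Simulate coupled Hopf oscillators
#'
#' Euler-Maruyama integration of the coupled noisy Hopf model
#' \deqn{dx_j = [(a_j - x_j^2 - y_j^2) x_j - \omega_j y_j +
#'       G \sum_i C_{ji} (x_i - x_j)] dt + \sigma dW}
#' (and the symmetric equation for `y`), with `C` oriented column to row.
#' The x component is subsampled at the TR after a discarded burn-in.
#'
#' @param network A `"ground_truth_network"`, or a bare coupling matrix.
#' @param hopf A `"hopf_params"`.
#' @param acq An `"acq_params"`; `TR / dt` must be an integer.
#' @param seed Integer seed (initial conditions and noise).
#' @param burn_in Discarded initial transient in seconds (default 60).
#' @return Numeric matrix, `n_samples` x `n` regions.
#' @examples
#' net <- make_ground_truth_network(4, 0.5, seed = 2)
#' ts <- simulate_hopf(net, hopf_params(), acquisition_params(n_samples = 100),
#'                     seed = 3)
#' dim(ts)
#' @export
simulate_hopf <- function(network, hopf = hopf_params(),
                          acq = acquisition_params(), seed = 1L,
                          burn_in = 60) {
  C <- if (inherits(network, "ground_truth_network")) network$C_true
       else as.matrix(network)
  n <- nrow(C)
  sub <- acq$TR / hopf$dt
  if (abs(sub - round(sub)) > 1e-9)
    stop("TR must be an integer multiple of the integration step dt")
  sub <- as.integer(round(sub))
  if (hopf$dt > acq$TR) stop("dt must not exceed TR")
  a <- rep_len(hopf$a, n)
  omega <- rep_len(hopf$omega, n)
  set.seed(seed)
  x0 <- rnorm(n, 0, 0.1)
  y0 <- rnorm(n, 0, 0.1)
  burn_steps <- as.integer(round(burn_in / hopf$dt))
  out <- hopf_sim_core(C, a, omega, hopf$G, hopf$sigma, hopf$dt,
                       acq$n_samples, sub, burn_steps, x0, y0)
  colnames(out) <- colnames(C)
  out
}
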