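#' Model parameters for the binary E/I network
#'
#' Bundles the scalar parameters of the recurrent network and its external
#' drive. The network has \code{N} neurons, a fraction \code{alpha} of which
#' are inhibitory; every directed pair is connected independently with
#' probability \code{p}. Outgoing excitatory weights are drawn uniformly in
#' \eqn{[0, w]} and inhibitory weights uniformly in \eqn{[-g w, 0]}, so the
#' mean excitatory weight is \eqn{w/2} and the mean inhibitory weight is
#' \eqn{-g w/2}; \code{g} is the I/E weight ratio. Each neuron additionally
#' fires with probability \code{p_ext} per step regardless of its input.
#'
#' @param N neuron count (default 1000).
#' @param p connection probability (default 0.2).
#' @param alpha inhibitory fraction; \code{alpha * N} must be an integer
#'   (default 0.2).
#' @param w excitatory weight scale, the maximum excitatory weight (> 0).
#' @param g I/E weight ratio (>= 0).
#' @param p_ext per-neuron external firing probability per step
#'   (default \code{0.005 / N}, i.e. one externally driven spike per 200
#'   steps across the whole network).
#' @return An object of class \code{"model_params"}.
#' @examples
#' model_params(w = 0.0125, g = 0)
#' @export
model_params <- function(N = 1000, p = 0.2, alpha = 0.2, w = 0.0125, g = 0,
                         p_ext = 0.005 / N) {
  stopifnot(length(N) == 1, length(p) == 1, length(alpha) == 1,
            length(w) == 1, length(g) == 1, length(p_ext) == 1)
  N <- as.integer(N)
  if (N < 2) stop("N must be >= 2")
  if (!(p > 0 && p <= 1)) stop("p must be in (0, 1]")
  if (!(alpha >= 0 && alpha < 1)) stop("alpha must be in [0, 1)")
  if (abs(alpha * N - round(alpha * N)) > 1e-8)
    stop("alpha * N must be an integer number of inhibitory neurons")
  if (!(w > 0)) stop("w must be > 0")
  if (g < 0) stop("g must be >= 0")
  if (!(p_ext >= 0 && p_ext <= 1)) stop("p_ext must be in [0, 1]")
  structure(list(N = N, p = p, alpha = alpha, w = w, g = g, p_ext = p_ext),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Binary E/I network parameters\n")
  cat(sprintf("  N = %d (%d excitatory, %d inhibitory), p = %g\n",
              x$N, n_excitatory(x), n_inhibitory(x), x$p))
  cat(sprintf("  w = %g, g = %g (I/E ratio), p_ext = %g\n",
              x$w, x$g, x$p_ext))
  invisible(x)
}

n_inhibitory <- function(params) as.integer(floor(params$alpha * params$N + 0.5))
n_excitatory <- function(params) params$N - n_inhibitory(params)

#' Simulation run configuration
#'
#' Run length, burn-in and initial condition for [simulate_network()]. The
#' model itself does not fix these; the defaults are long enough for stable
#' avalanche statistics at desk scale while keeping single runs fast.
#'
#' @param steps total simulated steps, including burn-in.
#' @param burn_in initial steps discarded before any analysis.
#' @param initial_active number of neurons active at t = 0 (or a fraction
#'   in (0, 1), interpreted relative to N at simulation time).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(steps = 2e5, burn_in = 1e4, initial_active = 10) {
  steps <- as.integer(steps); burn_in <- as.integer(burn_in)
  if (!(steps > burn_in && burn_in >= 0))
    stop("need steps > burn_in >= 0")
  if (initial_active < 0) stop("initial_active must be >= 0")
  structure(list(steps = steps, burn_in = burn_in,
                 initial_active = initial_active),
            class = "sim_config")
}

#' Derive a child RNG seed from a master seed
#'
#' Counter-based derivation used by the sweep drivers so that any single
#' (g, w, seed) cell of a sweep can be re-run in isolation. The map is a
#' fixed affine congruence modulo the Mersenne prime 2^31 - 1; distinct
#' (master, index) pairs used in one sweep give distinct children.
#'
#' @param master master seed (integer).
#' @param index non-negative counter.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(master, index) {
  m <- 2147483647
  x <- (as.double(master) %% m) * 48271 + 7919 * (as.double(index) + 1)
  as.integer(x %% (m - 1) + 1)
}
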