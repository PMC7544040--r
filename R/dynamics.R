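#' Recurrent synaptic input for a given network state
#'
#' Computes \eqn{I_i = \sum_j J_{ij} s_j} for a binary state vector s: the
#' total synaptic input each neuron would receive at the next step.
#'
#' @param J square coupling matrix (or a \code{"connectivity"} object).
#' @param state binary vector of length N.
#' @return Numeric input vector of length N.
#' @export
synaptic_input <- function(J, state) {
  if (inherits(J, "connectivity")) J <- J$J
  if (length(state) != ncol(J)) stop("state length must equal N")
  if (!all(state %in% c(0, 1))) stop("state must be binary")
  drop(J %*% state)
}

#' One update of the probabilistic binary dynamics
#'
#' The recurrent firing probability of neuron i is its clamped synaptic
#' input, \eqn{p_i = \min(\max(I_i, 0), 1)}; a neuron with \eqn{I_i \ge 1}
#' fires with certainty and one with \eqn{I_i < 0} cannot fire recurrently.
#' External drive is then applied independently, so the total firing
#' probability is \eqn{1 - (1 - p_i)(1 - p_{ext})}. This pure-R step is the
#' reference implementation used to validate the compiled simulator.
#'
#' @param J coupling matrix or \code{"connectivity"} object.
#' @param state current binary state vector.
#' @param p_ext external firing probability per neuron per step.
#' @return The next binary state vector.
#' @export
step_network <- function(J, state, p_ext = 0) {
  I <- synaptic_input(J, state)
  p <- pmin(pmax(I, 0), 1)
  fired <- stats::runif(length(p)) < p
  fired <- fired | (stats::runif(length(p)) < p_ext)
  as.integer(fired)
}

#' Simulate the binary E/I network
#'
#' Iterates the dynamics for \code{config$steps} synchronous updates from an
#' initial state with \code{config$initial_active} active neurons, discarding
#' the burn-in window. The heavy loop is compiled; with the same
#' connectivity, configuration and seed the spike raster is reproduced
#' bit for bit.
#'
#' @param conn a [build_connectivity()] object.
#' @param config a [sim_config()] object.
#' @param seed RNG seed for the dynamics (independent of the connectivity
#'   seed).
#' @return An object of class \code{"spike_raster"}: event vectors
#'   \code{neuron} and \code{time} (times 1..steps - burn_in, post burn-in),
#'   per-step active \code{counts}, per-neuron \code{mean_state}, and the
#'   generating objects.
#' @export
simulate_network <- function(conn, config = sim_config(), seed = 1) {
  stopifnot(inherits(conn, "connectivity"), inherits(config, "sim_config"))
  N <- conn$params$N
  k0 <- config$initial_active
  if (k0 > 0 && k0 < 1) k0 <- round(k0 * N)
  k0 <- as.integer(k0)
  if (k0 > N) stop("initial_active exceeds N")
  set.seed(as.integer(seed))
  init <- if (k0 > 0) sample.int(N, k0) else integer(0)
  res <- sim_core(conn$J, config$steps, config$burn_in, init,
                  conn$params$p_ext)
  structure(list(neuron = res$neuron, time = res$time, counts = res$counts,
                 mean_state = res$mean_state, N = N,
                 steps_kept = config$steps - config$burn_in,
                 params = conn$params, config = config,
                 seed = as.integer(seed), conn_seed = conn$seed),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike raster: N = %d, %d steps kept, %d spikes (mean S = %.4f)\n",
              x$N, x$steps_kept, length(x$neuron),
              mean(x$counts) / x$N))
  invisible(x)
}

#' Dense binary state matrix of a raster
#'
#' Expands the event-list raster into a neurons x time 0/1 matrix. Intended
#' for small rasters (tests, fixtures, input decomposition on windows); large
#' runs should stay in event-list form.
#'
#' @param raster a \code{"spike_raster"} object.
#' @param window optional integer range of kept time steps to expand.
#' @return Integer matrix N x length(window).
#' @export
raster_matrix <- function(raster, window = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.null(window)) window <- seq_len(raster$steps_kept)
  keep <- raster$time %in% window
  m <- matrix(0L, raster$N, length(window))
  if (any(keep)) {
    tpos <- match(raster$time[keep], window)
    m[cbind(raster$neuron[keep], tpos)] <- 1L
  }
  m
}

#' Population firing rate series
#'
#' The population activity \eqn{S(t)} is the fraction of neurons active at
#' step t. Returns the series with its time mean and standard deviation, the
#' two quantities that distinguish the synchronous (large relative
#' fluctuations) from the asynchronous (small relative fluctuations) regime.
#'
#' @param raster a \code{"spike_raster"} object, or a vector of active
#'   counts with \code{N} supplied.
#' @param N network size when \code{raster} is a plain count vector.
#' @return An object of class \code{"rate_series"}: \code{S}, \code{mean_rate},
#'   \code{std_rate}.
#' @export
population_rate <- function(raster, N = NULL) {
  if (inherits(raster, "spike_raster")) {
    counts <- raster$counts; N <- raster$N
  } else {
    counts <- raster
    if (is.null(N)) stop("supply N for a plain count vector")
  }
  if (length(counts) == 0) stop("empty series")
  S <- counts / N
  structure(list(S = S, mean_rate = mean(S),
                 std_rate = stats::sd(S)),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("rate series: %d steps, mean S = %.4f, sd S = %.4f\n",
              length(x$S), x$mean_rate, x$std_rate))
  invisible(x)
}

#' Save / load a spike raster as a plain-text event list
#'
#' Events are written as a two-column CSV (neuron, time) with a JSON sidecar
#' carrying the model parameters, run configuration and seeds.
#'
#' @param raster a \code{"spike_raster"} object.
#' @param path base path; \code{<path>.csv} and \code{<path>.json} are
#'   written.
#' @return \code{write_raster}: the base path, invisibly;
#'   \code{read_raster}: the reconstructed raster.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  utils::write.csv(data.frame(neuron = raster$neuron, time = raster$time),
                   paste0(path, ".csv"), row.names = FALSE)
  side <- list(params = unclass(raster$params),
               config = unclass(raster$config),
               N = raster$N, steps_kept = raster$steps_kept,
               seed = raster$seed, conn_seed = raster$conn_seed)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- utils::read.csv(paste0(path, ".csv"))
  counts <- tabulate(ev$time, nbins = side$steps_kept)
  params <- do.call(model_params, as.list(side$params))
  config <- do.call(sim_config, as.list(side$config))
  ms <- numeric(side$N)
  tab <- tabulate(ev$neuron, nbins = side$N)
  ms <- tab / side$steps_kept
  structure(list(neuron = ev$neuron, time = ev$time, counts = counts,
                 mean_state = ms, N = side$N, steps_kept = side$steps_kept,
                 params = params, config = config,
                 seed = side$seed, conn_seed = side$conn_seed),
            class = "spike_raster")
}

#' Export the population-rate series as CSV
#'
#' @param raster a \code{"spike_raster"} object.
#' @param path output CSV path (columns t, S).
#' @export
write_rate_csv <- function(raster, path) {
  r <- population_rate(raster)
  utils::write.csv(data.frame(t = seq_along(r$S), S = r$S), path,
                   row.names = FALSE)
  invisible(path)
}
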