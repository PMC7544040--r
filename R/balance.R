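#' Decompose synaptic input into excitatory and inhibitory streams
#'
#' Splits the total synaptic input \eqn{I_i(t)} into the excitatory part
#' \eqn{I^E_i(t)} (only positive couplings count) and the inhibitory part
#' \eqn{I^I_i(t) \le 0} (only negative couplings), with
#' \eqn{I_i = I^E_i + I^I_i} exactly. Input at kept step t is driven by the
#' state at t - 1; the first column uses the state preceding the window, so
#' decompositions start at the second kept step when only a raster window is
#' available.
#'
#' @param J coupling matrix or \code{"connectivity"} object.
#' @param states binary N x T state matrix (e.g. from [raster_matrix()]).
#' @return An object of class \code{"input_decomposition"} with N x (T-1)
#'   matrices \code{I_E}, \code{I_I}, \code{I_total} (inputs at steps
#'   2..T of the supplied window).
#' @export
decompose_inputs <- function(J, states) {
  if (inherits(J, "connectivity")) J <- J$J
  if (!is.matrix(states) || nrow(states) != ncol(J))
    stop("states must be an N x T matrix matching J")
  if (ncol(states) < 2) stop("need at least 2 time steps")
  pre <- states[, -ncol(states), drop = FALSE]
  Jp <- pmax(J, 0)
  Jm <- pmin(J, 0)
  I_E <- Jp %*% pre
  I_I <- Jm %*% pre
  structure(list(I_E = I_E, I_I = I_I, I_total = I_E + I_I),
            class = "input_decomposition")
}

#' E/I tension of a network
#'
#' The tension of neuron i measures how tightly its time-averaged inhibitory
#' input cancels its excitatory input:
#' \deqn{T_i = 1 - \frac{\langle I_i \rangle}
#'   {\langle I^E_i \rangle + \langle |I^I_i| \rangle},}
#' which is 0 without inhibition and 1 under exact mean cancellation. The
#' network tension is the mean of \eqn{T_i} over neurons with nonzero total
#' drive.
#'
#' Given a raster, the time averages are computed through the linearity of
#' the input in the presynaptic state: \eqn{\langle I^E_i \rangle =
#' (J^+ \bar{s})_i} with \eqn{\bar{s}} the per-neuron mean activity over the
#' post-burn-in window (and likewise for the inhibitory part, whose sign is
#' constant), so no input time series needs to be stored.
#'
#' @param x an \code{"input_decomposition"} or a \code{"spike_raster"}.
#' @param conn the \code{"connectivity"} used to generate the raster
#'   (required for the raster method).
#' @return An object of class \code{"tension_result"} with per-neuron
#'   \code{T_i}, network mean \code{T}, and \code{n_excluded} (neurons with
#'   zero total drive).
#' @export
ei_tension <- function(x, conn = NULL) {
  if (inherits(x, "input_decomposition")) {
    mean_E <- rowMeans(x$I_E)
    mean_absI <- rowMeans(abs(x$I_I))
  } else if (inherits(x, "spike_raster")) {
    if (!inherits(conn, "connectivity"))
      stop("supply the connectivity used to generate the raster")
    sbar <- x$mean_state
    mean_E <- drop(pmax(conn$J, 0) %*% sbar)
    mean_absI <- drop(abs(pmin(conn$J, 0) %*% sbar))
  } else stop("x must be an input_decomposition or spike_raster")
  denom <- mean_E + mean_absI
  ok <- denom > 0
  T_i <- rep(NA_real_, length(denom))
  T_i[ok] <- 1 - (mean_E[ok] - mean_absI[ok]) / denom[ok]
  structure(list(T_i = T_i, T = mean(T_i[ok]),
                 n_excluded = sum(!ok)),
            class = "tension_result")
}

#' @export
print.tension_result <- function(x, ...) {
  cat(sprintf("E/I tension: T = %.4f (%d neurons excluded)\n",
              x$T, x$n_excluded))
  invisible(x)
}

#' Population-averaged input cross-correlograms
#'
#' Reconstructs the excitatory, inhibitory and total synaptic input series
#' for a subset of neurons over a window of the raster and computes lagged
#' correlations, averaged over a random sample of ordered neuron pairs, at
#' lags \code{-max_lag .. max_lag}. Each series is standardized over the
#' window (mean subtracted, unit variance), so the zero-lag value for a pair
#' is its Pearson correlation; constant series are excluded. The E and I
#' correlograms pair E-inputs with E-inputs and I-inputs with I-inputs. The
#' area under each correlogram is its plain sum over lags (negative lobes
#' subtract).
#'
#' @param conn the \code{"connectivity"} that generated the raster.
#' @param raster a \code{"spike_raster"}.
#' @param n_neurons number of neurons whose input series are reconstructed
#'   (default 60; pairs are sampled among these).
#' @param max_lag maximum lag in steps (default 20).
#' @param window_len length of the analysis window in kept steps
#'   (default 5000, taken from the start of the post-burn-in record).
#' @param n_pairs number of ordered neuron pairs averaged (default 2000).
#' @param seed RNG seed for the neuron/pair sample.
#' @return An object of class \code{"ccg_set"}: \code{lags},
#'   \code{ccg_total}, \code{ccg_EE}, \code{ccg_II}, areas \code{A_total},
#'   \code{A_EE}, \code{A_II}, and \code{n_pairs}.
#' @export
input_ccg <- function(conn, raster, n_neurons = 60, max_lag = 20,
                      window_len = 5000, n_pairs = 2000, seed = 1) {
  stopifnot(inherits(conn, "connectivity"), inherits(raster, "spike_raster"))
  N <- raster$N
  W <- min(window_len, raster$steps_kept)
  if (W < 4 * max_lag) stop("window too short for the requested lags")
  set.seed(as.integer(seed))
  sub <- sort(sample.int(N, min(n_neurons, N)))
  states <- raster_matrix(raster, window = seq_len(W))
  pre <- states[, -W, drop = FALSE]
  X_E <- pmax(conn$J[sub, , drop = FALSE], 0) %*% pre
  X_I <- pmin(conn$J[sub, , drop = FALSE], 0) %*% pre
  X_T <- X_E + X_I

  std_rows <- function(X) {
    mu <- rowMeans(X)
    X <- X - mu
    sd <- sqrt(rowMeans(X^2))
    keep <- sd > 0
    X[keep, ] <- X[keep, , drop = FALSE] / sd[keep]
    list(X = X, keep = keep)
  }
  sE <- std_rows(X_E); sI <- std_rows(X_I); sT <- std_rows(X_T)
  # neurons qualify on their total input; a constant E or I stream stays a
  # zero row after standardization and contributes no correlation
  keep <- sT$keep
  if (sum(keep) < 2) stop("fewer than 2 neurons with nonconstant inputs")
  M <- sum(keep)
  XE <- sE$X[keep, , drop = FALSE]
  XI <- sI$X[keep, , drop = FALSE]
  XT <- sT$X[keep, , drop = FALSE]

  pairs_all <- which(matrix(TRUE, M, M) & !diag(TRUE, M), arr.ind = TRUE)
  take <- sample.int(nrow(pairs_all), min(n_pairs, nrow(pairs_all)))
  pa <- pairs_all[take, , drop = FALSE]

  lags <- -max_lag:max_lag
  Tlen <- ncol(XT)
  avg_ccg <- function(X) {
    vapply(lags, function(l) {
      if (l >= 0) {
        A <- X[, 1:(Tlen - l), drop = FALSE]
        B <- X[, (1 + l):Tlen, drop = FALSE]
      } else {
        A <- X[, (1 - l):Tlen, drop = FALSE]
        B <- X[, 1:(Tlen + l), drop = FALSE]
      }
      C <- tcrossprod(A, B) / ncol(A)
      mean(C[pa])
    }, numeric(1))
  }
  ccg_T <- avg_ccg(XT); ccg_E <- avg_ccg(XE); ccg_I <- avg_ccg(XI)
  structure(list(lags = lags, ccg_total = ccg_T, ccg_EE = ccg_E,
                 ccg_II = ccg_I, A_total = sum(ccg_T), A_EE = sum(ccg_E),
                 A_II = sum(ccg_I), n_pairs = nrow(pa)),
            class = "ccg_set")
}

#' @export
print.ccg_set <- function(x, ...) {
  cat(sprintf("input CCGs over %d ordered pairs, lags %d..%d\n",
              x$n_pairs, min(x$lags), max(x$lags)))
  cat(sprintf("  areas: total %.3f, EE %.3f, II %.3f\n",
              x$A_total, x$A_EE, x$A_II))
  invisible(x)
}

#' Asynchrony index from input correlogram areas
#'
#' \deqn{\eta = 1 - \frac{A_{Total}}{(A_{EE} + A_{II})/2}.}
#' When the total-input correlations vanish while the separate E and I
#' streams remain correlated (tight cancellation), \eqn{\eta \to 1}; when
#' the total correlogram carries as much area as the E and I ones,
#' \eqn{\eta = 0}.
#'
#' @param ccgs a \code{"ccg_set"} (or any list with \code{A_total},
#'   \code{A_EE}, \code{A_II}).
#' @return The asynchrony index (numeric scalar, <= 1 when areas are
#'   non-negative).
#' @export
asynchrony_index <- function(ccgs) {
  denom <- (ccgs$A_EE + ccgs$A_II) / 2
  if (abs(denom) < .Machine$double.eps)
    stop("degenerate denominator: A_EE + A_II is zero")
  1 - ccgs$A_total / denom
}

#' Inter-spike-interval coefficient of variation
#'
#' Per-neuron ISIs are differences of consecutive spike times in discrete
#' steps; \eqn{CV_i = sd(ISI_i)/mean(ISI_i)}. Poisson-like (geometric)
#' firing gives CV near 1, bursty firing CV above 1, periodic firing 0.
#' Neurons with fewer than \code{min_spikes} spikes are excluded from the
#' population mean and counted.
#'
#' @param raster a \code{"spike_raster"}, or a list of per-neuron spike-time
#'   vectors.
#' @param min_spikes minimum spikes for a neuron to enter the mean
#'   (default 3, i.e. at least 2 ISIs).
#' @return An object of class \code{"isi_stats"}: per-neuron \code{cv}
#'   (NA where excluded), \code{mean_cv}, \code{n_included},
#'   \code{n_excluded}.
#' @export
isi_cv <- function(raster, min_spikes = 3) {
  if (inherits(raster, "spike_raster")) {
    if (length(raster$neuron) == 0) stop("all-silent raster")
    spike_times <- split(raster$time, factor(raster$neuron,
                                             levels = seq_len(raster$N)))
  } else spike_times <- raster
  cv <- vapply(spike_times, function(st) {
    if (length(st) < min_spikes) return(NA_real_)
    isi <- diff(sort(st))
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  ok <- !is.na(cv)
  if (!any(ok)) stop("no neuron has enough spikes")
  structure(list(cv = cv, mean_cv = mean(cv[ok]),
                 n_included = sum(ok), n_excluded = sum(!ok)),
            class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  cat(sprintf("ISI CV: mean %.4f over %d neurons (%d excluded)\n",
              x$mean_cv, x$n_included, x$n_excluded))
  invisible(x)
}

#' Export CCG curves as CSV
#'
#' @param ccgs a \code{"ccg_set"}.
#' @param path output CSV path (columns lag, ccg_total, ccg_EE, ccg_II).
#' @export
write_ccg_csv <- function(ccgs, path) {
  utils::write.csv(data.frame(lag = ccgs$lags, ccg_total = ccgs$ccg_total,
                              ccg_EE = ccgs$ccg_EE, ccg_II = ccgs$ccg_II),
                   path, row.names = FALSE)
  invisible(path)
}
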