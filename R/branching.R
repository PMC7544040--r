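#' Empirical branching function of a network realization
#'
#' The branching function \eqn{\Lambda(S)} is the expected one-step growth
#' ratio of population activity conditioned on the current active fraction,
#' \eqn{\Lambda(S) = E[S(t+1) | S(t) = S] / S}. It is estimated by imposing
#' \eqn{S(1) = k/N} (activating k uniformly chosen neurons), sampling one
#' forward step of the recurrent dynamics, and averaging \eqn{S(2)/S(1)} over
#' trials. External drive is excluded: the branching function measures
#' recurrent propagation only.
#'
#' @param conn a [build_connectivity()] object.
#' @param S_grid active fractions to probe; each must be a multiple of 1/N.
#'   Default: every k/N up to 0.5.
#' @param n_trials forward samples per grid point (default 200).
#' @param seed RNG seed for the trials.
#' @return An object of class \code{"branching_curve"} with \code{S},
#'   \code{Lambda}, \code{stderr}, \code{method = "empirical"},
#'   \code{n_trials}, and the generating params.
#' @export
branching_empirical <- function(conn, S_grid = NULL, n_trials = 200,
                                seed = 1) {
  stopifnot(inherits(conn, "connectivity"))
  N <- conn$params$N
  if (is.null(S_grid)) S_grid <- seq_len(ceiling(N / 2)) / N
  ks <- as.integer(round(S_grid * N))
  if (any(abs(ks / N - S_grid) > 1e-9))
    stop("S_grid values must be multiples of 1/N")
  if (any(ks < 1)) stop("S_grid must be positive")
  set.seed(as.integer(seed))
  m <- branching_trials(conn$J, ks, as.integer(n_trials))
  structure(list(S = ks / N, Lambda = m[, 1], stderr = m[, 2],
                 method = "empirical", n_trials = n_trials,
                 params = conn$params),
            class = "branching_curve")
}

#' Semi-analytic branching function of the network ensemble
#'
#' Noise-free prediction of \eqn{\Lambda(S)} from the connectivity ensemble:
#' the numbers of active excitatory and inhibitory presynaptic neurons are
#' taken as Poisson with means \eqn{\mu_E = N p (1-\alpha) S} and
#' \eqn{\mu_I = N p \alpha S}, each contributing its average weight, and the
#' clamped-linear transfer \eqn{\sigma} of the dynamics is averaged over
#' both:
#' \deqn{\Lambda(S) = \frac{1}{S} \sum_{n_E} \sum_{n_I}
#'   P(n_E) P(n_I)\, \sigma\!\left(\tfrac{w}{2} n_E - \tfrac{g w}{2} n_I\right).}
#' The sums run from zero (the zero-count term carries Poisson mass even
#' though its \eqn{\sigma} value vanishes) and are truncated where the
#' Poisson tail mass drops below \code{tail_tol}.
#'
#' @param params a [model_params()] object.
#' @param S_grid active fractions (multiples of 1/N; default up to 0.5).
#' @param tail_tol Poisson tail mass at which the sums are truncated.
#' @return A \code{"branching_curve"} with \code{method = "semianalytic"}.
#' @export
branching_semianalytic <- function(params, S_grid = NULL,
                                   tail_tol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  N <- params$N
  if (is.null(S_grid)) S_grid <- seq_len(ceiling(N / 2)) / N
  if (any(S_grid <= 0)) stop("S_grid must be positive")
  w <- params$w; g <- params$g; p <- params$p; a <- params$alpha
  Lambda <- vapply(S_grid, function(S) {
    mu_E <- N * p * (1 - a) * S
    mu_I <- N * p * a * S
    nE <- 0:max(1, stats::qpois(tail_tol, mu_E, lower.tail = FALSE))
    nI <- 0:max(1, stats::qpois(tail_tol, mu_I, lower.tail = FALSE))
    pE <- stats::dpois(nE, mu_E)
    pI <- stats::dpois(nI, mu_I)
    drive <- outer(nE * w / 2, nI * g * w / 2, `-`)
    sig <- pmin(pmax(drive, 0), 1)
    as.numeric(pE %*% sig %*% pI) / S
  }, numeric(1))
  structure(list(S = S_grid, Lambda = Lambda, stderr = rep(0, length(S_grid)),
                 method = "semianalytic", n_trials = NA_integer_,
                 params = params),
            class = "branching_curve")
}

#' @export
print.branching_curve <- function(x, ...) {
  cat(sprintf("branching curve (%s): %d grid points, S in [%g, %g]\n",
              x$method, length(x$S), min(x$S), max(x$S)))
  invisible(x)
}

# Linear interpolation of the largest-S downward crossing of `level`.
# Returns NA when the curve never crosses from above to below the level.
.cross_down <- function(S, Lambda, level) {
  above <- Lambda >= level
  idx <- which(above[-length(above)] & !above[-1])
  if (length(idx) == 0) return(NA_real_)
  i <- max(idx)
  S[i] + (level - Lambda[i]) * (S[i + 1] - S[i]) / (Lambda[i + 1] - Lambda[i])
}

#' Critical range of a branching curve
#'
#' The critical range \eqn{\rho = S_2 - S_1} measures how wide an activity
#' interval the branching function spends near 1: \eqn{S_1} is the activity
#' where \eqn{\Lambda} crosses 1.05 and \eqn{S_2} where it crosses 0.95,
#' both located by linear interpolation between grid points. With several
#' crossings, the largest-S crossing of 1.05 is taken and the first 0.95
#' crossing beyond it. A flat curve that never reaches 1.05 falls back to
#' \eqn{S_1 =} smallest grid S; if 0.95 is never crossed, \eqn{S_2 =}
#' largest grid S with \eqn{\Lambda \ge 0.95}. Fallbacks are flagged.
#'
#' @param curve a \code{"branching_curve"}.
#' @param upper,lower the two levels bracketing 1 (defaults 1.05 and 0.95).
#' @return List with \code{S1}, \code{S2}, \code{rho}, and logical flags
#'   \code{S1_fallback}, \code{S2_fallback}.
#' @export
critical_range <- function(curve, upper = 1.05, lower = 0.95) {
  stopifnot(inherits(curve, "branching_curve"))
  S <- curve$S; L <- curve$Lambda
  S1 <- .cross_down(S, L, upper)
  S1_fb <- is.na(S1)
  if (S1_fb) S1 <- min(S)
  after <- S >= S1
  S2 <- .cross_down(S[after], L[after], lower)
  S2_fb <- is.na(S2)
  if (S2_fb) {
    ok <- which(L >= lower & S >= S1)
    S2 <- if (length(ok)) max(S[ok]) else S1
  }
  list(S1 = S1, S2 = S2, rho = max(S2 - S1, 0),
       S1_fallback = S1_fb, S2_fallback = S2_fb)
}

#' Avalanche detection threshold from a branching curve
#'
#' The avalanche threshold is the activity level \eqn{S^\dagger} at which
#' the branching function falls to 1.01 (largest such crossing, by linear
#' interpolation); population excursions above it are counted as avalanches.
#' A curve that never reaches 1.01 — the exactly-critical flat case — falls
#' back to the single-neuron level \eqn{S^\dagger = 1/N}, flagged.
#'
#' @param curve a \code{"branching_curve"} (the semi-analytic curve is
#'   preferred, being noise-free).
#' @param level branching level defining the threshold (default 1.01).
#' @return List with \code{S_dagger} (fraction), \code{count} (absolute
#'   neuron-count threshold \eqn{\lceil S^\dagger N \rceil}) and
#'   \code{fallback}.
#' @export
avalanche_threshold <- function(curve, level = 1.01) {
  stopifnot(inherits(curve, "branching_curve"))
  N <- curve$params$N
  Sd <- .cross_down(curve$S, curve$Lambda, level)
  fb <- is.na(Sd)
  if (fb) Sd <- 1 / N
  list(S_dagger = Sd, count = as.integer(ceiling(Sd * N)), fallback = fb)
}

#' Export a branching curve as CSV
#'
#' @param curve a \code{"branching_curve"}.
#' @param path output CSV path (columns S, Lambda, stderr, method).
#' @export
write_branching_csv <- function(curve, path) {
  utils::write.csv(data.frame(S = curve$S, Lambda = curve$Lambda,
                              stderr = curve$stderr, method = curve$method),
                   path, row.names = FALSE)
  invisible(path)
}
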