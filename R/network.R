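#' Build a random E/I connectivity matrix
#'
#' Draws one quenched realization of the signed weighted connectivity matrix
#' J. Entry \code{J[j, i]} is the synapse from presynaptic neuron i to
#' postsynaptic neuron j. The first \code{(1 - alpha) * N} neurons are
#' excitatory (columns in \eqn{[0, w]}), the rest inhibitory (columns in
#' \eqn{[-g w, 0]}). Each off-diagonal entry is nonzero independently with
#' probability p; the diagonal is zero (no self-connections).
#'
#' @param params a [model_params()] object.
#' @param seed RNG seed; one (seed, g, w) triple identifies one network
#'   realization.
#' @return An object of class \code{"connectivity"}: a list with the dense
#'   matrix \code{J}, index vectors \code{excitatory} and \code{inhibitory},
#'   and the generating \code{params} and \code{seed}.
#' @examples
#' conn <- build_connectivity(model_params(N = 100, w = 0.05, g = 2), seed = 1)
#' range(conn$J[, conn$inhibitory])
#' @export
build_connectivity <- function(params, seed) {
  stopifnot(inherits(params, "model_params"))
  N <- params$N
  n_inh <- n_inhibitory(params)
  n_exc <- N - n_inh
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(N * N) < params$p, N, N)
  mag <- matrix(stats::runif(N * N), N, N)
  J <- mask * mag * params$w
  if (n_inh > 0) {
    inh <- (n_exc + 1):N
    J[, inh] <- -params$g * J[, inh]
  }
  diag(J) <- 0
  structure(list(J = J,
                 excitatory = seq_len(n_exc),
                 inhibitory = if (n_inh > 0) (n_exc + 1):N else integer(0),
                 params = params, seed = as.integer(seed)),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("E/I connectivity: N = %d (%d E / %d I), seed %d\n",
              x$params$N, length(x$excitatory), length(x$inhibitory), x$seed))
  cat(sprintf("  density %.4f, w = %g, g = %g\n",
              mean(x$J[row(x$J) != col(x$J)] != 0), x$params$w, x$params$g))
  invisible(x)
}

#' Closed-form eigenvalue theory of the connectivity ensemble
#'
#' For the random E/I matrix ensemble the spectrum consists of a bulk of
#' complex eigenvalues inside a disc of radius R centred at the origin plus
#' one real outlier lambda_b set by the net mean excitation minus inhibition:
#' \deqn{\lambda_b = \frac{w}{2} N p (1-\alpha) - \frac{g w}{2} N p \alpha,}
#' \deqn{R = \sqrt{N[(1-\alpha)\sigma_E^2 + \alpha \sigma_I^2]},}
#' with element variances \eqn{\sigma_E^2 = (p/3 - p^2/4) w^2} and
#' \eqn{\sigma_I^2 = (p/3 - p^2/4) (g w)^2} (variance over all entries of a
#' sub-matrix, zeros included). The largest eigenvalue is
#' \eqn{\lambda_{max} = \max(\lambda_b, R)}.
#'
#' @param params a [model_params()] object.
#' @return An object of class \code{"eigen_theory"} with fields
#'   \code{lambda_b}, \code{R}, \code{lambda_max}, \code{sigma2_E},
#'   \code{sigma2_I}.
#' @export
eigen_theory <- function(params) {
  stopifnot(inherits(params, "model_params"))
  N <- params$N; p <- params$p; a <- params$alpha
  w <- params$w; g <- params$g
  lambda_b <- (w / 2) * N * p * (1 - a) - (g * w / 2) * N * p * a
  v <- p / 3 - p^2 / 4
  sigma2_E <- v * w^2
  sigma2_I <- v * (g * w)^2
  R <- sqrt(N * ((1 - a) * sigma2_E + a * sigma2_I))
  structure(list(lambda_b = lambda_b, R = R,
                 lambda_max = max(lambda_b, R),
                 sigma2_E = sigma2_E, sigma2_I = sigma2_I),
            class = "eigen_theory")
}

#' @export
print.eigen_theory <- function(x, ...) {
  cat(sprintf("lambda_b = %.6g, R = %.6g, lambda_max = %.6g\n",
              x$lambda_b, x$R, x$lambda_max))
  invisible(x)
}

#' Crossover I/E weight ratio between outlier- and bulk-dominated spectra
#'
#' Whether the outlier \eqn{\lambda_b} or the bulk radius R dominates the
#' spectrum depends only on g, not on w. Setting \eqn{\lambda_b(g) = R(g)}
#' and squaring gives the quadratic \eqn{A g^2 - 2 B g + C = 0} with
#' \eqn{A = p\alpha^2 - (4/3 - p)\alpha/N}, \eqn{B = p\alpha(1-\alpha)},
#' \eqn{C = p(1-\alpha)^2 - (4/3 - p)(1-\alpha)/N}. The physical crossover is
#' the root \eqn{g^* = (B - \sqrt{B^2 - AC})/A}, which lies where
#' \eqn{\lambda_b \ge 0}; the companion root is an artifact of squaring. As
#' \eqn{N \to \infty} both roots collapse to \eqn{(1-\alpha)/\alpha}.
#'
#' @param params a [model_params()] object with \code{alpha > 0}; \code{w}
#'   and \code{g} are ignored (the crossover is independent of both).
#' @param method \code{"closed_form"} (default); \code{"root"}, a bisection
#'   solve of \eqn{\lambda_b(g) = R(g)} used as an independent cross-check;
#'   or \code{"large_N"}, the infinite-network limit \eqn{(1-\alpha)/\alpha}.
#' @return The crossover ratio g* (numeric scalar).
#' @examples
#' crossover_ratio(model_params())  # about 3.34 for N = 1000
#' crossover_ratio(model_params(), method = "large_N")  # exactly 4
#' @export
crossover_ratio <- function(params,
                            method = c("closed_form", "root", "large_N")) {
  stopifnot(inherits(params, "model_params"))
  method <- match.arg(method)
  N <- params$N; p <- params$p; a <- params$alpha
  if (a <= 0) stop("crossover requires alpha > 0")
  if (method == "large_N") {
    (1 - a) / a
  } else if (method == "closed_form") {
    A <- p * a^2 - (4 / 3 - p) * a / N
    B <- p * a * (1 - a)
    C <- p * (1 - a)^2 - (4 / 3 - p) * (1 - a) / N
    disc <- B^2 - A * C
    if (disc < 0 || A <= 0)
      stop("no positive real crossover for these parameters")
    (B - sqrt(disc)) / A
  } else {
    f <- function(g) {
      th <- eigen_theory(model_params(N = N, p = p, alpha = a, w = 1, g = g,
                                      p_ext = params$p_ext))
      th$lambda_b - th$R
    }
    upper <- (1 - a) / a  # lambda_b = 0 here, R > 0: f < 0
    if (f(0) <= 0) stop("no crossing: bulk dominates at g = 0")
    stats::uniroot(f, c(0, upper), tol = 1e-13)$root
  }
}

#' Synaptic weight scale on the critical boundary
#'
#' Solves for the weight scale w* at which the largest eigenvalue of the
#' connectivity ensemble equals 1 for a given I/E ratio g. Below the
#' crossover g* the outlier branch applies,
#' \eqn{w^* = 1 / [\frac{Np}{2}((1-\alpha) - g\alpha)]}; at and above g* the
#' bulk-radius branch applies,
#' \eqn{w^* = 1 / \sqrt{N (p/3 - p^2/4)((1-\alpha) + \alpha g^2)}}.
#'
#' @param g I/E weight ratio (scalar or vector, >= 0).
#' @param params a [model_params()] object supplying N, p, alpha (its w and g
#'   are ignored).
#' @return w* such that \code{eigen_theory()} at (g, w*) gives
#'   \code{lambda_max == 1} to machine precision.
#' @examples
#' boundary_weight(0)  # 0.0125 for the default network
#' boundary_weight(4)  # about 0.0664
#' @export
boundary_weight <- function(g, params = model_params()) {
  stopifnot(inherits(params, "model_params"), all(g >= 0))
  N <- params$N; p <- params$p; a <- params$alpha
  gstar <- if (a > 0) crossover_ratio(params) else Inf
  vapply(g, function(gi) {
    if (gi < gstar) {
      denom <- (N * p / 2) * ((1 - a) - gi * a)
      if (denom <= 0) stop("outlier branch unbounded at g = ", gi)
      1 / denom
    } else {
      1 / sqrt(N * (p / 3 - p^2 / 4) * ((1 - a) + a * gi^2))
    }
  }, numeric(1))
}

#' Empirical eigenvalue spectrum of one connectivity realization
#'
#' Full eigendecomposition of a sampled J, summarising the largest-modulus
#' eigenvalue and the largest real part. For boundary networks the summary
#' modulus fluctuates around the theoretical \code{lambda_max} at the few-
#' percent level for N = 1000.
#'
#' @param conn a [build_connectivity()] object (or a square matrix).
#' @return List with \code{values} (complex eigenvalues),
#'   \code{lambda_max_mod} (largest modulus), \code{lambda_max_re}
#'   (largest real part).
#' @export
empirical_spectrum <- function(conn) {
  J <- if (inherits(conn, "connectivity")) conn$J else conn
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("J must be square")
  ev <- eigen(J, only.values = TRUE)$values
  list(values = ev,
       lambda_max_mod = max(Mod(ev)),
       lambda_max_re = max(Re(ev)))
}

#' Save / load a connectivity realization as sparse triplet text
#'
#' The matrix is stored as a three-column table (row, col, weight) of its
#' nonzero entries plus a JSON header file carrying the model parameters and
#' seed, so a realization round-trips exactly through plain text.
#'
#' @param conn a \code{"connectivity"} object.
#' @param path base path; \code{<path>.tsv} and \code{<path>.json} are
#'   written.
#' @return \code{write_connectivity}: the base path, invisibly.
#'   \code{read_connectivity}: the reconstructed \code{"connectivity"}
#'   object.
#' @export
write_connectivity <- function(conn, path) {
  stopifnot(inherits(conn, "connectivity"))
  nz <- which(conn$J != 0, arr.ind = TRUE)
  df <- data.frame(row = nz[, 1], col = nz[, 2],
                   weight = conn$J[nz])
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  hdr <- c(unclass(conn$params), list(seed = conn$seed))
  jsonlite::write_json(hdr, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- model_params(N = hdr$N, p = hdr$p, alpha = hdr$alpha,
                         w = hdr$w, g = hdr$g, p_ext = hdr$p_ext)
  df <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  J <- matrix(0, params$N, params$N)
  J[cbind(df$row, df$col)] <- df$weight
  n_inh <- n_inhibitory(params)
  n_exc <- params$N - n_inh
  structure(list(J = J, excitatory = seq_len(n_exc),
                 inhibitory = if (n_inh > 0) (n_exc + 1):params$N
                              else integer(0),
                 params = params, seed = as.integer(hdr$seed)),
            class = "connectivity")
}
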