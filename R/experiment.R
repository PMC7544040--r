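#' Phase-diagram sweep over the (g, w) plane
#'
#' For every grid cell one network realization per seed is drawn and
#' simulated; the time-averaged population rate, its standard deviation and
#' the theoretical spectral quantities are recorded. The sweep reproduces
#' the qualitative phase structure: a high-rate regime where
#' \eqn{\lambda_{max} > 1}, a low-rate regime where \eqn{\lambda_{max} < 1},
#' and a ridge of rate fluctuations along the \eqn{\lambda_{max} = 1}
#' boundary.
#'
#' @param g_values,w_values grid of I/E ratios and weight scales.
#' @param params base [model_params()] (w and g overridden per cell).
#' @param config a [sim_config()].
#' @param seeds realizations per cell.
#' @param master_seed master seed; per-cell seeds derive from it via
#'   [child_seed()].
#' @return Data frame with one row per (g, w, seed): g, w, seed, mean_rate,
#'   std_rate, lambda_b, R, lambda_max_theory.
#' @export
run_phase_diagram <- function(g_values, w_values, params = model_params(),
                              config = sim_config(), seeds = 1,
                              master_seed = 1) {
  rows <- list(); cell <- 0
  for (g in g_values) for (w in w_values) {
    p_cell <- model_params(N = params$N, p = params$p, alpha = params$alpha,
                           w = w, g = g, p_ext = params$p_ext)
    th <- eigen_theory(p_cell)
    for (s in seq_len(seeds)) {
      cell <- cell + 1
      conn <- build_connectivity(p_cell, seed = child_seed(master_seed, cell))
      ras <- simulate_network(conn, config,
                              seed = child_seed(master_seed, cell + 500000))
      r <- population_rate(ras)
      rows[[cell]] <- data.frame(g = g, w = w, seed = s,
                                 mean_rate = r$mean_rate,
                                 std_rate = r$std_rate,
                                 lambda_b = th$lambda_b, R = th$R,
                                 lambda_max_theory = th$lambda_max)
    }
  }
  do.call(rbind, rows)
}

#' Full statistic suite along the critical boundary
#'
#' For each I/E ratio g the weight scale is set to \eqn{w^*(g)} so that
#' \eqn{\lambda_{max} = 1}, and per realization the complete analysis stack
#' is run: population rate, E/I tension, ISI CV, branching-derived avalanche
#' threshold, avalanche catalog with kappa statistics and power-law exponent
#' fits, critical range, and (optionally) the asynchrony index from input
#' correlograms and the empirical spectral radius. Missing statistics (e.g.
#' from zero-avalanche runs) are NA with a QC flag, never silent zeros.
#'
#' @param g_values I/E ratios to scan.
#' @param params base [model_params()].
#' @param config a [sim_config()].
#' @param seeds realizations per g.
#' @param master_seed master seed for [child_seed()] derivation.
#' @param include_ccg compute input correlograms and eta (default TRUE).
#' @param include_spectrum compute the empirical eigenvalue summary of each
#'   realization (dense eigendecomposition; default FALSE).
#' @return Data frame, one row per (g, seed), with the statistic columns and
#'   a \code{qc} string flagging missing entries.
#' @export
run_boundary_scan <- function(g_values, params = model_params(),
                              config = sim_config(), seeds = 5,
                              master_seed = 1, include_ccg = TRUE,
                              include_spectrum = FALSE) {
  rows <- list(); cell <- 0
  for (g in g_values) {
    w <- boundary_weight(g, params)
    p_g <- model_params(N = params$N, p = params$p, alpha = params$alpha,
                        w = w, g = g, p_ext = params$p_ext)
    th <- eigen_theory(p_g)
    curve <- branching_semianalytic(p_g)
    thr <- avalanche_threshold(curve)
    cr <- critical_range(curve)
    for (s in seq_len(seeds)) {
      cell <- cell + 1
      qc <- character(0)
      conn <- build_connectivity(p_g, seed = child_seed(master_seed, cell))
      ras <- simulate_network(conn, config,
                              seed = child_seed(master_seed, cell + 500000))
      r <- population_rate(ras)
      tens <- ei_tension(ras, conn)
      cv <- tryCatch(isi_cv(ras)$mean_cv,
                     error = function(e) { NA_real_ })
      if (is.na(cv)) qc <- c(qc, "no_isi")
      cat_ <- detect_avalanches(ras, thr$count)
      ks <- kd <- es <- ed <- NA_real_
      if (cat_$n_avalanches >= 2 && length(unique(cat_$sizes)) >= 2) {
        ks <- kappa_stat(cat_$sizes, 1.5)$kappa
        # sizes are bounded below by threshold + 1, so the zeta fit starts
        # at the smallest observable size, not at 1
        es <- fit_power_law(cat_$sizes, x_min = min(cat_$sizes))$epsilon_hat
      } else qc <- c(qc, "few_avalanches")
      if (cat_$n_avalanches >= 2 && length(unique(cat_$durations)) >= 2) {
        kd <- kappa_stat(cat_$durations, 1.7)$kappa
        ed <- fit_power_law(cat_$durations,
                            x_min = min(cat_$durations))$epsilon_hat
      }
      eta <- NA_real_
      if (include_ccg) {
        eta <- tryCatch(asynchrony_index(
          input_ccg(conn, ras, seed = child_seed(master_seed, cell + 900000))),
          error = function(e) NA_real_)
        if (is.na(eta)) qc <- c(qc, "no_ccg")
      }
      emp_lmax <- NA_real_
      if (include_spectrum)
        emp_lmax <- empirical_spectrum(conn)$lambda_max_mod
      rows[[cell]] <- data.frame(
        g = g, w = w, seed = s,
        mean_rate = r$mean_rate, std_rate = r$std_rate,
        lambda_b = th$lambda_b, R = th$R,
        lambda_max_theory = th$lambda_max,
        lambda_max_empirical = emp_lmax,
        rho = cr$rho, S_dagger = thr$S_dagger, threshold = thr$count,
        kappa_size = ks, kappa_duration = kd,
        epsilon_hat_size = es, epsilon_hat_duration = ed,
        T = tens$T, eta = eta, mean_CV = cv,
        n_avalanches = cat_$n_avalanches,
        qc = paste(qc, collapse = ";"))
    }
  }
  do.call(rbind, rows)
}

#' Write hand-traceable test fixtures
#'
#' Generates the small fixtures used across the test suites, each with its
#' expected statistics recorded in a JSON manifest: a 3-neuron connectivity
#' with hand-computed synaptic inputs, toy count series with their expected
#' avalanche catalogs, a discrete power-law sample with its generation seed,
#' and periodic / Bernoulli spike trains for CV checks.
#'
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed for the stochastic fixtures.
#' @return Path of the manifest JSON, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 42) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()

  # 3-neuron matrix; state (1, 1, 0) drives input = col1 + col2
  J3 <- matrix(c(0.0, 0.2, 0.5,
                 0.4, 0.0, -0.3,
                 0.1, 0.0, 0.0), 3, 3, byrow = TRUE)
  utils::write.table(J3, file.path(out_dir, "J3.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  manifest$J3 <- list(file = "J3.tsv", state = c(1, 1, 0),
                      expected_input = as.numeric(J3 %*% c(1, 1, 0)))

  # toy count series with hand-traced avalanche catalogs
  manifest$avalanches <- list(
    list(counts = c(0, 2, 3, 1, 0), threshold = 1,
         durations = 2, sizes = 5),
    list(counts = c(0, 5, 0, 4, 4, 0), threshold = 2,
         durations = c(1, 2), sizes = c(5, 8)))

  # discrete power-law sample for exponent recovery
  set.seed(seed)
  pl <- rpowerlaw_discrete(1e4, 1.5)
  utils::write.csv(data.frame(x = pl), file.path(out_dir, "powerlaw.csv"),
                   row.names = FALSE)
  manifest$powerlaw <- list(file = "powerlaw.csv", epsilon = 1.5,
                            n = 1e4, seed = seed)

  # spike trains for CV checks
  manifest$periodic_train <- list(times = seq(5, 100, by = 5), cv = 0)
  set.seed(seed + 1)
  bern <- which(stats::runif(1e5) < 0.01)
  utils::write.csv(data.frame(t = bern), file.path(out_dir, "bernoulli.csv"),
                   row.names = FALSE)
  manifest$bernoulli_train <- list(file = "bernoulli.csv", rate = 0.01,
                                   steps = 1e5, seed = seed + 1,
                                   expected_cv = 1)

  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
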