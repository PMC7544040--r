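test_that("parameter validation rejects out-of-range and inconsistent values", {
  expect_error(model_params(N = 1), "N must be")
  expect_error(model_params(p = 0), "p must be")
  expect_error(model_params(alpha = 1), "alpha must be")
  expect_error(model_params(N = 1000, alpha = 0.2005), "integer")
  expect_error(model_params(w = 0), "w must be")
  expect_error(model_params(g = -1), "g must be")
  expect_error(sim_config(steps = 100, burn_in = 100), "steps > burn_in")
})

test_that("connectivity respects the E/I partition, sign ranges and density", {
  params <- default_params(w = 0.05, g = 2)
  conn <- build_connectivity(params, seed = 1)
  expect_equal(length(conn$excitatory), 800)
  expect_equal(length(conn$inhibitory), 200)
  expect_true(all(conn$J[, conn$excitatory] >= 0))
  expect_true(all(conn$J[, conn$excitatory] <= params$w))
  expect_true(all(conn$J[, conn$inhibitory] <= 0))
  expect_true(all(conn$J[, conn$inhibitory] >= -params$g * params$w))
  expect_true(all(diag(conn$J) == 0))

  # fraction of nonzero off-diagonal entries ~ Binomial(N(N-1), p)
  off <- conn$J[row(conn$J) != col(conn$J)]
  n_draws <- length(off)
  se <- sqrt(params$p * (1 - params$p) / n_draws)
  expect_lt(abs(mean(off != 0) - params$p), 3 * se)

  # mean nonzero excitatory weight is w/2
  exc <- conn$J[, conn$excitatory]
  exc <- exc[exc > 0]
  expect_lt(abs(mean(exc) - params$w / 2),
            3 * params$w / sqrt(12 * length(exc)))
})

test_that("g = 0 yields a purely excitatory matrix; realizations are seed-reproducible", {
  conn <- build_connectivity(small_params(g = 0), seed = 3)
  expect_true(all(conn$J >= 0))
  conn2 <- build_connectivity(small_params(g = 0), seed = 3)
  expect_identical(conn$J, conn2$J)
  conn3 <- build_connectivity(small_params(g = 0), seed = 4)
  expect_false(identical(conn$J, conn3$J))
})

test_that("eigenvalue theory matches hand-evaluated values", {
  # w Np(1-alpha)/2 = 0.0125 * 80 = 1 exactly
  th <- eigen_theory(default_params(w = 0.0125, g = 0))
  expect_equal(th$lambda_b, 1)
  # hand evaluation: R = 0.0125 * sqrt(1000 * (0.2/3 - 0.04/4) * 0.8)
  expect_equal(th$R, 0.0125 * sqrt(1000 * (0.2 / 3 - 0.04 / 4) * 0.8),
               tolerance = 1e-12)
  expect_equal(th$R, 0.0842, tolerance = 1e-3)
  expect_equal(th$lambda_max, max(th$lambda_b, th$R))
  # the outlier cancels exactly at g = (1 - alpha)/alpha
  th0 <- eigen_theory(default_params(w = 0.03, g = 4))
  expect_equal(th0$lambda_b, 0)
  expect_equal(th0$sigma2_I, 16 * th0$sigma2_E)
})

test_that("crossover ratio: closed form, numeric root, w-independence, large-N limit", {
  params <- model_params()
  g_cf <- crossover_ratio(params)
  g_rt <- crossover_ratio(params, method = "root")
  expect_equal(g_cf, 3.34, tolerance = 0.01 / 3.34)
  expect_equal(g_cf, g_rt, tolerance = 1e-9)
  # independent of w
  for (w in c(0.001, 0.0125, 0.1))
    expect_equal(crossover_ratio(model_params(w = w)), g_cf, tolerance = 1e-12)
  # N -> infinity: g* -> (1 - alpha)/alpha, approached from below at ~N^(-1/2)
  expect_identical(crossover_ratio(model_params(), method = "large_N"), 4)
  expect_identical(crossover_ratio(model_params(alpha = 0.5, w = 0.01),
                                   method = "large_N"), 1)
  err6 <- abs(crossover_ratio(model_params(N = 1e6)) - 4)
  err8 <- abs(crossover_ratio(model_params(N = 1e8)) - 4)
  expect_lt(err8, 0.005)
  expect_lt(err8, err6)
})

test_that("boundary solver places lambda_max at 1 to machine precision", {
  params <- model_params()
  for (g in seq(0, 5, by = 0.5)) {
    w <- boundary_weight(g, params)
    th <- eigen_theory(model_params(w = w, g = g))
    expect_lt(abs(th$lambda_max - 1), 1e-12)
  }
  expect_equal(boundary_weight(0, params), 0.0125, tolerance = 1e-12)
  expect_equal(boundary_weight(4, params), 0.0664, tolerance = 1e-3)
})

test_that("empirical spectrum: zero matrix and the g = 0 outlier", {
  expect_equal(empirical_spectrum(matrix(0, 4, 4))$lambda_max_mod, 0)
  # at g = 0 on the boundary the outlier is real and close to lambda_b = 1
  lm <- vapply(1:6, function(s) {
    sp <- empirical_spectrum(build_connectivity(default_params(), seed = s))
    expect_equal(sp$lambda_max_re, sp$lambda_max_mod, tolerance = 1e-8)
    sp$lambda_max_mod
  }, numeric(1))
  expect_lt(abs(mean(lm) - 1), 0.1)
})

test_that("connectivity round-trips through the triplet text format", {
  conn <- build_connectivity(small_params(N = 50, g = 3), seed = 9)
  path <- file.path(tempdir(), "conn_rt")
  write_connectivity(conn, path)
  back <- read_connectivity(path)
  expect_equal(back$J, conn$J, tolerance = 1e-12)
  expect_equal(back$params$g, conn$params$g)
  expect_identical(back$inhibitory, conn$inhibitory)
})
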