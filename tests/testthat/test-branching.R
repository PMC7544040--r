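make_curve <- function(S, Lambda, N = 1000) {
  structure(list(S = S, Lambda = Lambda, stderr = rep(0, length(S)),
                 method = "semianalytic", n_trials = NA_integer_,
                 params = model_params(N = N, p_ext = 0.005 / N)),
            class = "branching_curve")
}

test_that("empirical branching: no propagation without coupling; exact 2-neuron expectation", {
  conn0 <- build_connectivity(small_params(N = 40, p_ext = 0), seed = 1)
  conn0$J[] <- 0
  emp <- branching_empirical(conn0, S_grid = c(1, 4, 10) / 40, n_trials = 50,
                             seed = 2)
  expect_equal(emp$Lambda, c(0, 0, 0))

  # symmetric 2-neuron toy: activating either neuron, the other fires with
  # probability 0.5, so Lambda(0.5) = E[S(2)]/0.5 = 0.5
  toy <- build_connectivity(model_params(N = 2, p = 1, alpha = 0,
                                         w = 1, g = 0, p_ext = 0), seed = 1)
  toy$J <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  emp2 <- branching_empirical(toy, S_grid = 0.5, n_trials = 4000, seed = 3)
  expect_equal(emp2$Lambda, 0.5, tolerance = 4 * 0.5 / sqrt(4000) / 0.5)
  expect_gt(emp2$stderr, 0)
})

test_that("semi-analytic branching is exactly critical in the linear regime and saturates", {
  p0 <- default_params(w = 0.0125, g = 0)
  sa <- branching_semianalytic(p0, S_grid = c(0.005, 0.01, 0.02))
  # linear transfer regime: Lambda = (w/2) N p (1-alpha) = lambda_b = 1
  expect_equal(sa$Lambda, rep(1, 3), tolerance = 1e-9)
  # saturation bounds growth: Lambda(S) * S = E[S(t+1)] <= 1 everywhere
  grid <- seq(0.01, 1, by = 0.045)
  for (g in c(0, 4)) {
    pg <- default_params(w = boundary_weight(g), g = g)
    cur <- branching_semianalytic(pg, S_grid = grid)
    expect_true(all(cur$Lambda * cur$S <= 1 + 1e-12))
  }
  expect_lt(branching_semianalytic(p0, S_grid = 0.999)$Lambda, 1)
})

test_that("critical range interpolates level crossings exactly on a linear curve", {
  S <- seq(0.01, 0.09, by = 0.01)
  cr <- critical_range(make_curve(S, 1.2 - 5 * (S - 0.01)))
  expect_equal(cr$S1, 0.04, tolerance = 1e-12)
  expect_equal(cr$S2, 0.06, tolerance = 1e-12)
  expect_equal(cr$rho, (1.05 - 0.95) / 5, tolerance = 1e-12)
  expect_false(cr$S1_fallback || cr$S2_fallback)
})

test_that("flat critical curve triggers the documented fallbacks", {
  S <- seq(0.002, 0.4, by = 0.002)
  cr <- critical_range(make_curve(S, rep(1, length(S))))
  expect_true(cr$S1_fallback)
  expect_equal(cr$S1, min(S))
  expect_equal(cr$S2, max(S))  # largest S with Lambda >= 0.95
  thr <- avalanche_threshold(make_curve(S, rep(1, length(S))))
  expect_true(thr$fallback)
  expect_equal(thr$S_dagger, 1 / 1000)
  expect_equal(thr$count, 1L)
})

test_that("avalanche threshold sits on the 1.01 level of a steep curve", {
  S <- seq(0.01, 0.2, by = 0.01)
  thr <- avalanche_threshold(make_curve(S, 1.5 - 5 * S))
  expect_false(thr$fallback)
  expect_equal(thr$S_dagger, (1.5 - 1.01) / 5, tolerance = 1e-12)

  # asynchronous-regime curve: steep crossing near the Lambda = 1 point
  p4 <- default_params(w = boundary_weight(4), g = 4)
  cur <- branching_semianalytic(p4, S_grid = seq(0.002, 0.4, by = 0.002))
  thr4 <- avalanche_threshold(cur)
  expect_false(thr4$fallback)
  # interpolated Lambda at S_dagger is the defining level
  lam_at <- stats::approx(cur$S, cur$Lambda, xout = thr4$S_dagger)$y
  expect_equal(lam_at, 1.01, tolerance = 1e-3)
  # the threshold lies inside the critical range (just above the 1.05 crossing)
  cr4 <- critical_range(cur)
  expect_gt(thr4$S_dagger, cr4$S1)
  expect_lt(thr4$S_dagger, cr4$S2)
})

test_that("critical range shrinks from the weak- to the strong-synapse boundary", {
  grid <- seq(0.002, 0.45, by = 0.002)
  rho_weak <- critical_range(branching_semianalytic(
    default_params(w = boundary_weight(0.5), g = 0.5), S_grid = grid))$rho
  rho_strong <- critical_range(branching_semianalytic(
    default_params(w = boundary_weight(4), g = 4), S_grid = grid))$rho
  expect_gt(rho_weak, rho_strong)
})

test_that("empirical and semi-analytic branching agree in the weak-synapse regime", {
  p05 <- default_params(w = boundary_weight(0.5), g = 0.5)
  conn <- build_connectivity(p05, seed = 21)
  grid <- seq(0.01, 0.2, by = 0.02)
  emp <- branching_empirical(conn, S_grid = grid, n_trials = 200, seed = 22)
  sa <- branching_semianalytic(p05, S_grid = grid)
  z <- abs(emp$Lambda - sa$Lambda) / emp$stderr
  expect_true(all(z < 3))
})
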