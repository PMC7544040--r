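test_that("input decomposition matches a hand trace and the exact identity", {
  J <- J3_fixture()
  states <- cbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 0))
  dec <- decompose_inputs(J, states)
  # inputs at step 2 driven by state (1,1,0): E part from positive entries
  expect_equal(dec$I_E[, 1], c(0.2, 0.4, 0.7))
  expect_equal(dec$I_I[, 1], c(0, 0, 0))
  # step 3 driven by (0,1,1): columns 2 + 3 split by sign
  expect_equal(dec$I_E[, 2], c(0.2, 0, 0.6))
  expect_equal(dec$I_I[, 2], c(-0.5, -0.3, 0))
  expect_equal(dec$I_total, dec$I_E + dec$I_I)
  expect_true(all(dec$I_E >= 0) && all(dec$I_I <= 0))
})

test_that("decomposed totals reproduce the simulator's synaptic input", {
  conn <- build_connectivity(small_params(N = 80, g = 2), seed = 4)
  ras <- simulate_network(conn, sim_config(steps = 400, burn_in = 0), seed = 5)
  states <- raster_matrix(ras)
  dec <- decompose_inputs(conn$J, states[, 1:50])
  for (t in c(2, 17, 50))
    expect_equal(dec$I_total[, t - 1],
                 synaptic_input(conn$J, states[, t - 1]))
})

test_that("tension identities: 0 without inhibition, 1 under exact cancellation", {
  # g = 0: no negative weights anywhere
  conn0 <- build_connectivity(small_params(N = 100, g = 0), seed = 2)
  ras0 <- simulate_network(conn0, sim_config(steps = 5000, burn_in = 500),
                           seed = 3)
  tens0 <- ei_tension(ras0, conn0)
  expect_equal(tens0$T, 0, tolerance = 1e-12)
  # synthetic perfect cancellation: mean total input identically zero
  I_E <- matrix(runif(50, 1, 2), 5, 10)
  dec <- structure(list(I_E = I_E, I_I = -I_E, I_total = I_E * 0),
                   class = "input_decomposition")
  expect_equal(ei_tension(dec)$T, 1, tolerance = 1e-12)
})

test_that("tension stays in [0, 2] and the two computation paths agree", {
  conn <- build_connectivity(small_params(N = 120, g = 3), seed = 6)
  ras <- simulate_network(conn, sim_config(steps = 6000, burn_in = 0), seed = 7)
  t_raster <- ei_tension(ras, conn)
  expect_true(all(t_raster$T_i >= 0 & t_raster$T_i <= 2, na.rm = TRUE))
  dec <- decompose_inputs(conn$J, raster_matrix(ras))
  t_dec <- ei_tension(dec)
  # raster path averages the state over the full window, decomposition path
  # over all but the last step: agreement up to O(1/steps)
  expect_equal(t_dec$T, t_raster$T, tolerance = 5e-3)
})

test_that("tension increases with the I/E ratio along the boundary", {
  means <- vapply(c(1, 2, 3, 4), function(g) {
    tt <- vapply(1:3, function(s) {
      conn <- build_connectivity(small_params(N = 300, g = g),
                                 seed = child_seed(31, 10 * g + s))
      ras <- simulate_network(conn, sim_config(steps = 15000, burn_in = 2000),
                              seed = child_seed(31, 10 * g + s + 500))
      ei_tension(ras, conn)$T
    }, numeric(1))
    mean(tt)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("asynchrony index identities and bounds", {
  expect_equal(asynchrony_index(list(A_total = 3, A_EE = 4, A_II = 2)), 0)
  expect_equal(asynchrony_index(list(A_total = 0, A_EE = 4, A_II = 2)), 1)
  expect_error(asynchrony_index(list(A_total = 1, A_EE = 1, A_II = -1)),
               "degenerate")
  # with non-negative areas eta never exceeds 1
  set.seed(12)
  for (i in 1:20) {
    a <- runif(3, 0, 5)
    expect_lte(asynchrony_index(list(A_total = a[1], A_EE = a[2],
                                     A_II = a[3])), 1)
  }
})

test_that("input CCGs: unit zero-lag on common input, null for independent drive, scale-free", {
  conn <- build_connectivity(small_params(N = 100, g = 2), seed = 8)
  ras <- simulate_network(conn, sim_config(steps = 4000, burn_in = 500),
                          seed = 9)
  ccg <- input_ccg(conn, ras, n_neurons = 30, window_len = 3000,
                   n_pairs = 400, seed = 10)
  expect_equal(ccg$lags, -20:20)
  expect_true(all(is.finite(ccg$ccg_total)))
  # rescaling all couplings by a positive constant leaves the CCGs unchanged
  conn2 <- conn; conn2$J <- 2.5 * conn$J
  ccg2 <- input_ccg(conn2, ras, n_neurons = 30, window_len = 3000,
                    n_pairs = 400, seed = 10)
  expect_equal(ccg2$ccg_total, ccg$ccg_total, tolerance = 1e-10)
  expect_equal(asynchrony_index(ccg2), asynchrony_index(ccg),
               tolerance = 1e-10)

  # fully shared input: every neuron driven by the same presynaptic column
  Jshare <- matrix(0, 40, 40); Jshare[, 1] <- 0.3; Jshare[1, 1] <- 0
  conn_s <- build_connectivity(small_params(N = 40, g = 0, w = 0.5), seed = 1)
  conn_s$J <- Jshare
  # strong external drive keeps the shared source neuron firing
  conn_s$params <- model_params(N = 40, p = 0.2, alpha = 0.2, w = 0.5, g = 0,
                                p_ext = 0.25)
  ras_s <- simulate_network(conn_s, sim_config(steps = 3000, burn_in = 100,
                                               initial_active = 5), seed = 2)
  ccg_s <- input_ccg(conn_s, ras_s, n_neurons = 20, window_len = 2500,
                     n_pairs = 100, seed = 3)
  expect_equal(ccg_s$ccg_total[ccg_s$lags == 0], 1, tolerance = 1e-9)

  # independent drive: diagonal-free private couplings, p_ext only
  Jind <- matrix(0, 40, 40)
  conn_i <- conn_s; conn_i$J <- Jind
  conn_i$params <- model_params(N = 40, p = 0.2, alpha = 0.2, w = 0.5, g = 0,
                                p_ext = 0.3)
  ras_i <- simulate_network(conn_i, sim_config(steps = 6000, burn_in = 100),
                            seed = 4)
  # inputs are all zero under J = 0, so correlate the spike trains themselves
  states <- raster_matrix(ras_i, window = 1:5000)
  cors <- stats::cor(t(states[1:10, ]))
  off <- cors[row(cors) != col(cors)]
  expect_lt(max(abs(off)), 4 / sqrt(5000))
})

test_that("ISI CV: periodic trains at 0, Bernoulli trains near 1, bursty above 1", {
  expect_equal(isi_cv(list(seq(5, 200, by = 5)))$mean_cv, 0)
  set.seed(13)
  trains <- replicate(30, which(runif(1e5) < 0.01), simplify = FALSE)
  cv_bern <- isi_cv(trains)$mean_cv
  expect_lt(abs(cv_bern - 1), 0.05)
  # bursty train: 5-spike bursts separated by long gaps (CV tends to 2)
  bursty <- as.vector(outer(0:4, seq(0, 9000, by = 300), `+`)) + 1
  expect_gt(isi_cv(list(sort(bursty)))$mean_cv, 1.5)
  # exclusion bookkeeping
  st <- isi_cv(list(c(1, 50, 99), c(3), integer(0)))
  expect_equal(st$n_included, 1)
  expect_equal(st$n_excluded, 2)
  expect_error(isi_cv(list(c(1), c(2))), "enough spikes")
})
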