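test_that("retinal drive is seeded, piecewise-constant and statistically correct", {
  nc <- noise_config(mean = -65, sd = 2, dt_hold = 1, seed = 99)
  d1 <- generate_retinal_drive(nc, 1000)
  d2 <- generate_retinal_drive(nc, 1000)
  expect_identical(d1$values, d2$values)
  d3 <- generate_retinal_drive(noise_config(seed = 100), 1000)
  expect_false(identical(d1$values, d3$values))
  # sd = 0 gives a constant trace at the mean
  d0 <- generate_retinal_drive(noise_config(mean = -70, sd = 0, seed = 1),
                               500)
  expect_true(all(d0$values == -70))
  # moment check at n = 1e6 within 3 standard errors
  big <- generate_retinal_drive(noise_config(mean = -65, sd = 2, seed = 7),
                                1e6)
  n <- length(big$values)
  expect_lt(abs(mean(big$values) - (-65)), 3 * 2 / sqrt(n))
  expect_lt(abs(stats::sd(big$values) - 2), 3 * 2 / sqrt(2 * n))
  # the session RNG stream is not disturbed
  set.seed(42); x1 <- rnorm(3)
  set.seed(42); invisible(generate_retinal_drive(nc, 100)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("pure-leak circuit matches the exponential closed form", {
  p <- default_params()
  for (pw in c("ampa_ret", "ampa_t2n", "gabaa_n2t", "gabaa_n2n",
               "gabab_n2t"))
    p <- set_param(p, paste0(pw, ".g_max"), 0)
  sc <- solver_config(duration = 2000)
  drive <- generate_retinal_drive(noise_config(seed = 1), sc$duration)
  ts <- integrate_circuit(p, drive, sc)
  tt <- ts$t
  v0 <- p$tcr$V_rest
  closed <- p$tcr$V_leak + (v0 - p$tcr$V_leak) *
    exp(-p$tcr$g_leak * tt / p$tcr$kappa_m)
  expect_lt(max(abs(ts$values - closed) / abs(closed)), 1e-6)
  closed_n <- p$trn$V_leak + (p$trn$V_rest - p$trn$V_leak) *
    exp(-p$trn$g_leak * tt / p$trn$kappa_m)
  expect_lt(max(abs(ts$state[, "V_trn"] - closed_n) / abs(closed_n)), 1e-6)
})

test_that("constant-drive gating matches the two-state exponential solution", {
  p <- default_params()
  vconst <- -60
  drive <- kin_timeseries(seq(0, 1000, by = 1), rep(vconst, 1001))
  ts <- integrate_circuit(p, drive, solver_config(duration = 1000))
  T_ret <- transmitter_concentration(vconst, p$transmitter$ret)
  rate <- p$ampa_ret$alpha * T_ret + p$ampa_ret$beta
  r_inf <- steady_state_open_fraction(T_ret, p$ampa_ret)
  closed <- r_inf * (1 - exp(-rate * ts$t))
  expect_lt(max(abs(ts$state[, "r_ampa_ret"] - closed)), 1e-6)
})

test_that("adaptive RKF45 agrees with the fixed-step RK4 oracle", {
  # contractive configuration: pointwise cross-integrator agreement is
  # only meaningful where trajectories are not exponentially sensitive
  p <- default_params()
  nc <- noise_config(seed = 21)
  dur <- 10000
  drive <- generate_retinal_drive(nc, dur)
  ts_a <- integrate_circuit(p, drive, solver_config(duration = dur))
  ts_f <- integrate_circuit(p, drive,
                            solver_config(duration = dur,
                                          method = "rk4_fixed",
                                          fixed_dt = 0.01))
  expect_lt(max(abs(ts_a$values - ts_f$values)), 0.01)
  expect_lt(max(abs(ts_a$state[, "V_trn"] - ts_f$state[, "V_trn"])), 0.01)
})

test_that("trajectories agree with an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  vconst <- -63  # constant drive keeps the ODE smooth for lsoda
  drive <- kin_timeseries(seq(0, 2000, by = 1), rep(vconst, 2001))
  ts <- integrate_circuit(p, drive, solver_config(duration = 2000,
                                                  rel_tol = 1e-10,
                                                  abs_tol = 1e-12))
  f <- function(t, y, parms) list(as.numeric(circuit_rhs(y, vconst, p)))
  ref <- deSolve::lsoda(initial_state(p), seq(0, 2000, by = 1), f,
                        rtol = 1e-9, atol = 1e-11)
  # the startup transient crosses the steep release sigmoid, where
  # different steppers place their error differently; ~1e-5 relative
  # agreement on a 60 mV signal is the meaningful bar
  expect_lt(max(abs(ts$values - ref[, "V_tcr"])), 1e-3)
  expect_lt(max(abs(ts$state[, "X_gabab"] - ref[, "X_gabab"])), 1e-6)
})

test_that("gating variables never leave [0,1] beyond solver tolerance", {
  p <- preset("spindling")
  drive <- generate_retinal_drive(noise_config(sd = 5, seed = 3), 20000)
  ts <- integrate_circuit(p, drive, solver_config(duration = 20000))
  g <- ts$state[, c("r_ampa_ret", "r_gabaa_n2t", "R_gabab", "r_ampa_t2n",
                    "r_gabaa_n2n")]
  expect_gt(min(g), -1e-9)
  expect_lt(max(g), 1 + 1e-9)
  expect_true(all(ts$state[, "X_gabab"] >= -1e-9))
})

test_that("halving the tolerances barely changes the reported trajectory", {
  p <- default_params()
  drive <- generate_retinal_drive(noise_config(seed = 8), 2000)
  t1 <- integrate_circuit(p, drive, solver_config(duration = 2000,
                                                  rel_tol = 1e-6,
                                                  abs_tol = 1e-8))
  t2 <- integrate_circuit(p, drive, solver_config(duration = 2000,
                                                  rel_tol = 5e-7,
                                                  abs_tol = 5e-9))
  expect_lt(max(abs(t1$values - t2$values)), 1e-4 * max(abs(t1$values)))
})

test_that("far-subthreshold drive keeps the synapse-free fixed point", {
  # all release thresholds far above any reachable potential, so [T] ~ 0
  # everywhere and the leak fixed point is self-consistent
  p <- default_params(transmitter_params(1, theta_s = 100, sigma_s = 2))
  y0 <- c(p$tcr$V_leak, p$trn$V_leak, 0, 0, 0, 0, 0, 0)
  drive <- kin_timeseries(seq(0, 5000, by = 1), rep(-500, 5001))
  ts <- integrate_circuit(p, drive, solver_config(duration = 5000),
                          y0 = y0)
  expect_lt(max(abs(ts$values - p$tcr$V_leak)), 1e-6)
  expect_lt(max(abs(ts$state[, "V_trn"] - p$trn$V_leak)), 1e-6)
})

test_that("ensemble protocol averages seeded trials", {
  p <- default_params()
  nc <- noise_config(seed = 30)
  sc <- solver_config(duration = 3000)
  # n_trials = 1 reduces to a single run with seed + 1
  e1 <- run_ensemble(p, nc, sc, n_trials = 1)
  d1 <- generate_retinal_drive(noise_config(seed = 31), sc$duration)
  s1 <- integrate_circuit(p, d1, sc)
  expect_equal(e1$values, s1$values)
  # with sd = 0 all trials coincide with any single trial
  nc0 <- noise_config(mean = -65, sd = 0, seed = 30)
  e0 <- run_ensemble(p, nc0, sc, n_trials = 3)
  d0 <- generate_retinal_drive(noise_config(mean = -65, sd = 0, seed = 31),
                               sc$duration)
  expect_equal(e0$values, integrate_circuit(p, d0, sc)$values,
               tolerance = 1e-12)
  # determinism of the full protocol
  expect_identical(run_ensemble(p, nc, sc, n_trials = 2)$values,
                   run_ensemble(p, nc, sc, n_trials = 2)$values)
})

test_that("ensemble averaging shrinks point-attractor variance roughly as 1/n", {
  p <- default_params()
  sc <- solver_config(duration = 30000)
  post <- function(v) v[10001:30001]
  nc <- noise_config(seed = 55)
  single <- integrate_circuit(
    p, generate_retinal_drive(noise_config(seed = 56), sc$duration), sc)
  ens <- run_ensemble(p, nc, sc, n_trials = 8)
  v1 <- stats::var(post(single$values))
  v8 <- stats::var(post(ens$values))
  # noise-driven fluctuation variance drops by about the trial count
  expect_lt(v8, v1 / 3)
})
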