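#' Retinal-drive noise configuration
#'
#' The extrinsic input is the ensemble membrane potential of retinal cells
#' at rest, modelled as Gaussian white noise realized piecewise-constant
#' over `dt_hold` intervals (one independent draw per interval). The hold
#' makes the ODE piecewise-smooth, which an adaptive integrator requires,
#' and at the default 1 ms hold matches the simulation resolution.
#'
#' The mean and SD have no published values; the defaults are part of the
#' package's one-time calibration (see the methods vignette) and keep the
#' default circuit in the point-attractor regime.
#'
#' @param mean mean drive potential (mV).
#' @param sd drive SD (mV), >= 0.
#' @param dt_hold hold interval (ms), > 0.
#' @param seed integer RNG seed.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(mean = -67.5, sd = 2, dt_hold = 1, seed = 42L) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, sd >= 0,
            is.numeric(dt_hold), length(dt_hold) == 1L, dt_hold > 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(mean = mean, sd = sd, dt_hold = dt_hold,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Solver configuration
#'
#' @param duration total simulated time (ms); the published protocol uses
#'   600 s (600000 ms).
#' @param report_dt reporting resolution (ms); published value 1 ms.
#' @param rel_tol,abs_tol adaptive error tolerances.
#' @param method `"rkf45"` (adaptive Runge-Kutta-Fehlberg 4(5)) or
#'   `"rk4_fixed"` (classic fixed-step RK4 at `fixed_dt`, kept as the
#'   cross-checking oracle).
#' @param fixed_dt step for `"rk4_fixed"` (ms); must divide the noise hold.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(duration = 600000, report_dt = 1,
                          rel_tol = 1e-6, abs_tol = 1e-8,
                          method = c("rkf45", "rk4_fixed"),
                          fixed_dt = 0.01) {
  method <- match.arg(method)
  stopifnot(duration > 0, report_dt > 0, rel_tol > 0, abs_tol > 0,
            fixed_dt > 0)
  structure(list(duration = duration, report_dt = report_dt,
                 rel_tol = rel_tol, abs_tol = abs_tol, method = method,
                 fixed_dt = fixed_dt),
            class = "solver_config")
}

#' Generate the stochastic retinal drive
#'
#' One independent Gaussian draw per hold interval; the same seed always
#' reproduces the same trace. The RNG state of the session is left
#' untouched.
#'
#' @param nc a [noise_config()].
#' @param duration covered time span (ms).
#' @return a [kin_timeseries()] whose samples are the per-interval hold
#'   values on the grid of interval start times.
#' @export
generate_retinal_drive <- function(nc, duration) {
  stopifnot(inherits(nc, "noise_config"), duration > 0)
  n <- ceiling(duration / nc$dt_hold)
  vals <- local_rng(nc$seed, stats::rnorm(n, mean = nc$mean, sd = nc$sd))
  kin_timeseries(t = seq(0, by = nc$dt_hold, length.out = max(n, 2L)),
                 values = if (n >= 2L) vals else rep(vals, 2L),
                 meta = list(seed = nc$seed, mean = nc$mean, sd = nc$sd,
                             dt_hold = nc$dt_hold))
}

# Evaluate `expr` under a private RNG stream without disturbing the
# session's .Random.seed.
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Integrate the circuit under a given retinal drive
#'
#' Adaptive RKF45 (or the fixed-step RK4 oracle) over the piecewise-smooth
#' segments delimited by the drive-hold boundaries, reporting the state on
#' the uniform `report_dt` grid. Gating variables are kept in \[0, 1\] by
#' the dynamics alone; no post-hoc clipping is applied.
#'
#' @param p a [circuit_params()].
#' @param drive retinal drive from [generate_retinal_drive()].
#' @param sc a [solver_config()].
#' @param y0 optional initial state (default [initial_state()]).
#' @return a [kin_timeseries()] of `V_tcr` with the full state matrix
#'   attached as `$state`.
#' @export
integrate_circuit <- function(p, drive, sc = solver_config(), y0 = NULL) {
  stopifnot(inherits(p, "circuit_params"), inherits(drive, "kin_timeseries"),
            inherits(sc, "solver_config"))
  dt_hold <- ts_dt(drive)
  if (length(drive$values) * dt_hold < sc$duration - 1e-9)
    stop("drive does not cover [0, duration]")
  if (is.null(y0)) y0 <- initial_state(p)
  stopifnot(length(y0) == 8L)
  pack <- pack_params(p)
  out <- if (sc$method == "rkf45") {
    cpp_integrate_rkf45(as.numeric(y0), drive$values, dt_hold, sc$report_dt,
                        sc$duration, pack, sc$rel_tol, sc$abs_tol)
  } else {
    cpp_integrate_rk4(as.numeric(y0), drive$values, dt_hold, sc$report_dt,
                      sc$duration, pack, sc$fixed_dt)
  }
  colnames(out) <- state_names()
  tgrid <- seq(0, by = sc$report_dt, length.out = nrow(out))
  kin_timeseries(tgrid, out[, "V_tcr"], state = out,
                 meta = list(seed = drive$meta$seed,
                             params_hash = params_hash(p),
                             method = sc$method, rel_tol = sc$rel_tol,
                             abs_tol = sc$abs_tol))
}

params_hash <- function(p) {
  v <- pack_params(p)
  paste0("p", format(sum(v * seq_along(v)) + sum(v^2), digits = 17))
}

#' Run the ensemble-averaging protocol
#'
#' The published protocol integrates the circuit `n_trials` times (20 in
#' the full protocol), each trial with an independent noise seed
#' (`nc$seed + k` for trial `k`), and averages the TCR voltage pointwise.
#'
#' @param p a [circuit_params()].
#' @param nc a [noise_config()]; trial `k` uses seed `nc$seed + k`.
#' @param sc a [solver_config()].
#' @param n_trials number of trials, >= 1.
#' @param keep_trials retain the per-trial voltage traces in
#'   `$meta$trials`.
#' @return a [kin_timeseries()] of the ensemble-mean `V_tcr`.
#' @export
run_ensemble <- function(p, nc = noise_config(), sc = solver_config(),
                         n_trials = 20, keep_trials = FALSE) {
  stopifnot(inherits(nc, "noise_config"), n_trials >= 1)
  acc <- NULL
  trials <- if (keep_trials) vector("list", n_trials)
  tgrid <- NULL
  for (k in seq_len(n_trials)) {
    nck <- noise_config(mean = nc$mean, sd = nc$sd, dt_hold = nc$dt_hold,
                        seed = nc$seed + k)
    drive <- generate_retinal_drive(nck, sc$duration)
    ts <- integrate_circuit(p, drive, sc)
    if (is.null(acc)) { acc <- ts$values; tgrid <- ts$t }
    else acc <- acc + ts$values
    if (keep_trials) trials[[k]] <- ts$values
  }
  kin_timeseries(tgrid, acc / n_trials,
                 meta = list(seed = nc$seed, n_trials = n_trials,
                             params_hash = params_hash(p),
                             trials = trials))
}
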