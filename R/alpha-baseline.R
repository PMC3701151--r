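# The conventional neural-mass building blocks that the kinetic synapse
# formulation replaces: the alpha-function PSP kernel and the
# bi-exponential conductance kernel, kept for comparison and regression
# tests.

#' Alpha-function synapse parameters
#'
#' @param H synaptic amplitude (mV).
#' @param tau synaptic time constant (ms), > 0.
#' @return an object of class `alpha_synapse_params`.
#' @export
alpha_synapse_params <- function(H, tau) {
  stopifnot(is.numeric(H), length(H) == 1L, is.finite(H),
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(H = H, tau = tau), class = "alpha_synapse_params")
}

#' Bi-exponential conductance synapse parameters
#'
#' @param H amplitude.
#' @param tau_a rise time (ms).
#' @param tau_b decay time (ms); must exceed `tau_a`.
#' @param V_rev reversal potential (mV) used when the conductance is turned
#'   into a current.
#' @return an object of class `biexp_synapse_params`.
#' @export
biexp_synapse_params <- function(H, tau_a, tau_b, V_rev = 0) {
  stopifnot(is.numeric(H), length(H) == 1L, is.finite(H),
            is.numeric(tau_a), tau_a > 0, is.numeric(tau_b),
            is.numeric(V_rev), length(V_rev) == 1L, is.finite(V_rev))
  if (tau_b <= tau_a) stop("'tau_b' must exceed 'tau_a'")
  structure(list(H = H, tau_a = tau_a, tau_b = tau_b, V_rev = V_rev),
            class = "biexp_synapse_params")
}

#' Sigmoid firing-rate parameters
#'
#' Potential-to-rate sigmoid of the classical neural mass lineage. The
#' published circuit does not assign values to these parameters; the
#' defaults are the widely used lineage values (e0 = 2.5 /s, s0 = 6 mV,
#' nu = 0.56 /mV) and are fully configurable.
#'
#' @param e0 half of the maximum firing rate (per s), > 0.
#' @param s0 threshold potential (mV).
#' @param nu sigmoid steepness (per mV), > 0.
#' @return an object of class `sigmoid_rate_params`.
#' @export
sigmoid_rate_params <- function(e0 = 2.5, s0 = 6, nu = 0.56) {
  stopifnot(is.numeric(e0), e0 > 0, is.numeric(s0), is.finite(s0),
            is.numeric(nu), nu > 0)
  structure(list(e0 = e0, s0 = s0, nu = nu), class = "sigmoid_rate_params")
}

#' Alpha-function impulse response
#'
#' `(H/tau) * t * exp(-t/tau)`; peaks at `t = tau` with value `H/e`.
#'
#' @param t time since the impulse (ms), >= 0; vectorised.
#' @param p an [alpha_synapse_params()] object.
#' @return postsynaptic potential (mV).
#' @export
alpha_impulse_response <- function(t, p) {
  stopifnot(inherits(p, "alpha_synapse_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  (p$H / p$tau) * t * exp(-t / p$tau)
}

#' Second-order ODE form of the alpha-function synapse
#'
#' Acceleration of the PSP `y` under presynaptic firing rate `E`:
#' `(H/tau)*E - (2/tau)*ydot - y/tau^2`. Integrating this from rest under
#' an impulse in `E` reproduces [alpha_impulse_response()].
#'
#' @param y PSP (mV).
#' @param ydot PSP rate (mV/ms).
#' @param E presynaptic firing rate.
#' @param p an [alpha_synapse_params()] object.
#' @return y'' (mV/ms^2).
#' @export
alpha_psp_rate <- function(y, ydot, E, p) {
  stopifnot(inherits(p, "alpha_synapse_params"))
  (p$H / p$tau) * E - (2 / p$tau) * ydot - y / p$tau^2
}

#' Second-order ODE form of the bi-exponential conductance synapse
#'
#' `g'' = [H*(tau_a - tau_b)*E - (tau_a + tau_b)*g' - g] / (tau_a*tau_b)`,
#' implemented exactly as the conventional printed form. Its unit-impulse
#' response is exactly the kernel of [biexp_kernel()],
#' `H*(exp(-t/tau_a) - exp(-t/tau_b))` (no additional scale factor), which
#' under the side condition `tau_b > tau_a` is non-positive for `H > 0`:
#' with `tau_a` labelled the rise time, the kernel as printed carries a
#' negative lobe. This sign behaviour is verified numerically in the
#' package tests and documented rather than silently corrected.
#'
#' @param g conductance (mS).
#' @param gdot conductance rate (mS/ms).
#' @param E presynaptic firing rate.
#' @param p a [biexp_synapse_params()] object.
#' @return g'' (mS/ms^2).
#' @export
biexp_conductance_rate <- function(g, gdot, E, p) {
  stopifnot(inherits(p, "biexp_synapse_params"))
  if (p$tau_b <= p$tau_a) stop("'tau_b' must exceed 'tau_a'")
  (p$H * (p$tau_a - p$tau_b) * E - (p$tau_a + p$tau_b) * gdot - g) /
    (p$tau_a * p$tau_b)
}

#' Bi-exponential kernel
#'
#' The closed-form kernel `H * (exp(-t/tau_a) - exp(-t/tau_b))`, used for
#' comparison with the ODE form.
#'
#' @inheritParams alpha_impulse_response
#' @param p a [biexp_synapse_params()] object.
#' @return kernel value.
#' @export
biexp_kernel <- function(t, p) {
  stopifnot(inherits(p, "biexp_synapse_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  p$H * (exp(-t / p$tau_a) - exp(-t / p$tau_b))
}

#' Ensemble sigmoid firing rate
#'
#' `2*e0 / (1 + exp(nu*(s0 - V)))`; bounded by (0, 2*e0), equal to `e0` at
#' the threshold `s0`.
#'
#' @param V ensemble membrane potential (mV); vectorised.
#' @param p a [sigmoid_rate_params()] object.
#' @return firing rate (per s).
#' @export
sigmoid_firing_rate <- function(V, p = sigmoid_rate_params()) {
  stopifnot(inherits(p, "sigmoid_rate_params"), is.numeric(V))
  2 * p$e0 / (1 + exp(p$nu * (p$s0 - V)))
}

#' Integrate a second-order synapse ODE under a firing-rate input
#'
#' Fixed-step RK4 integration of either the alpha-function PSP ODE or the
#' bi-exponential conductance ODE from rest, driven by a sampled input
#' `E(t)`. Used for the kernel-vs-ODE equivalence checks and for
#' side-by-side demonstration runs against the kinetic circuit.
#'
#' @param E input samples on a uniform grid.
#' @param dt grid step (ms).
#' @param p an [alpha_synapse_params()] or [biexp_synapse_params()] object.
#' @param y0,ydot0 initial output and output rate (a unit impulse in the
#'   input at t = 0 is equivalent to starting from the matching jump in
#'   `ydot0`).
#' @return numeric vector of the integrated output (`y` or `g`) at the
#'   input grid points.
#' @export
simulate_second_order <- function(E, dt, p, y0 = 0, ydot0 = 0) {
  stopifnot(is.numeric(E), length(E) >= 2L, dt > 0)
  rate <- if (inherits(p, "alpha_synapse_params")) {
    function(y, ydot, e) alpha_psp_rate(y, ydot, e, p)
  } else if (inherits(p, "biexp_synapse_params")) {
    function(y, ydot, e) biexp_conductance_rate(y, ydot, e, p)
  } else stop("'p' must be alpha_synapse_params or biexp_synapse_params")
  n <- length(E)
  y <- numeric(n)
  ydot <- ydot0
  yy <- y0
  y[1L] <- y0
  for (i in seq_len(n - 1L)) {
    e <- E[i]
    # RK4 on the first-order system (y, ydot)
    k1y <- ydot;               k1v <- rate(yy, ydot, e)
    k2y <- ydot + dt / 2 * k1v; k2v <- rate(yy + dt / 2 * k1y, ydot + dt / 2 * k1v, e)
    k3y <- ydot + dt / 2 * k2v; k3v <- rate(yy + dt / 2 * k2y, ydot + dt / 2 * k2v, e)
    k4y <- ydot + dt * k3v;     k4v <- rate(yy + dt * k3y, ydot + dt * k3v, e)
    yy <- yy + dt / 6 * (k1y + 2 * k2y + 2 * k3y + k4y)
    ydot <- ydot + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    y[i + 1L] <- yy
  }
  y
}
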