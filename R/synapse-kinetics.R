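#' Transmitter-release parameters
#'
#' Parameters of the sigmoid mapping from the presynaptic ensemble membrane
#' potential to the neurotransmitter concentration in the synaptic cleft.
#' The concentration saturates at `T_max` (well approximated by 1 mM),
#' reaches `T_max/2` at `theta_s`, and rises with steepness `sigma_s`.
#'
#' `theta_s` and `sigma_s` are not fixed by receptor physiology; they
#' position the release sigmoid relative to the operating range of the
#' ensemble potentials and are the main calibration knobs of the model (see
#' the methods vignette).
#'
#' @param T_max maximum cleft concentration (mM), > 0.
#' @param theta_s half-activation potential (mV).
#' @param sigma_s sigmoid steepness (mV), > 0.
#' @return an object of class `transmitter_params`.
#' @export
transmitter_params <- function(T_max = 1, theta_s = -58, sigma_s = 1) {
  stopifnot(is.numeric(T_max), length(T_max) == 1L, is.finite(T_max),
            T_max > 0,
            is.numeric(theta_s), length(theta_s) == 1L, is.finite(theta_s),
            is.numeric(sigma_s), length(sigma_s) == 1L, is.finite(sigma_s),
            sigma_s > 0)
  structure(list(T_max = T_max, theta_s = theta_s, sigma_s = sigma_s),
            class = "transmitter_params")
}

#' Two-state ligand-gated receptor parameters (AMPA / GABA_A)
#'
#' @param alpha forward (binding) rate constant (per mM per ms), >= 0.
#' @param beta backward (unbinding) rate constant (per ms), >= 0.
#' @param g_max maximum ensemble conductance (mS), >= 0.
#' @param V_rev reversal potential (mV).
#' @return an object of class `ligand_gated_params`.
#' @export
ligand_gated_params <- function(alpha, beta, g_max, V_rev) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            alpha >= 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0,
            is.numeric(g_max), length(g_max) == 1L, is.finite(g_max),
            g_max >= 0,
            is.numeric(V_rev), length(V_rev) == 1L, is.finite(V_rev))
  structure(list(alpha = alpha, beta = beta, g_max = g_max, V_rev = V_rev),
            class = "ligand_gated_params")
}

#' GABA_B receptor / G-protein cascade parameters
#'
#' The metabotropic GABA_B synapse is modelled in three stages: transmitter
#' activates membrane receptors (fraction `R`, rates `alpha1`/`beta1`);
#' activated receptors catalyse production of G-protein (`X`, rates
#' `alpha2`/`beta2`); `X` binds at `n` independent sites to open ion
#' channels, with Hill dissociation constant `K_d`.
#'
#' @param alpha1 receptor activation rate (per mM per ms).
#' @param beta1 receptor deactivation rate (per ms).
#' @param alpha2 G-protein production rate (per ms).
#' @param beta2 G-protein decay rate (per ms).
#' @param K_d dissociation constant of X binding to the channel (in units of
#'   the scaled G-protein concentration to the n-th power), > 0.
#' @param n number of binding sites (integer >= 1).
#' @param g_max maximum ensemble conductance (mS).
#' @param V_rev reversal potential (mV).
#' @return an object of class `gabab_params`.
#' @export
gabab_params <- function(alpha1, beta1, alpha2, beta2, K_d = 100, n = 4,
                         g_max = 0.06, V_rev = -100) {
  rates <- c(alpha1, beta1, alpha2, beta2)
  stopifnot(is.numeric(rates), all(is.finite(rates)), all(rates >= 0),
            is.numeric(K_d), length(K_d) == 1L, is.finite(K_d), K_d > 0,
            is.numeric(n), length(n) == 1L, n >= 1, n == round(n),
            is.numeric(g_max), length(g_max) == 1L, g_max >= 0,
            is.numeric(V_rev), length(V_rev) == 1L, is.finite(V_rev))
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, K_d = K_d, n = as.integer(n), g_max = g_max,
                 V_rev = V_rev),
            class = "gabab_params")
}

#' Cleft transmitter concentration
#'
#' Sigmoid release function: `T_max / (1 + exp(-(V - theta_s)/sigma_s))`.
#' Strictly increasing in `V`, with range (0, `T_max`).
#'
#' @param V presynaptic ensemble membrane potential (mV); vectorised.
#' @param tp a [transmitter_params()] object.
#' @return transmitter concentration (mM), same length as `V`.
#' @export
transmitter_concentration <- function(V, tp = transmitter_params()) {
  stopifnot(inherits(tp, "transmitter_params"), is.numeric(V))
  if (any(!is.finite(V))) stop("'V' must be finite")
  tp$T_max / (1 + exp(-(V - tp$theta_s) / tp$sigma_s))
}

#' Open-fraction kinetics of a two-state channel
#'
#' Rate of change of the open-channel fraction `r` under transmitter
#' concentration `T`: `alpha*T*(1 - r) - beta*r`.
#'
#' @param r open-channel fraction in \[0, 1\].
#' @param T_conc transmitter concentration (mM), >= 0.
#' @param p a [ligand_gated_params()] object.
#' @return dr/dt (per ms).
#' @export
ligand_gated_rate <- function(r, T_conc, p) {
  stopifnot(inherits(p, "ligand_gated_params"), is.numeric(r),
            is.numeric(T_conc), all(T_conc >= 0))
  if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]")
  p$alpha * T_conc * (1 - r) - p$beta * r
}

#' G-protein cascade kinetics of the GABA_B synapse
#'
#' Rates of change of the activated-receptor fraction `R` and the activated
#' G-protein concentration `X`:
#' `dR/dt = alpha1*T*(1 - R) - beta1*R`, `dX/dt = alpha2*R - beta2*X`.
#'
#' @param R activated-receptor fraction in \[0, 1\].
#' @param X activated G-protein concentration, >= 0.
#' @param T_conc transmitter concentration (mM), >= 0.
#' @param p a [gabab_params()] object.
#' @return named numeric vector `c(dR = ..., dX = ...)` (per ms).
#' @export
gabab_cascade_rate <- function(R, X, T_conc, p) {
  stopifnot(inherits(p, "gabab_params"), is.numeric(R), is.numeric(X),
            is.numeric(T_conc), all(T_conc >= 0), all(X >= 0))
  if (any(R < 0 | R > 1)) stop("'R' must lie in [0, 1]")
  c(dR = p$alpha1 * T_conc * (1 - R) - p$beta1 * R,
    dX = p$alpha2 * R - p$beta2 * X)
}

#' GABA_B channel open fraction (Hill form)
#'
#' Fraction of channels opened by the activated G-protein:
#' `X^n / (X^n + K_d)`. Monotone increasing in `X`, half-activated at
#' `X = K_d^(1/n)`, with range \[0, 1).
#'
#' @param X activated G-protein concentration, >= 0; vectorised.
#' @param p a [gabab_params()] object.
#' @return open fraction.
#' @export
gabab_open_fraction <- function(X, p) {
  stopifnot(inherits(p, "gabab_params"), is.numeric(X))
  if (any(X < 0)) stop("'X' must be >= 0")
  Xn <- X^p$n
  Xn / (Xn + p$K_d)
}

#' Postsynaptic ensemble current through a receptor population
#'
#' `g_max * r * (V_post - V_rev)`; zero at the reversal potential or when no
#' channels are open. Units are mS * mV under the project-wide convention.
#'
#' @param r open-channel fraction in \[0, 1\].
#' @param V_post postsynaptic ensemble membrane potential (mV).
#' @param p a [ligand_gated_params()] or [gabab_params()] object.
#' @return synaptic current (mS mV).
#' @export
synaptic_current <- function(r, V_post, p) {
  stopifnot(inherits(p, c("ligand_gated_params", "gabab_params")),
            is.numeric(r), is.numeric(V_post))
  if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]")
  p$g_max * r * (V_post - p$V_rev)
}

#' Steady-state open fraction of a two-state channel
#'
#' Closed-form fixed point of the two-state kinetics at constant transmitter
#' concentration: `alpha*T / (alpha*T + beta)`.
#'
#' @param T_conc transmitter concentration (mM), >= 0; vectorised.
#' @param p a [ligand_gated_params()] object.
#' @return steady-state open fraction.
#' @export
steady_state_open_fraction <- function(T_conc, p) {
  stopifnot(inherits(p, "ligand_gated_params"), is.numeric(T_conc),
            all(T_conc >= 0))
  denom <- p$alpha * T_conc + p$beta
  if (any(denom == 0)) stop("alpha*T + beta must be positive")
  p$alpha * T_conc / denom
}

#' @export
print.transmitter_params <- function(x, ...) {
  cat(sprintf(
    "Transmitter release: T_max = %g mM, theta_s = %g mV, sigma_s = %g mV\n",
    x$T_max, x$theta_s, x$sigma_s))
  invisible(x)
}

#' @export
print.ligand_gated_params <- function(x, ...) {
  cat(sprintf(
    "Two-state receptor: alpha = %g /mM/ms, beta = %g /ms, g_max = %g mS, V_rev = %g mV\n",
    x$alpha, x$beta, x$g_max, x$V_rev))
  invisible(x)
}

#' @export
print.gabab_params <- function(x, ...) {
  cat(sprintf(
    "GABA_B cascade: alpha1 = %g, beta1 = %g, alpha2 = %g, beta2 = %g, K_d = %g, n = %d, g_max = %g mS, V_rev = %g mV\n",
    x$alpha1, x$beta1, x$alpha2, x$beta2, x$K_d, x$n, x$g_max, x$V_rev))
  invisible(x)
}
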