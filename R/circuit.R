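#' Cell-membrane parameters of one neural mass
#'
#' @param kappa_m ensemble membrane capacitance (charge/mV in the ms/mV/mS
#'   unit system), > 0. No experimental value is available at the ensemble
#'   scale; the default 1 puts the membrane time constant at
#'   `kappa_m/g_leak` = 100 ms with the default leak.
#' @param g_leak non-specific leak conductance (mS), >= 0.
#' @param V_leak leak reversal potential (mV).
#' @param V_rest resting potential used as the initial condition (mV).
#' @return an object of class `population_params`.
#' @export
population_params <- function(kappa_m = 1, g_leak, V_leak, V_rest) {
  stopifnot(is.numeric(kappa_m), length(kappa_m) == 1L, kappa_m > 0,
            is.numeric(g_leak), length(g_leak) == 1L, g_leak >= 0,
            is.numeric(V_leak), length(V_leak) == 1L, is.finite(V_leak),
            is.numeric(V_rest), length(V_rest) == 1L, is.finite(V_rest))
  structure(list(kappa_m = kappa_m, g_leak = g_leak, V_leak = V_leak,
                 V_rest = V_rest),
            class = "population_params")
}

#' Synaptic connectivity weights of the two-population circuit
#'
#' Multiplicative weights on the five synaptic pathways: retina to TCR
#' (AMPA), TRN to TCR (GABA_A and GABA_B), TCR to TRN (AMPA) and the
#' intra-TRN self-inhibition (GABA_A).
#'
#' The source connectivity table annotates the two TRN-to-TCR weights as
#' "34 of 30.9" and "14 of 30.9". They are implemented as plain weights 34
#' and 14; set `renormalize_tni = TRUE` to rescale them so that they sum to
#' 30.9 while keeping their ratio (the alternative reading of the
#' annotation).
#'
#' @param C_tre retina -> TCR weight.
#' @param C_tni_a TRN -> TCR GABA_A weight.
#' @param C_tni_b TRN -> TCR GABA_B weight.
#' @param C_nte TCR -> TRN weight.
#' @param C_nsi TRN -> TRN weight.
#' @param renormalize_tni rescale `C_tni_a`/`C_tni_b` to sum to 30.9.
#' @return an object of class `connectivity_params`.
#' @export
connectivity_params <- function(C_tre = 7.1, C_tni_a = 34, C_tni_b = 14,
                                C_nte = 35, C_nsi = 20,
                                renormalize_tni = FALSE) {
  w <- c(C_tre, C_tni_a, C_tni_b, C_nte, C_nsi)
  stopifnot(is.numeric(w), all(is.finite(w)), all(w >= 0))
  if (isTRUE(renormalize_tni)) {
    tot <- C_tni_a + C_tni_b
    if (tot > 0) {
      C_tni_a <- C_tni_a / tot * 30.9
      C_tni_b <- C_tni_b / tot * 30.9
    }
  }
  structure(list(C_tre = C_tre, C_tni_a = C_tni_a, C_tni_b = C_tni_b,
                 C_nte = C_nte, C_nsi = C_nsi,
                 renormalize_tni = isTRUE(renormalize_tni)),
            class = "connectivity_params")
}

#' Full parameterization of the thalamocortical circuit
#'
#' Assembles transmitter-release, receptor, membrane and connectivity
#' parameters of the two-population (TCR, TRN) circuit. The TCR population
#' receives AMPA input from the retina and GABA_A plus GABA_B input from
#' the TRN; the TRN receives AMPA input from the TCR and GABA_A input from
#' itself.
#'
#' @param transmitter either a single [transmitter_params()] shared by all
#'   afferents or a named list with elements `ret`, `tcr`, `trn`.
#' @param ampa_ret AMPA receptor parameters of the retina -> TCR synapse.
#' @param ampa_t2n AMPA receptor parameters of the TCR -> TRN synapse.
#' @param gabaa_n2t GABA_A parameters of the TRN -> TCR synapse.
#' @param gabaa_n2n GABA_A parameters of the intra-TRN synapse.
#' @param gabab_n2t GABA_B cascade parameters of the TRN -> TCR synapse.
#' @param tcr,trn [population_params()] of the two populations.
#' @param conn [connectivity_params()].
#' @return an object of class `circuit_params`.
#' @seealso [default_params()], [preset()]
#' @export
circuit_params <- function(transmitter, ampa_ret, ampa_t2n, gabaa_n2t,
                           gabaa_n2n, gabab_n2t, tcr, trn, conn) {
  if (inherits(transmitter, "transmitter_params"))
    transmitter <- list(ret = transmitter, tcr = transmitter,
                        trn = transmitter)
  stopifnot(is.list(transmitter),
            all(c("ret", "tcr", "trn") %in% names(transmitter)),
            all(vapply(transmitter[c("ret", "tcr", "trn")], inherits,
                       logical(1), "transmitter_params")),
            inherits(ampa_ret, "ligand_gated_params"),
            inherits(ampa_t2n, "ligand_gated_params"),
            inherits(gabaa_n2t, "ligand_gated_params"),
            inherits(gabaa_n2n, "ligand_gated_params"),
            inherits(gabab_n2t, "gabab_params"),
            inherits(tcr, "population_params"),
            inherits(trn, "population_params"),
            inherits(conn, "connectivity_params"))
  structure(list(transmitter = transmitter[c("ret", "tcr", "trn")],
                 ampa_ret = ampa_ret, ampa_t2n = ampa_t2n,
                 gabaa_n2t = gabaa_n2t, gabaa_n2n = gabaa_n2n,
                 gabab_n2t = gabab_n2t, tcr = tcr, trn = trn, conn = conn),
            class = "circuit_params")
}

#' Default circuit parameters
#'
#' The published parameter set of the kinetic thalamocortical circuit:
#' AMPA alpha = 2 /mM/ms, beta = 0.1 /ms, g_max = 0.1 mS, V_rev = 0 mV;
#' GABA_A alpha = 2, beta = 0.08, g_max = 0.1 (TRN->TCR, V_rev = -85 mV)
#' and 0.2 (TRN->TRN, V_rev = -75 mV); GABA_B alpha1 = 0.02, beta1 = 0.05,
#' alpha2 = 0.03, beta2 = 0.01, K_d = 100, n = 4, g_max = 0.06,
#' V_rev = -100 mV; leak 0.01 mS with V_leak = -55 (TCR) / -72.5 mV (TRN);
#' rest -61 / -84 mV; connectivity C_tre = 7.1, C_tni_a = 34, C_tni_b = 14,
#' C_nte = 35, C_nsi = 20.
#'
#' The transmitter-release sigmoid has no published values; the default
#' (`theta_s` = -58 mV, `sigma_s` = 1 mV, shared by all afferents) is the
#' package's one-time calibration, chosen so the default circuit under the
#' default retinal noise sits in the point-attractor regime while remaining
#' dynamically active (see the methods vignette).
#'
#' @param transmitter optional override of the release sigmoid(s).
#' @param renormalize_tni see [connectivity_params()].
#' @return a [circuit_params()] object.
#' @export
default_params <- function(transmitter = transmitter_params(),
                           renormalize_tni = FALSE) {
  circuit_params(
    transmitter = transmitter,
    ampa_ret  = ligand_gated_params(alpha = 2, beta = 0.1, g_max = 0.1,
                                    V_rev = 0),
    ampa_t2n  = ligand_gated_params(alpha = 2, beta = 0.1, g_max = 0.1,
                                    V_rev = 0),
    gabaa_n2t = ligand_gated_params(alpha = 2, beta = 0.08, g_max = 0.1,
                                    V_rev = -85),
    gabaa_n2n = ligand_gated_params(alpha = 2, beta = 0.08, g_max = 0.2,
                                    V_rev = -75),
    gabab_n2t = gabab_params(alpha1 = 0.02, beta1 = 0.05, alpha2 = 0.03,
                             beta2 = 0.01, K_d = 100, n = 4, g_max = 0.06,
                             V_rev = -100),
    tcr = population_params(kappa_m = 1, g_leak = 0.01, V_leak = -55,
                            V_rest = -61),
    trn = population_params(kappa_m = 1, g_leak = 0.01, V_leak = -72.5,
                            V_rest = -84),
    conn = connectivity_params(renormalize_tni = renormalize_tni))
}

#' Named circuit presets
#'
#' `"defaults"` is [default_params()]. `"spindling"` starts from
#' the defaults and sets the AMPA kinetics to alpha = 20, beta = 1 with
#' g_max = 0.3 on both AMPA pathways, the configuration in which the
#' circuit produces waxing-and-waning spindle oscillations.
#'
#' @param name preset name; see [preset_names()].
#' @return a [circuit_params()] object.
#' @export
preset <- function(name = preset_names()) {
  name <- match.arg(name)
  p <- default_params()
  if (name == "spindling") {
    p <- set_param(p, "ampa.alpha", 20)
    p <- set_param(p, "ampa.beta", 1)
    p <- set_param(p, "g_ampa", 0.3)
  }
  p
}

#' @rdname preset
#' @export
preset_names <- function() c("defaults", "spindling")

#' Leak current of a neural mass membrane
#'
#' @param V membrane potential (mV); vectorised.
#' @param pop a [population_params()] object.
#' @return leak current `g_leak * (V - V_leak)` (mS mV).
#' @export
leak_current <- function(V, pop) {
  stopifnot(inherits(pop, "population_params"), is.numeric(V))
  pop$g_leak * (V - pop$V_leak)
}

#' Membrane potential rate of change
#'
#' Current-balance equation of one neural mass:
#' `dV/dt = (-sum(weight * current) - leak_current(V)) / kappa_m`.
#'
#' @param V membrane potential (mV).
#' @param weighted_currents list of `c(weight, current)` pairs (or an empty
#'   list for a pure-leak membrane).
#' @param pop a [population_params()] object.
#' @return dV/dt (mV/ms).
#' @export
membrane_rate <- function(V, weighted_currents = list(), pop) {
  stopifnot(inherits(pop, "population_params"), is.numeric(V),
            is.list(weighted_currents))
  syn <- 0
  for (wc in weighted_currents) {
    stopifnot(is.numeric(wc), length(wc) == 2L)
    syn <- syn + wc[[1]] * wc[[2]]
  }
  (-syn - leak_current(V, pop)) / pop$kappa_m
}

#' Initial state of the circuit
#'
#' Voltages start at the published resting potentials; all gating variables
#' start closed (0). Transients are discarded by the analysis epoch.
#'
#' @param p a [circuit_params()] object.
#' @return named numeric state vector of length 8.
#' @export
initial_state <- function(p) {
  stopifnot(inherits(p, "circuit_params"))
  c(V_tcr = p$tcr$V_rest, V_trn = p$trn$V_rest,
    r_ampa_ret = 0, r_gabaa_n2t = 0, R_gabab = 0, X_gabab = 0,
    r_ampa_t2n = 0, r_gabaa_n2n = 0)
}

state_names <- function() {
  c("V_tcr", "V_trn", "r_ampa_ret", "r_gabaa_n2t", "R_gabab", "X_gabab",
    "r_ampa_t2n", "r_gabaa_n2n")
}

#' Vector field of the full circuit
#'
#' Time derivative of the 8-dimensional circuit state at a given retinal
#' drive potential. The TCR voltage is driven by retinal AMPA, TRN GABA_A
#' and TRN GABA_B currents (the GABA_B open fraction being the algebraic
#' Hill function of the G-protein concentration, not a stored state); the
#' TRN voltage by TCR AMPA and intra-TRN GABA_A currents.
#'
#' @param state named or unnamed numeric state vector of length 8 in the
#'   order of [initial_state()].
#' @param V_ret retinal ensemble potential (mV).
#' @param p a [circuit_params()] object.
#' @return named numeric vector of derivatives (per ms).
#' @export
circuit_rhs <- function(state, V_ret, p) {
  stopifnot(inherits(p, "circuit_params"), is.numeric(state),
            length(state) == 8L, is.numeric(V_ret), length(V_ret) == 1L,
            is.finite(V_ret))
  s <- as.numeric(state)
  T_ret <- transmitter_concentration(V_ret, p$transmitter$ret)
  T_tcr <- transmitter_concentration(s[1], p$transmitter$tcr)
  T_trn <- transmitter_concentration(s[2], p$transmitter$trn)

  dr_ampa_ret  <- ligand_gated_rate(s[3], T_ret, p$ampa_ret)
  dr_gabaa_n2t <- ligand_gated_rate(s[4], T_trn, p$gabaa_n2t)
  dRX          <- gabab_cascade_rate(s[5], s[6], T_trn, p$gabab_n2t)
  dr_ampa_t2n  <- ligand_gated_rate(s[7], T_tcr, p$ampa_t2n)
  dr_gabaa_n2n <- ligand_gated_rate(s[8], T_trn, p$gabaa_n2n)

  r_b <- gabab_open_fraction(s[6], p$gabab_n2t)
  dV_tcr <- membrane_rate(
    s[1],
    list(c(p$conn$C_tre,   synaptic_current(s[3], s[1], p$ampa_ret)),
         c(p$conn$C_tni_a, synaptic_current(s[4], s[1], p$gabaa_n2t)),
         c(p$conn$C_tni_b, synaptic_current(r_b,  s[1], p$gabab_n2t))),
    p$tcr)
  dV_trn <- membrane_rate(
    s[2],
    list(c(p$conn$C_nte, synaptic_current(s[7], s[2], p$ampa_t2n)),
         c(p$conn$C_nsi, synaptic_current(s[8], s[2], p$gabaa_n2n))),
    p$trn)

  out <- c(dV_tcr, dV_trn, dr_ampa_ret, dr_gabaa_n2t, dRX[["dR"]],
           dRX[["dX"]], dr_ampa_t2n, dr_gabaa_n2n)
  names(out) <- state_names()
  out
}

# Flatten circuit parameters into the numeric vector consumed by the
# compiled right-hand side. Order must match the enum in src/integrate.cpp.
pack_params <- function(p) {
  stopifnot(inherits(p, "circuit_params"))
  tr <- p$transmitter
  c(tr$ret$T_max, tr$ret$theta_s, tr$ret$sigma_s,
    tr$tcr$T_max, tr$tcr$theta_s, tr$tcr$sigma_s,
    tr$trn$T_max, tr$trn$theta_s, tr$trn$sigma_s,
    p$ampa_ret$alpha,  p$ampa_ret$beta,  p$ampa_ret$g_max,  p$ampa_ret$V_rev,
    p$ampa_t2n$alpha,  p$ampa_t2n$beta,  p$ampa_t2n$g_max,  p$ampa_t2n$V_rev,
    p$gabaa_n2t$alpha, p$gabaa_n2t$beta, p$gabaa_n2t$g_max, p$gabaa_n2t$V_rev,
    p$gabaa_n2n$alpha, p$gabaa_n2n$beta, p$gabaa_n2n$g_max, p$gabaa_n2n$V_rev,
    p$gabab_n2t$alpha1, p$gabab_n2t$beta1, p$gabab_n2t$alpha2,
    p$gabab_n2t$beta2, p$gabab_n2t$K_d, p$gabab_n2t$n, p$gabab_n2t$g_max,
    p$gabab_n2t$V_rev,
    p$tcr$kappa_m, p$tcr$g_leak, p$tcr$V_leak,
    p$trn$kappa_m, p$trn$g_leak, p$trn$V_leak,
    p$conn$C_tre, p$conn$C_tni_a, p$conn$C_tni_b, p$conn$C_nte, p$conn$C_nsi)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Thalamocortical circuit parameters (kinetic synapses)\n")
  cat(sprintf("  AMPA ret->TCR : alpha %g, beta %g, g %g, V_rev %g\n",
              x$ampa_ret$alpha, x$ampa_ret$beta, x$ampa_ret$g_max,
              x$ampa_ret$V_rev))
  cat(sprintf("  AMPA TCR->TRN : alpha %g, beta %g, g %g, V_rev %g\n",
              x$ampa_t2n$alpha, x$ampa_t2n$beta, x$ampa_t2n$g_max,
              x$ampa_t2n$V_rev))
  cat(sprintf("  GABA_A TRN->TCR: alpha %g, beta %g, g %g, V_rev %g\n",
              x$gabaa_n2t$alpha, x$gabaa_n2t$beta, x$gabaa_n2t$g_max,
              x$gabaa_n2t$V_rev))
  cat(sprintf("  GABA_A TRN->TRN: alpha %g, beta %g, g %g, V_rev %g\n",
              x$gabaa_n2n$alpha, x$gabaa_n2n$beta, x$gabaa_n2n$g_max,
              x$gabaa_n2n$V_rev))
  cat(sprintf("  GABA_B TRN->TCR: a1 %g, b1 %g, a2 %g, b2 %g, K_d %g, n %d, g %g, V_rev %g\n",
              x$gabab_n2t$alpha1, x$gabab_n2t$beta1, x$gabab_n2t$alpha2,
              x$gabab_n2t$beta2, x$gabab_n2t$K_d, x$gabab_n2t$n,
              x$gabab_n2t$g_max, x$gabab_n2t$V_rev))
  cat(sprintf("  TCR membrane: kappa %g, g_leak %g, V_leak %g, V_rest %g\n",
              x$tcr$kappa_m, x$tcr$g_leak, x$tcr$V_leak, x$tcr$V_rest))
  cat(sprintf("  TRN membrane: kappa %g, g_leak %g, V_leak %g, V_rest %g\n",
              x$trn$kappa_m, x$trn$g_leak, x$trn$V_leak, x$trn$V_rest))
  cat(sprintf("  Connectivity: C_tre %g, C_tni_a %g, C_tni_b %g, C_nte %g, C_nsi %g\n",
              x$conn$C_tre, x$conn$C_tni_a, x$conn$C_tni_b, x$conn$C_nte,
              x$conn$C_nsi))
  cat(sprintf("  Transmitter (ret): T_max %g, theta_s %g, sigma_s %g\n",
              x$transmitter$ret$T_max, x$transmitter$ret$theta_s,
              x$transmitter$ret$sigma_s))
  invisible(x)
}
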