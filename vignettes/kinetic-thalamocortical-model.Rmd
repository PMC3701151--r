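---
title: "A kinetic-synapse neural mass model of the thalamocortical circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic-synapse neural mass model of the thalamocortical circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinmass)
```

## The model

`kinmass` simulates a two-population neural mass model of the visual
thalamus: a thalamocortical relay (TCR) population, whose ensemble
membrane potential is the model output, and a thalamic reticular nucleus
(TRN) population that inhibits it. The retina drives the TCR through an
AMPA-type synapse; the TCR excites the TRN through AMPA; the TRN
inhibits the TCR through both GABA~A~ and GABA~B~ receptors and inhibits
itself through GABA~A~. Each state variable is an "ensemble" quantity
standing for the average over 10^4^–10^7^ co-active neurons.

What distinguishes this model from the classical neural-mass lineage is
the synapse. Instead of convolving presynaptic activity with an alpha
kernel (the conventional building block, kept in this package as
`alpha_impulse_response()` / `alpha_psp_rate()` for comparison), synaptic
transmission is modelled mechanistically in three stages:

1. **Release.** The cleft transmitter concentration is a sigmoid of the
   presynaptic ensemble potential,
   $[T](V) = T_{\max} / (1 + e^{-(V-\theta_s)/\sigma_s})$, saturating at
   $T_{\max} = 1$ mM.
2. **Gating.** AMPA and GABA~A~ channels are two-state (open/closed):
   $\dot r = \alpha [T] (1-r) - \beta r$. The desensitized state is
   deliberately ignored; two-state kinetics fit ligand-gated channel data
   remarkably well.
3. **GABA~B~ cascade.** Transmitter activates receptors
   ($\dot R = \alpha_1 [T](1-R) - \beta_1 R$), activated receptors
   catalyse G-protein production ($\dot X = \alpha_2 R - \beta_2 X$), and
   the G-protein opens channels through a Hill function
   $r = X^n / (X^n + K_d)$ with $n = 4$ binding sites.

Each postsynaptic current is $I = g_{\max} r (V - V_{rev})$, weighted by
an anatomical connectivity constant, and each membrane obeys
$\kappa_m \dot V = -\sum C \cdot I - g_\lambda (V - V_\lambda)$. The
eight state variables (two voltages, six gating variables) are assembled
in `circuit_rhs()`; `default_params()` carries the published parameter
set (AMPA $\alpha = 2$ /mM/ms, $\beta = 0.1$ /ms, $g = 0.1$ mS; GABA~A~
$\alpha = 2$, $\beta = 0.08$, $g = 0.1$ mS TRN→TCR and $0.2$ mS
TRN→TRN; GABA~B~ $\alpha_1 = 0.02$, $\beta_1 = 0.05$,
$\alpha_2 = 0.03$, $\beta_2 = 0.01$, $K_d = 100$, $g = 0.06$ mS; leak
$0.01$ mS; weights $C_{tre} = 7.1$, $C^a_{tni} = 34$, $C^b_{tni} = 14$,
$C_{nte} = 35$, $C_{nsi} = 20$). Units project-wide: ms, mV, mS, mM.

The connectivity table annotates the TRN→TCR weights as "34 of 30.9" and
"14 of 30.9", a notation with two defensible readings; the package uses
the plain weights 34 and 14 by default and offers
`connectivity_params(renormalize_tni = TRUE)` to rescale them onto a
total of 30.9 while preserving their ratio.

## Stochastic drive and integration

The only input is the retinal ensemble potential at rest, modelled as
Gaussian white noise. True white noise is incompatible with an adaptive
integrator, so the drive is realized piecewise-constant: one independent
draw per 1-ms hold interval (`generate_retinal_drive()`), which matches
the 1-ms simulation resolution of the reference protocol and makes the
ODE piecewise smooth. Within each hold the circuit is integrated by an
embedded Runge–Kutta–Fehlberg 4(5) pair with adaptive step control
(tolerances $10^{-6}$ relative / $10^{-8}$ absolute by default),
restarted at every hold boundary; a fixed-step classic RK4 at 0.01 ms is
kept as an independent oracle and the two agree to better than 0.01 mV
over 10 s on the spindling preset. Gating variables stay inside $[0,1]$
by the dynamics alone — no clipping is applied, and the tests assert no
excursion beyond $10^{-9}$.

The reference protocol integrates 600 s at 1-ms reporting resolution and
averages the TCR voltage over 20 trials, each with its own noise seed
(trial $k$ uses `seed + k`). `run_ensemble()` implements this; all
randomness flows through a private RNG stream so the session RNG is
untouched, and identical seeds give bit-identical traces.

## Spectral analysis and regime classification

`preprocess()` reproduces the reference analysis chain: crop to the
post-transient epoch (100–599 s in the full protocol), decimate
1000 Hz → 250 Hz behind an anti-alias low-pass, and band-pass
3.5–14 Hz with an order-10 Butterworth design. Filtering is applied
forward–backward (zero phase): the regime metrics below depend on signal
envelopes, which phase distortion would bias. `stft()` computes a
one-sided power spectrogram with a 10-s Hamming window at 50% overlap,
normalized so each column satisfies the discrete Parseval identity;
`band_power()` integrates it over the theta (4–7 Hz) and alpha
(8–13 Hz) bands.

`classify_regime()` formalizes the qualitative regime vocabulary into
five labels, decided in order on the ensemble-averaged output:

* **quiescent** — raw epoch SD below $10^{-3}$ of the absolute mean
  level;
* **slow_oscillation** — the globally dominant component of the raw,
  detrended epoch lies below 0.5 Hz and stands ≥ 10 dB above the
  slow-band median spectrum (the band-passed chain would destroy
  sub-Hz structure, so this test runs on the raw signal);
* **point_attractor** — no peak of the in-band Welch spectrum rises
  10 dB above the in-band median (the output merely reflects the noisy
  drive);
* **limit_cycle** — otherwise, if the analytic-signal envelope has a
  coefficient of variation below 0.25 (constant-envelope oscillation);
* **spindling** — otherwise (waxing-and-waning envelope); a burst-rate
  metric (envelope excursions above twice the median, per minute) is
  reported alongside.

All thresholds are `spectral_config()` fields; they were fixed once
against constructed synthetic signals (pure tones, AM bursts, noise,
slow sines — the same signals frozen into the test suite) and are not
tuned against model output. Welch averaging (the STFT columns) rather
than a raw periodogram decides spectral prominence because raw
periodogram bins fluctuate enough, over a 500-s epoch, to push white
noise across any usable threshold.

## Calibration of the unprinted parameters

Four quantities the model needs are not fixed by the published
parameterization: the release-sigmoid position and steepness
($\theta_s$, $\sigma_s$), the retinal noise mean and SD, and the
ensemble membrane capacitance $\kappa_m$. They were calibrated once,
before freezing, against two requirements: the default parameter set
must sit in the point-attractor regime while remaining dynamically
active, and raising the AMPA unbinding rate $\beta$ must carry the model
into a sustained oscillation.

The survey (several thousand configurations over per-afferent
$\theta_s$, $\sigma_s$, noise settings and $\kappa_m$) found one
mechanism with that orientation: with $\theta_s$ midway between the TCR
resting and leak potentials ($-58$ mV), a steep sigmoid
($\sigma_s = 1$ mV), and a retinal drive of mean $-67.5$ mV and SD 2 mV,
the tonic retinal AMPA conductance holds the TCR above the release
threshold (a stable, noise-rectified latch: the classical
"low-amplitude noisy output reflecting the input"), and reducing the
open-channel fraction by raising $\beta$ releases a theta/alpha-band
relaxation oscillation carried by the leak-driven TCR drift and the
TCR–TRN loop. $\kappa_m$ stays at 1, putting the leak time constant at
100 ms. These are the package defaults; everything is overridable per
pathway.

Two properties of the model under this (or, as far as the survey could
establish, any) calibration deserve emphasis, because they bound what
the simulations can show:

* **The printed GABA~B~ constants make the cascade nearly inert.** With
  $\alpha_1 = 0.02$, $\beta_1 = 0.05$ the activated-receptor fraction
  saturates at $\alpha_1/(\alpha_1+\beta_1) = 0.286$ even at maximal
  transmitter; with $\alpha_2/\beta_2 = 3$ the G-protein concentration
  therefore never exceeds $0.86$, and the Hill stage
  $X^4/(X^4 + 100)$ opens at most 0.54% of the channels. The slow
  inhibitory feedback that sustains waxing-and-waning spindling and the
  very-low-frequency (~0.03 Hz) synchronized state in the experimental
  literature cannot operate at that amplitude. Consequently the
  spindling preset classifies as a point attractor here, and the
  intra-TRN blockade configuration shows only broadband sub-0.5 Hz
  drift rather than a coherent ~0.03 Hz line.
* **Ensemble averaging decoheres oscillation phase.** Trials differ
  only in their noise stream, and the oscillation phase diffuses across
  trials over hundreds of seconds. The pointwise mean of decohered
  oscillations keeps the rhythm but acquires an irregularly modulated
  envelope (CV ≈ 0.5), so on ensemble averages the released oscillation
  classifies as *spindling* rather than *limit_cycle*. A
  constant-envelope label on a 20-trial average would require phase
  coherence throughout the epoch, which no noise level compatible with
  a noise-stabilized default can provide. Single-trial output does
  classify as a limit cycle deep in the oscillatory regime.

## Sweeps and experiments

`run_sweep()` takes a `sweep_spec()` (a dotted parameter path or a
linked alias such as `"g_ampa"`, which moves both AMPA conductances
jointly, with `"g_ampa_tcr"` / `"g_ampa_trn"` as the separate knobs), a
sorted grid, and the protocol configuration; each grid point is
simulated, ensemble-averaged and classified, with session-level caching
keyed by parameters and seeds. `find_bifurcation()` reports the first
grid value whose label matches the target while its predecessor matches
the source — the bracketing grid value, not a refined root, since the
reference account itself reports an approximate bifurcation point.
`blockade_experiment()` zeroes the maximum conductance of named
pathways; the tests verify this is exactly equivalent to removing the
pathway's connectivity weight.

Ready-made configurations for the sweep and blockade experiments ship
under `inst/experiments/`, and a thin command-line wrapper
(`inst/cli/kinmass`) exposes `simulate`, `ensemble`, `analyze`, `sweep`,
`blockade` and `presets` verbs over YAML configs.

## Problem sizes and numerical choices

The test suite and the acceptance script use a scaled protocol — 5
trials of 150 s with 120-s analysis epochs (440 s for the slow
configuration, so that a 0.005-Hz floor stays resolvable with two full
cycles) — as the reduced counterpart of the full 20 × 600 s protocol;
the shipped experiment configs carry the full protocol. Classifier
decisions at the regime boundaries shift by at most one grid step
between the scales.

Other numerical choices: periodograms are linearly detrended before
peaking; the slow-band floor is raised to $2/T$ for epochs shorter than
400 s; the forward–backward order-10 Butterworth cascade is linear to
about $10^{-6}$ relative (double-precision conditioning of a high-order
IIR, which is why the linearity test uses that tolerance rather than
machine epsilon); the bi-exponential baseline ODE is implemented exactly
as conventionally printed, and its impulse response — verified
numerically — equals the kernel
$H(e^{-t/\tau_a} - e^{-t/\tau_b})$, which is non-positive under the
stated side condition $\tau_b > \tau_a$; this sign is documented rather
than silently corrected.

## Known limitations

Interneurons, cortical populations and corticothalamic feedback are
outside the model's scope, as are single-cell mechanisms (T-type
calcium and h-currents) that contribute to thalamic rhythms in nature.
The regime labels operationalize a qualitative vocabulary; their
thresholds are defaults, not measurements. And as detailed above, the
printed GABA~B~ parameterization caps that pathway's influence, so
GABA~B~-dependent phenomena (sustained slow oscillation under intra-TRN
GABA~A~ blockade, spindle-envelope pacing) are outside what this
parameter set can produce; the package reports what the equations give.
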