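---
title: "The subthalamo-pallido-thalamic network model: equations, presets and analysis conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The subthalamo-pallido-thalamic network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgdbs)
```

## The model

`bgdbs` implements a conductance-based network of four basal-ganglia
populations — subthalamic nucleus (STN), external and internal globus
pallidus (GPe, GPi) and thalamus — with 20 single-compartment
Hodgkin–Huxley-type cells per population. The model's purpose is mechanistic:
in its Parkinsonian (PD) parameter regime the STN–GPe loop generates
synchronized beta-band (13–30 Hz) bursting driven by post-inhibitory rebound
through the low-threshold T-type calcium current, and the package's
stimulation layer asks whether high-frequency deep brain stimulation (DBS) of
the STN quenches that rhythm when it is excitatory (EDBS) or inhibitory
(IDBS).

### Cell equations

Each STN/GPe/GPi cell follows

$$C_m v' = -I_L - I_{Na} - I_K - I_{Ca} - I_T - I_{AHP} - I_{syn} + I_{app}$$

with instantaneous activations ($m_\infty^3 h$ sodium, $n^4$ potassium,
$s_\infty^2$ high-threshold calcium), a T-type current gated by a slow
variable $r$, a calcium-gated after-hyperpolarization current
$g_{AHP}(v-E_K)\,[Ca]/([Ca]+k_1)$, and first-order gating kinetics
$X' = \phi_X (X_\infty(v) - X)/\tau_X(v)$ for $X = n, h, r$ with
$\tau_X(v) = \tau^0_X + \tau^1_X/(1+e^{-(v-\theta^\tau_X)/\sigma^\tau_X})$.
The calcium pool integrates the two calcium currents,
$[Ca]' = \varepsilon(-I_{Ca} - I_T - k_{Ca}[Ca])$. The STN T current is
gated by $b_\infty(r)^2$, where $b_\infty$ is a logistic in $r$ normalized so
that $b_\infty(0) = 0$; the pallidal cells gate their T current by $r$
directly (they carry no $\theta_b, \sigma_b$ constants). Thalamocortical
relay cells are three-variable cells ($v, h, r$) with the potassium
activation tied to sodium inactivation through $(0.75(1-h))^4$ and a
rebound-generating T current $g_T\,p_\infty(v)^2\,r\,(v - E_T)$.

Synapses are conductance-based: each presynaptic neuron carries one gate
$s' = \alpha H_\infty(v_{pre} - \theta_{pre})(1-s) - \beta s$ shared by all
of its targets (the gate depends only on the presynaptic voltage), and the
postsynaptic current is $g\,(v_{post} - E)\sum_j s_j$. With the
double-shift convention (default) the gate's effective midpoint is
$\theta_{pre} + \theta^H$ (−19 mV for STN, −27 mV for the pallidal cells), so
transmitter release is spike-triggered. A single-shift variant
(`theta_shift = "single"`, midpoint $\theta^H$ alone) is available for
sensitivity analysis; under it the printed $\theta_{pre}$ constants are dead
parameters and the pallidal gates would be half-open at subthreshold
voltages, which is why it is not the default.

### Connectivity

Wiring is deterministic and sparse (`buildConnectivity()`): STN cell *i*
excites GPe *i* and GPi *i*; GPe cell *i* inhibits STN, GPe and GPi cells
*i±1*; GPi cell *i* inhibits thalamic cell *i*. Neighbour indices wrap
around (ring topology): an open chain would give the two end cells a single
GPe afferent, violating the stated two-afferent in-degree, so the ring is
the only layout consistent with the degree constraints. Indices are 0-based
in all serialized output.

### Healthy and Parkinsonian presets

`conditionPreset()` bundles all constants. The healthy→PD switch changes
exactly: $I_{app}$ of STN (8.4→3), GPe (5.9→0.5) and GPi (7.7→4) pA/µm²
(reduced cortical drive and increased striato-pallidal inhibition), and the
coupling $g_{GPe\to STN}$ (2.2→7), $g_{STN\to GPe}$ (0.01→0.55),
$g_{GPe\to GPe}$ (0.01→0.9), $g_{STN\to GPi}$ (0.005→1.1),
$g_{GPe\to GPi}$ (0.01→1.9) nS/µm² (subthalamo-pallidal strengthening).
$g_{GPi\to Th} = 0.05$ nS/µm² in both conditions. Thalamic parameters are
condition-independent.

A handful of printed constants required editorial resolution; all of them
live in one annotated block in `R/presets.R` and are overridable:

* the STN table lists $\tau^1_h$ twice (500 and 100 ms); the second value is
  assigned to $\tau^1_n$, the only otherwise-missing STN time constant;
* "$\theta^1_r$ 17.5 mV" is read as $\tau^1_r = 17.5$ ms, and the garbled
  n-gate entry "−26 mV" as $\sigma^\tau_n = -26$ mV (uncertain; exposed as
  the `sigma_tau_n` argument of `neuronParameters()`);
* the published time-constant formula omits the slope divisor
  $\sigma^\tau_X$ even though the tables list $\sigma^\tau$ values;
  the divisor is restored, otherwise those entries would be dead parameters;
* the offset in $b_\infty$ is taken as $1/(1+e^{-\theta_b/\sigma_b})$ so
  that $b_\infty(0) = 0$; the printed variant ($e^{\theta_b/\sigma_b}$,
  differing by <4e-4) is selectable via `b_form = "printed"`;
* the thalamic potassium constants are absent from the printed table and are
  filled from the thalamocortical relay cell of the model's lineage
  ($g_K = 5$ nS/µm², $E_K = -90$ mV);
* the thalamic $r_\infty$ midpoint is implemented at −84 mV. The printed
  value (−48 mV) leaves the T-type deinactivation gate ~97% open at rest,
  which hands the relay cell a large tonic inward current: it then sits
  around −30 mV, never rests, never relays, and fires at rest even in the
  healthy network — contradicting every thalamic result the model is built
  to produce. −84 mV is the lineage value and the two digits are a plain
  transposition. This is the single thalamic constant corrected against the
  printed equations.

### Stimulation

All pulse trains come from one closed form
(`pulseWaveform()`): rectangular pulses of width $\delta$ immediately before
each downward zero-crossing of $\sin(2\pi f t/1000)$. DBS uses
$f = 150$ Hz, $\delta = 0.1$ ms, with amplitude positive (EDBS) or negative
(IDBS); the paired working amplitudes ±126.57 and ±147.36 pA/µm² are the
equal-STN-rate amplitudes found by the sweep (below). Cortico-thalamic
sensorimotor (SMC) drive uses $A = 4.5$ pA/µm², $f = 20$ Hz, $\delta = 5$ ms.
DBS reaches every STN cell identically (no per-neuron jitter — nothing in
the model suggests one) and SMC reaches every thalamic cell identically.
The `"poisson"` pattern replaces the regular grid by a homogeneous Poisson
process of the same rate, redrawn per trial from the trial seed. The
resting state is SMC set to zero.

## Numerics

The production integrator is fixed-step RK4 at 0.05 ms, compiled (Rcpp);
stimuli are sampled piecewise-constant on the step grid (a 0.1 ms DBS pulse
covers 2–3 samples). Spikes are detected during integration as upward
crossings of −10 mV separated by ≥2 ms. The first 250 ms of every run are
discarded; analysis rasters are re-zeroed at that boundary. Initial
conditions (the only stochastic ingredient besides Poisson pulse trains) are
drawn per trial: $v \sim U(-70, -50)$ mV, gates at their steady state for the
drawn voltage, $[Ca] = 0.05$ (arbitrary units), synaptic gates at 0. Trial
seeds derive deterministically from a master seed, so ensembles are
reproducible and identical under serial or parallel execution.

`solver = "adaptive"` integrates an independent R transcription of the same
vector field with deSolve's lsoda; at a fine step the two routes agree
pathwise to ~1e-3. One caveat documented by the tests: the coupled network is
chaotic, with spike-time perturbations reaching inter-spike-interval scale
within ~100 ms, so trajectories at the 0.05 ms production step and at finer
steps (or the adaptive solver) diverge pathwise on long horizons while all
ensemble statistics (rates, spectra, synchrony) agree. Single cells,
which are not chaotic, are converged at 0.05 ms (spike counts change by ≤1
under step halving).

## Analysis conventions

* **Population firing rate**: spikes of all neurons in a sliding 10 ms
  window, 1 ms step, divided by window length *and neuron count* (sp/s per
  neuron). The per-neuron normalization makes the series commensurate with
  the reported per-neuron means (~19–65 sp/s); a raw-population mode exists.
  The Fano factor (variance/mean of that series, population variance) is
  scale-dependent, so its convention is fixed package-wide and recorded here.
* **Spectra**: Welch's method with the reference defaults — 1000 Hz
  sampling, 1000-sample segments, periodic Hann window, 50% overlap,
  per-segment constant detrend, one-sided density scaling (validated against
  closed-form expectations in the tests). Characterization therefore needs
  ≥1009 ms of analysed time per trial; the default runs use 2250 ms total
  (2000 ms analysed, two Welch segments). The oscillation index is the
  trapezoid area of the mean PSD in 13–30 Hz over the area in 1–500 Hz
  (edges inclusive on the 1 Hz Welch grid); the peak frequency is the argmax
  over 1–500 Hz.
* **Thalamic fidelity**: per neuron and SMC pulse, spikes in
  [onset, onset + 25 ms) are classified correct (exactly 1), missed (0) or
  extra (k−1 of k≥2); spikes outside every window are undesired; fidelity is
  $1 - (N_M + N_E + N_U)/N_{exp}$ with $N_{exp}$ = neurons × pulses. The
  25 ms window is a package convention (the defining supplementary figure is
  not in the main text); it is half the 20 Hz inter-pulse interval, so
  windows cannot overlap.
* **Bursts**: maximal runs of inter-spike intervals ≤10 ms with ≥3 spikes
  (a declared convention, carried in the output metadata); burst rate is
  bursts per neuron per second, duration last−first spike.
* **Excessive thalamic activity**: the mean thalamic rate of a resting-state
  (SMC-off) run — any such spiking is pathological.

## Experiments and scale

`runCharacterization()` reproduces the healthy/PD comparison (rates, Fano
factor, spectra, oscillation index, fidelity, GPi bursts);
`runDbsComparison()` adds EDBS/IDBS protocols on the PD network with deltas
against the PD baseline; `runAmplitudeSweep()` sweeps ±50–300 pA/µm² at
150 Hz and locates the equal-rate crossings of the EDBS and IDBS STN-rate
curves by linear interpolation; `runRestingState()` measures the excessive
thalamic activity. Defaults are desk-scale: 10 trials for characterization
and 5 per sweep point (the original analyses used 50 and 20) — a full
characterization ensemble runs in ~15 s on one CPU, the default sweep in
~2 min. Trial counts are plain arguments, so full-scale runs are one flag
away.

In this implementation the EDBS/IDBS rate curves cross more than twice over
the sweep range: beyond ~180 pA/µm², excitation drives GPe so hard that the
strengthened PD pallido-subthalamic feedback silences part of the STN and
the curve order inverts again. The sweep therefore reports all crossings but
defines the *operating pair* as the first two sign changes of
rate$_{EDBS}$ − rate$_{IDBS}$ (≈117 and ≈158 pA/µm² on the default grid);
`upper_crossing` is the larger of that pair.

## What the simulations do and do not show

The generator of variability is the initial-condition distribution and (for
irregular DBS) Poisson pulse trains; there is no channel noise, no synaptic
jitter, no heterogeneity across cells of a population, no axonal delay, and
no cortex or striatum. Reproducing the published summary statistics
therefore tests the network mechanism — rebound-driven beta in the
subthalamo-pallidal loop and its response to stimulation — not the
biological realism of any single cell.

Two published quantities resist reproduction from the printed parameter set,
and the package reports them honestly rather than absorbing them into
recalibrated parameters:

* **Healthy GPi rate.** The printed GPi cell (the GPe cell with
  $\phi_h = 0.1$, $\phi_n = 0.135$, $I_{app} = 7.7$) fires ~47 sp/s in the
  healthy network, versus the published 56.52 ± 2 sp/s. The GPe anchor —
  the same cell at its own constants gives 45.5 sp/s against a published
  45.47 — says the shared pallidal parameters are right; no defensible
  reading of the GPi-specific entries reaches 56 sp/s (it would need
  $I_{app} \approx 10$).
* **Resting-state thalamic activity.** In the PD resting state each pause
  between GPi bursts releases one thalamic rebound spike, so the excess rate
  tracks the GPi burst rate (~13 bursts/s at the ~28 Hz network rhythm),
  giving ~13.7 sp/s versus the published 8.24 ± 1. In the healthy resting
  state the model's slower, pause-prone GPi (the point above) lets through
  ~4 sp/s of thalamic rebound where the publication reports silence. Both
  deviations trace to the same GPi discrepancy and are stable across seeds.

Everything else in the headline set reproduces within the across-trial
dispersion: healthy STN/GPe rates, all three PD rates with their directional
switches, beta-band emergence in PD (peak ~28 Hz; oscillation index and Fano
factor above healthy in STN, GPe and GPi in every seed), quenching by EDBS
but not IDBS (regular or Poisson), the fidelity ordering
healthy ≈ EDBS > PD ≥ IDBS, and the equal-rate crossing near 150 pA/µm².

## A worked example

```{r example, eval = FALSE}
library(bgdbs)

# healthy vs Parkinsonian characterization (10 trials each)
healthy <- runCharacterization("healthy", n_trials = 10, master_seed = 1)
pd <- runCharacterization("PD", n_trials = 10, master_seed = 1)
print(pd)

# regular excitatory DBS at the upper equal-rate amplitude
edbs <- runCharacterization("PD", n_trials = 10, master_seed = 1,
                            dbs = stimulusProtocol("EDBS"))
c(PD = pd$populations$STN$oscillation_index,
  EDBS = edbs$populations$STN$oscillation_index)

# locate the equal-rate amplitudes
sw <- runAmplitudeSweep(n_trials = 5, master_seed = 1)
sw$crossing_pair
```
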