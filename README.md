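# bgdbs — Parkinsonian beta oscillations and deep brain stimulation in a subthalamo-pallido-thalamic network model

`bgdbs` is an R package for simulating a conductance-based
(Hodgkin–Huxley-type) network of the subthalamic nucleus (STN), external and
internal globus pallidus (GPe, GPi) and thalamus — 20 single-compartment
cells per population — and for analysing its spike output with the summary
statistics used in the basal-ganglia literature. It is aimed at
computational neuroscientists studying the subthalamo-pallidal origin of
Parkinsonian beta-band (13–30 Hz) oscillations and the mechanism of
high-frequency deep brain stimulation (DBS).

The scientific core:

* **Cells.** STN/GPe/GPi cells follow
  `C_m v' = −I_L − I_Na − I_K − I_Ca − I_T − I_AHP − I_syn + I_app`
  with first-order gating `X' = φ_X (X∞(v) − X)/τ_X(v)` and a calcium pool
  `[Ca]' = ε(−I_Ca − I_T − k_Ca [Ca])`; the STN low-threshold T current is
  gated by `b∞(r)²`, the engine of post-inhibitory rebound bursting.
  Thalamocortical relay cells are three-variable cells whose T current
  `g_T p∞(v)² r (v − E_T)` converts pauses in pallidal inhibition into
  rebound spikes.
* **Synapses.** Conductance-based gates
  `s' = α H∞(v_pre − θ_pre)(1 − s) − β s`, current `g (v_post − E) Σ s_j`,
  on a deterministic sparse ring: STN *i* → GPe *i*, GPi *i*; GPe *i* ⊣
  STN/GPe/GPi *i±1*; GPi *i* ⊣ thalamus *i*.
* **Conditions.** A healthy and a Parkinsonian (PD) preset differing only in
  the applied currents (STN 8.4→3, GPe 5.9→0.5, GPi 7.7→4 pA/µm²) and the
  subthalamo-pallidal coupling (e.g. g_GPe→STN 2.2→7 nS/µm²).
* **Stimulation.** Heaviside-gated pulse trains: 150 Hz, 0.1 ms DBS pulses
  (excitatory EDBS or inhibitory IDBS, regular or Poisson-irregular) to every
  STN cell, and 20 Hz, 5 ms, 4.5 pA/µm² cortico-thalamic sensorimotor pulses
  to every thalamic cell.
* **Metrics.** Sliding-window population firing rate (10 ms window, 1 ms
  step, per-neuron normalized), Fano factor of that series (synchrony),
  Welch power spectra (1000 Hz, 1000-sample segments) with the beta-band
  oscillation index (area 13–30 Hz / area 1–500 Hz) and peak frequency,
  thalamic relay fidelity `1 − (N_missed + N_extra + N_undesired)/N_expected`,
  burst statistics (ISI ≤ 10 ms, ≥ 3 spikes), and resting-state (excessive)
  thalamic activity.

The integrator is fixed-step RK4 at 0.05 ms in compiled code; an independent
R transcription of the vector field integrated with deSolve (`solver =
"adaptive"`) serves as a cross-check. Trial ensembles are seeded and
reproducible, serial or parallel.

## A worked example

```r
library(bgdbs)

healthy <- runCharacterization("healthy", n_trials = 10, master_seed = 1)
pd      <- runCharacterization("PD",      n_trials = 10, master_seed = 1)
edbs    <- runCharacterization("PD", n_trials = 10, master_seed = 1,
                               dbs = stimulusProtocol("EDBS"))  # +147.36 pA/µm²
idbs    <- runCharacterization("PD", n_trials = 10, master_seed = 1,
                               dbs = stimulusProtocol("IDBS"))  # −147.36 pA/µm²
print(pd)
```

```
<metrics_report> PD (10 trials, 2000 ms analysed per trial)
  STN  rate  28.04 +- 1.37 sp/s | Fano   7.53 | OI 0.777 | peak 28 Hz
  GPe  rate  36.81 +- 0.34 sp/s | Fano   9.82 | OI 0.833 | peak 28 Hz
  GPi  rate  55.40 +- 0.42 sp/s | Fano  10.90 | OI 0.861 | peak 28 Hz
  Th   rate  23.34 +- 0.36 sp/s | Fano  52.51 | OI 0.589 | peak 20 Hz
  thalamic fidelity 0.823 +- 0.017 | GPi bursts 13.20 /s (15 ms, 4.1 spikes)
```

Reading the numbers: in the PD preset the STN rate rises (28.0 vs 21.3 sp/s
healthy), the population rhythm peaks at 28 Hz inside the beta band, and the
oscillation index (OI) jumps from 0.15 (healthy) to 0.78 — synchronized beta
bursting. Thalamic fidelity to the 20 Hz sensorimotor drive drops from 0.99
to 0.82 because the GPi now bursts (~13 bursts/s) instead of firing
tonically. Applying excitatory versus inhibitory DBS to the STN separates
the two hypotheses about DBS action:

```r
sapply(list(healthy = healthy, PD = pd, EDBS = edbs, IDBS = idbs),
       function(r) r$populations$STN$oscillation_index)
#>    healthy         PD       EDBS       IDBS
#> 0.14877780 0.77740370 0.06375637 0.75597020
```

EDBS quenches the beta oscillation (OI 0.78 → 0.06, fidelity back to 0.99);
IDBS at the matched amplitude leaves it intact (OI 0.76, fidelity 0.77) —
the excitatory reading of DBS. The matched amplitudes are the equal-rate
crossings of the two STN rate-vs-amplitude curves:

```r
sw <- runAmplitudeSweep(n_trials = 5, master_seed = 1)
sw$crossing_pair   # ≈ 117 and 158 pA/µm²
```

Resting state (sensorimotor input off): `runRestingState("healthy", ...)`
leaves the thalamus nearly silent, while the PD network shows excessive
rebound spiking (~13.7 sp/s with this preset), suppressed by EDBS but not by
IDBS.

See the vignette (`vignettes/bgdbs-model.Rmd`) for the full model
description, the editorial resolutions applied to ambiguous printed
constants, analysis conventions, and known limitations — including the two
published summary values (healthy GPi rate; resting-state thalamic rate)
that the printed parameter set does not reproduce.

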