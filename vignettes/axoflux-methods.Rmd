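---
title: "Models and methods behind axoflux"
author: "axoflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoflux)
```

# The scientific problem

Alpha-toxins from scorpion venom bind voltage-gated Na⁺ channels (Na_v) and
slow their inactivation. At the whole-cell level this prolongs the action
potential (AP); in the axon initial segment (AIS), where Na_v density is
highest and the AP is generated, the effect is much stronger and has
downstream consequences for Na⁺ and Ca²⁺ influx. Quantifying this requires
a chain of measurements — voltage-clamp dose–response in expression
systems, somatic electrode recordings, and high-speed fluorescence imaging
of membrane potential, Na⁺ and Ca²⁺ in the AIS — each with its own
preprocessing and statistics.

`axoflux` packages that analysis chain, together with a biophysical
simulator that generates synthetic recordings with the same structure, so
every step of the chain can be validated against a known ground truth.

# The voltage-clamp model and the T50 statistic

A depolarising step (default −100 mV → 0 mV for 50 ms, 20 kHz) elicits an
inward Na⁺ current modelled as

$$ I(t) = g_\max\, m(t)^3\, h_\text{eff}(t)\,(V - E_\text{Na}), \qquad
   m(t) = 1 - e^{-t/\tau_\text{act}} $$

with the inactivation term partitioned by equilibrium toxin occupancy
$\phi$ (a Hill function of concentration, $\phi(c) = c^n/(c^n +
EC_{50}^n)$):

$$ h_\text{eff}(t) = (1-\phi)\,e^{-t/\tau_h} +
   \phi\left[p + (1-p)\,e^{-t/(k\,\tau_h)}\right]. $$

Bound channels inactivate $k$-fold more slowly (`slowdown`) and keep a
fraction $p$ of their conductance at the end of the step
(`persistent_frac`). The binding scheme is deliberately minimal: the data
this package analyses constrain phenomenology (delayed inactivation, a
persistent component, saturation with concentration), not a kinetic
mechanism.

**T50** is the time from the current peak to the point where the magnitude
has decayed halfway from peak to the residual current at the end of the
step, with the crossing located by linear interpolation between samples
(this removes the sample-rate bias of a nearest-sample rule). For a pure
exponential decay with residual → 0, T50 = τ·ln 2 exactly, which the test
suite uses as a closed-form oracle. T50 is invariant to rescaling of the
current, so it can be compared across cells with different channel
densities.

Dose–response tables collect per-cell relative T50 increases,
`(T50_toxin − T50_ctrl)/T50_ctrl`; per-concentration means are divided by
the maximal mean so the largest effect is exactly 1. Normalisation to the
maximum is the natural reading of a published series whose maximum prints
as 1, but it is an inference, not a statement about the original
computation.

# The soma-plus-axon AP simulator

`simulate_ap_experiment()` integrates a chain of compartments: a soma plus
an axon sampled every 5 µm out to 45 µm, resistively coupled — the same
spatial grid as the imaging ROIs. Each compartment carries:

* a Na⁺ conductance with HH-style gating (`m³h`, steady-state activation
  and inactivation curves with fixed midpoints and slopes). The
  inactivation time constant is bell-shaped in voltage: fast at spike-top
  voltages, slow around −55 mV and fast again near rest. The subthreshold
  slow lobe gives refractoriness — it prevents re-firing during the
  remainder of the stimulus pulse, a failure mode that otherwise corrupts
  the width statistic;
* a fast delayed-rectifier K⁺ conductance (`n²`). Its activation midpoint
  is −35 mV at the soma and −25 mV in the axon: the somatic AP then falls
  steeply through the −30 mV width threshold, which keeps the somatic
  width metric well conditioned;
* a slow M-type-like adaptation K⁺ conductance. Without it, the
  persistent-Na component sustains a standing depolarised plateau that
  never repolarises within the record, and the width statistic becomes a
  discontinuous function of the model parameters. The adaptation gate
  (τ = 2 ms) guarantees that every AP repolarises in-record and turns the
  toxin effect into a smooth, graded widening;
* two Ca²⁺ influx pathways, recorded diagnostically (they are small and
  are not fed back into the voltage equation): a high-voltage-activated
  VGCC conductance whose density falls linearly with distance from the
  soma, and a Ca²⁺-permeable fraction of the Na_v flux that is negligible
  proximally and rises into the distal AIS. The VGCC carries a fast
  inactivation gate whose time constant shortens further at spike-top
  voltages, so its integrated Ca²⁺ charge is dominated by the spike
  upstroke and is nearly insensitive to the late AP widening — this is
  what reproduces the observed dissociation (toxin-induced Ca²⁺ gain in
  the distal but not the proximal AIS).

The toxin enters exactly as in the voltage-clamp model: conductance is
partitioned by Hill occupancy into a free pool and a bound pool whose
inactivation gate relaxes `slowdown`-fold more slowly and whose effective
inactivation has the floor `persistent_frac`.

The stimulus is a somatic current pulse, default 2.5 nA for 3 ms starting
at 0.5 ms, in an 8 ms record — strong and brief so the AP time jitter is
minimal and single trials can be averaged directly. (Published protocol
descriptions give the pulse duration as 2–3 ms in one place and 3–4 ms in
another; 3 ms is used here.) Records are integrated with the fixed-step
classical 4th-order Runge–Kutta scheme of `deSolve::rk4()` at 100 kHz and
downsampled to 20 kHz; the integration is noise-free and bit-for-bit
reproducible.

**Calibration.** The free constants (densities, capacitances, gate
midpoints) were fixed once so that the control (no-toxin) simulation
reproduces the measured operating point of layer-5 pyramidal neurons: AP
width — the total time above −30 mV — between 0.7 and 1.4 ms at the soma
and between 0.45 and 1 ms in the AIS, somatic and AIS AP amplitudes
comparable (the premise of the optical normalisation step), and full
repolarisation within the 8 ms record. With the default toxin model for
local slice delivery (EC50 30 nM, Hill 1.5, slowdown 2.4, persistent
fraction 0.15) a 7 nM application gives a soma width change of roughly
+8%, an AIS width change of roughly +35%, a Na⁺ peak-transient gain of
~+20%, and a Ca²⁺ gain of ~+22% distally but ~0% proximally. The EC50 for
local delivery in tissue is far above the sub-nanomolar potency seen in
expression systems; tissue experiments report an equivalent-concentration
shift of more than an order of magnitude for locally delivered toxin, and
the default encodes that.

# The fluorescence forward model

`render_fluorescence()` maps any noise-free ground-truth trace to raw
camera counts:

$$ F(t) = F_0\, B(t)\,\left(1 + \frac{g\,s(t)}{F_0}\right) + \epsilon(t),
   \qquad B(t) = 1 - \textstyle\sum_i a_i + \sum_i a_i e^{-t/\tau_i} $$

with multi-exponential photobleaching $B$ (equal to 1 at the start of the
record), gain $g$, and i.i.d. Gaussian camera noise $\epsilon$. Each call
also renders matching signal-free ("dark") trials — bleaching and noise
only — which are exactly what the bleach-correction step fits in real
experiments. All randomness flows from the single integer seed of the
forward model; the biophysical simulation itself is deterministic.
Resampling from the simulation rate to the camera frame rate is by block
averaging, and a frame rate above the simulation rate is an error rather
than an interpolation.

Default gains and noise were chosen once to give realistic averaged-trace
signal-to-noise for the three indicators (voltage dye ΔF/F₀ ≈ 10%, Na⁺
indicator ≈ 5%, Ca²⁺ indicator ≈ 3–35% depending on ROI, camera noise at
~0.15% of baseline counts).

# Preprocessing

* **ROI extraction** averages pixels whose axial coordinate falls in a
  half-open interval `[a, b)` µm from the soma edge; half-open so adjacent
  ROIs never share pixels. Presets: mid = [10, 30), proximal = [5, 15),
  distal = [30, 40).
* **Trial averaging** is a pointwise mean of 4–7 trials. When somatic
  electrode traces accompany the trials, trials whose somatic AP peak time
  deviates by more than 0.1 ms or whose peak V_m deviates by more than
  2 mV from the first trial are excluded (with a warning carrying the
  indices). The criterion quantifies the qualitative requirement of an
  "identical somatic response"; the tolerances are the time of one to two
  camera frames and the amplitude noise of a whole-cell recording.
* **Bleach correction** fits `offset + Σ aᵢ·exp(−t/τᵢ)` (1–3 exponentials,
  Levenberg–Marquardt with a multi-start over log-spaced time constants)
  to the mean of the dark trials, then divides the signal trials by the
  fitted curve normalised to 1 at the first sample — so correction changes
  shape, never the initial level, and correcting then re-multiplying is an
  exact round trip.
* **ΔF/F₀** uses a baseline window, by default the first 1 ms of the
  record (and always ending before the stimulus onset in the pipeline);
  the window mean is F₀ and the output is (F − F₀)/F₀. A window mean is
  used rather than literally the first frame: it is the same estimator at
  window length one frame, and less noisy otherwise. Output over the
  baseline window has exactly zero mean by construction.
* **Optical AP normalisation** maps the dye waveform affinely so its
  baseline equals the somatic electrode baseline and its peak equals the
  somatic peak — valid because AIS and somatic AP amplitudes are
  comparable. The result is invariant to any positive affine transform of
  the optical input, which the tests verify directly. An optical trace
  whose peak is not at least 5 baseline-SDs above baseline is rejected.
* **Bridge/junction correction** subtracts `R_bridge · I_inj(t)` using the
  recorded injected current, and an 11 mV liquid-junction offset.
* **Na⁺ calibration** is a user-supplied linear factor (mM per unit
  ΔF/F₀). The full calibration procedure for the Na⁺ indicator is
  described elsewhere in the literature; within the indicator's linear
  operating regime it reduces to this one factor.

# Transient model fitting and current estimation

Cumulative ion influx reported by a low-affinity indicator is monotone and
step-like. Two model families are fitted by bounded nonlinear least
squares (`minpack.lm`, trust-region Levenberg–Marquardt; amplitudes ≥ 0,
τ ∈ [0.02, 5] ms, half-rise times inside the window; 8 Latin-hypercube
multi-starts from a fixed seed plus one data-driven start; best residual
wins, so the fit is deterministic given the seed):

* Na⁺: a **sum of logistic sigmoids** Σᵢ aᵢ σ((t − tᵢ)/τᵢ), non-decreasing
  because aᵢ ≥ 0. The number of components is configurable; the automatic
  rule fits n = 1, 2, … and keeps the smallest n whose residual RMS
  improves on n−1 by less than 5%.
* Ca²⁺: a **product of four rising sigmoids** A·∏ᵢσ((t − tᵢ)/τᵢ), values
  in [0, A]. The individual factors are generally non-identifiable; the
  fitted curve, not its parameters, is the result, and the tests check at
  curve level. Rising-only sigmoids are an interpretation — the product
  form is stated in the literature without orientation — chosen so the
  model is a monotone cumulative-influx curve like the Na⁺ model.

The logistic was chosen as the sigmoid family for its closed-form
derivative. The **ionic current estimate is the analytic time-derivative
of the fitted model**, evaluated on the acquisition grid — never a finite
difference of the raw data; a noise-free derivative is the entire point of
fitting a model function. For a single logistic component the derivative
peaks at exactly a/(4τ) at t = t_half, and for any fit the integral of the
derivative over the window equals the fitted influx increment (fundamental
theorem of calculus), both of which the tests assert. Current traces are
produced for shape comparison and display; quantitative endpoints use the
transient maxima, not the currents.

# Metrics and statistics

* **AP amplitude** is baseline-to-peak; **AP width** is the total time
  above −30 mV, crossings interpolated linearly, multiple supra-threshold
  intervals summed (the "total duration" reading of the threshold
  definition).
* **Peak-transient change** compares condition maxima, taken from the
  fitted model curves when fits are supplied (noise-robust) and from the
  averaged traces otherwise; the choice is recorded in the result.
* **Paired statistics**: two-sided paired t-test with significance at
  p < 0.01, the convention for these small (8–9 cell) cohorts; no
  multiple-testing correction beyond that single threshold, matching the
  original analysis style.

# The synthetic cohort pipeline

`run_pipeline()` chains everything: per cell, it simulates control and
toxin conditions (per-cell log-normal jitter of channel densities, 6%
relative SD, and a pulse amplitude drawn uniformly from 2–3 nA; all
per-cell seeds derived deterministically from the master seed), renders
4–7 fluorescence trials per indicator, preprocesses, fits, and computes
per-cell percent changes; across the cohort it runs the paired tests. The
default cohort is 9 cells, the typical size of these paired imaging
experiments. A manifest (config hash, seeds, versions) makes any bundle
reproducible: identical configurations produce byte-identical CSV tables.

Problem sizes were chosen so a full default run (9 cells × 2 conditions ×
3 indicators, plus all fits) completes in well under a minute on one CPU,
and the whole test suite in a couple of minutes.

# What the generator does and does not emulate

The simulator reproduces the *structure* the analysis assumes: control AP
width ranges at soma and AIS, comparable somatic/AIS amplitudes,
toxin-graded slowing of inactivation with a persistent component,
distally-dominant Na_v-mediated Ca²⁺ entry versus proximal VGCC entry,
multi-exponential bleaching, camera noise, and trial-to-trial variability.
Passing tests therefore show that the analysis chain recovers known ground
truth under those structural assumptions.

It does **not** emulate: quantitative Na_v1.2/Na_v1.6 gating differences,
stochastic channel gating, temperature effects, dye phototoxicity or
motion artifacts, imaging point-spread blur between ROIs, or the
amplitude of the real Na⁺ influx increase (the minimal two-gate model
saturates near +20% where tissue recordings report substantially larger
late-influx gains; the orderings — Na⁺ gain exceeding Ca²⁺ gain, distal
exceeding proximal, AIS widening exceeding somatic — are reproduced and
are what the validation asserts). Conclusions about real recordings should
rest on the method's behaviour, not on these synthetic effect sizes.

# Numerical choices and degenerate inputs

* Integration: fixed-step RK4 at 100 kHz; a non-finite state aborts with
  an explicit error rather than returning a truncated record.
* T50 on a trace that never decays from its peak is an error ("no
  inactivation"), as is a bleach curve that reaches zero inside the
  record, an F₀ ≤ 0, an optical AP indistinguishable from baseline noise,
  and paired differences with zero variance.
* Width of a subthreshold trace is 0, not an error.
* Fits of all-zero traces return zero amplitudes with near-zero residuals.
* Optimiser ties are broken by lowest residual, then smallest component
  count.

# Known limitations

The channel model is phenomenological: two-gate HH-style kinetics with
fixed slopes, an equilibrium (not kinetic) toxin-binding model, and Ca²⁺
pathways that do not feed back on the voltage. The compartment chain has
no myelin, no nodes, and no dendrites; axial resistance is a single
constant. The bleaching model is trial-independent. These are the right
simplifications for validating an analysis pipeline, and the wrong ones
for making biophysical predictions about real neurons.
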