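---
title: "Methods: current-clamp simulation, feature extraction and I_h fitting with ihclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: current-clamp simulation, feature extraction and I_h fitting with ihclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ihclamp` reimplements, as a tested pipeline, the computational analysis
of CA1 pyramidal-neuron excitability in an age-dependent amyloidopathy
mouse model: a reduced passive + I_h biophysical neuron, current-clamp
feature extraction, simultaneous multi-trace parameter fitting, synthetic
cohort generation with known ground truth, per-group statistics, and
tree-ensemble classification of feature tables. This vignette documents
the model, the numerical choices, and the design decisions, in enough
detail that a reader can judge what the passing tests do and do not show.

## The biophysical model

The membrane carries a leak conductance and a hyperpolarization-activated
cation current (I_h, carried by HCN channels). In each compartment,

$$C_m \frac{dV}{dt} = -\frac{V - e_\mathrm{pas}}{R_m}
  - \bar g_h\, l\, (V - E_h) + \frac{I_\mathrm{inj} + I_\mathrm{hold}}{A},$$

with a single first-order activation gate $l$ relaxing toward its
steady-state curve:

$$\frac{dl}{dt} = \frac{l_\infty(V) - l}{\tau_l(V)}, \qquad
l_\infty(V) = \frac{1}{1 + \exp\!\big({-(V - V_{l1/2})/k_l}\big)},$$

$$\tau_l(V) = \frac{\beta(V)}{q_t\, a_{0t}\, (1 + \alpha(V))}, \quad
\alpha = e^{c\,\zeta_t (V - V_{t1/2})}, \quad
\beta = e^{c\,\zeta_t \gamma_t (V - V_{t1/2})},$$

the thermodynamic rate formulation standard for this channel family. The
shape factor $k_l$ is negative: the channel opens with hyperpolarization,
and $l_\infty(V_{l1/2}) = 1/2$ exactly. Units are mV, ms, pA,
$\Omega\,\mathrm{cm}^2$, $\mu F/\mathrm{cm}^2$ and $S/\mathrm{cm}^2$
throughout.

Parameters the source model family fixes but the study tables do not
print, with our defaults (all configurable):

* $E_h = -30$ mV — conventional reversal for HCN currents.
* $C_m = 1\ \mu F/\mathrm{cm}^2$.
* $c = 0.0378\ \mathrm{mV}^{-1}$ ($\approx F/RT$ near 34 °C),
  $q_{10} = 4.5$ with reference temperature 33 °C; simulations run at
  34 °C.
* Single-compartment membrane area $A = 2.0\times10^{-4}\ \mathrm{cm}^2$,
  chosen so that the input resistance $R_m/A$ of the six packaged
  parameter sets falls in the physiological 100–200 MΩ range for CA1
  pyramidal neurons.

A ball-and-stick mode (`geom_ballstick()`) adds an unbranched dendrite
whose I_h density increases sigmoidally with distance from the soma
(defaults: 8-fold distal increase, half-distance 280 µm, steepness
50 µm), mirroring the dendritic gradient of the full-morphology model
this package reduces. The single compartment is the default and the
surface on which all quantitative checks run; the cable mode exists for
exploring the spatial gradient.

## Numerics

The integrator advances the voltage with a backward-Euler step (a
tridiagonal solve across compartments, which for one compartment reduces
to a scalar implicit update) and the gate exponentially against
$l_\infty$ and $\tau_l$ frozen at the step start. The scheme is
unconditionally stable; its accuracy contract is *grid refinement*, not
the particular update rule: halving the default step
$\Delta t = 0.025$ ms changes no voltage sample by more than 0.05 mV
(tested). Rate exponents are clamped at $|x| = 50$ so extreme voltages
cannot overflow. A sweep is declared an integration failure if $|V|$
exceeds 200 mV, and the error is reported with the sweep's amplitude —
never silently swallowed.

Holding currents are exact: with the gate at steady state at the holding
target, the bias current that clamps a single compartment at $-65$ mV
follows in closed form from the current balance; the pre-stimulus
baseline is therefore flat by construction. For the cable mode the bias
is found by root-finding on the settled somatic voltage. Steady-state
voltages used as test oracles are computed independently by root-finding
on the algebraic system with $l = l_\infty(V)$.

## Feature extraction

The extractor implements the standard current-clamp catalogue on
uniformly sampled sweeps:

* **RMP** — mean of an unstimulated baseline (≥ 100 ms); cells above
  −50 mV are flagged for exclusion.
* **Input resistance**, two estimators: Ohm's law on the holding current
  needed to reach −65 mV, and the least-squares slope of end-of-step
  deflection versus current over small negative steps. On linear model
  cells the two agree within 10% (tested); I_h rectification keeps the
  difference bounded.
* **Membrane time constant** — single-exponential least-squares fit
  $V(t) = V_{ss} + (V_{on} - V_{ss})e^{-(t-t_{on})/\tau}$ from stimulus
  onset to the voltage minimum (the sag peak). The two linear
  coefficients are profiled out and $\tau$ is optimized on (0.5, 200] ms;
  boundary hits return an explicit missing value with a diagnostic.
* **Sag** — steady-state voltage (mean of the last 10% of the step, a
  window choice the source analysis leaves open) minus the trace minimum,
  clipped at zero. The minimum is taken on a 2 ms boxcar-smoothed copy:
  the raw minimum of ~16,000 noisy samples is an extreme order statistic
  biased low by roughly four noise standard deviations, which at 0.2 mV
  noise would inflate every sag by ~0.8 mV. Smoothing reduces this bias
  to the few-hundredths level and leaves noiseless sweeps unchanged
  within tolerance.
* **Spikes** — one event per upward crossing of −10 mV (the detection
  threshold of the source analysis), timed at the local maximum.
* **First-AP shape** — onset at the start of the final run with
  $dV/dt \ge 20$ mV/ms before the peak (the onset criterion is not
  printed in the source; 20 mV/ms is the field's common choice and is
  configurable); amplitude = peak − onset voltage; width = full width at
  half height between onset voltage and peak with linear interpolation;
  maximal $dV/dt$ from centered differences. Phase-plane samples
  ($dV/dt$ vs $V$) are cut from a window around the first spike and are
  consistent with the AP features by construction.
* **Instantaneous frequency** — $f_i = 1000/\mathrm{ISI}_i$ for the first
  ten intervals at 300 pA, plus mean rate and an ISI adaptation index.

Missing features are explicit `NA`s, never zeros; imputation happens only
inside the classifier, per training fold. Extraction is pure: identical
sweeps give byte-identical tables.

## Parameter fitting

`fit_cell()` optimizes up to nine parameters
($R_m, e_\mathrm{pas}, \bar g_h, V_{l1/2}, k_l, V_{t1/2}, a_{0t},
\zeta_t, \gamma_t$) simultaneously against a family of hyperpolarizing
sweeps, replaying each reference stimulus with the candidate parameters
(holding current recomputed per candidate) and minimizing the pooled
voltage residual. The optimizer is seeded multi-start bounded
Levenberg–Marquardt on the residual vector; $R_m$, $\bar g_h$ and
$a_{0t}$ are fitted in log space. Box bounds span roughly a decade around
the published range for conductances and rates and ±30 mV for
half-voltages; the default start ensemble perturbs a neutral mid-range
initial model.

Two numerical facts shaped the design, both visible in the reported
start ensemble (the full ensemble is always returned, not just the
winner):

* **Kinetic degeneracy.** Over the sampled voltage range (about −95 to
  −65 mV) the activation curve never saturates, so a larger $\bar g_h$
  with a shifted/reshaped $l_\infty$ produces nearly the same current;
  the likelihood surface has a long, shallow valley. A scalar
  quasi-Newton optimizer stalls anywhere along it; Levenberg–Marquardt
  descends it reliably. The surface also has secondary basins (typically
  with the rate-slope parameters cornered at their bounds) whose
  boundaries shift with the noise realization, so start placement is
  staged: a pool of three candidates per reported start is triaged with
  short coarse-grid runs, the best-ranked points seed the deep
  optimizations on subsampled residuals (every 2nd sample), and the
  top-ranked results are re-polished against the full residual vector
  before the winner is chosen.
* **Deactivation information.** The post-stimulus rebound carries the
  I_h deactivation kinetics at the holding potential
  ($\tau_l(-65) \approx 50$ ms for the strong-amyloidopathy parameter
  set). Reference sweeps used for parameter-recovery runs therefore keep
  a 300 ms post-stimulus window, which pins the activation scale far
  better than a clipped tail.

Self-fits on noiseless references converge to machine-level residuals;
with 0.1 mV white noise the pooled RMS of every group fit settles at the
noise floor (≈ 0.1 mV, well below the 0.3 mV quality bound), and the
peak-conductance estimate typically lands within a few percent of the
generating value, with occasional excursions near ±10% that reflect the
information limit of three 400 ms sweeps at this noise level, not
optimizer failure (the from-truth optimum moves by the same amount).

## The synthetic cohort generator

The generator emulates the study's recording structure: six labelled
groups (wild-type and transgenic at three ages), group sizes
14/11/12/15/19/21, a −200…+400 pA protocol in 50 pA steps (13 sweeps; the
source text mentions 14 injections, which the arithmetic sequence cannot
produce — we keep the 13-step sequence and note the discrepancy), 400 ms
steps from a −65 mV holding baseline, plus one unclamped sweep per cell
for the resting potential.

**Between-cell variability.** Scale and shape parameters ($R_m$,
$\bar g_h$, $a_{0t}$, $\zeta_t$, $\gamma_t$, $k_l$, rheobase, f–I slope,
AP template dimensions) vary lognormally with a mean-corrected CV
(default 0.1). Voltage *locations* ($e_\mathrm{pas}$, $V_{l1/2}$,
$V_{t1/2}$) instead receive additive Gaussian jitter with a default SD of
2 mV: a multiplicative CV on a quantity measured in millivolts from an
arbitrary zero would mean ±8 mV swings of the activation midpoint —
larger than the entire wild-type/transgenic difference in the optimized
tables and far outside the few-millivolt spread seen across real cells.

**Spiking.** The subthreshold core is always the passive + I_h model.
For suprathreshold steps the inter-spike trajectory is the model's
response to an effective drive clamped at rheobase (ongoing spiking holds
the membrane near threshold), and an analytic AP template — linear rise,
exponential fall, built so its width at half height is exact — is spliced
at spike times scheduled deterministically from the cell's f–I law
(mean rate = slope × (I − rheobase), geometric ISI progression with
ratio $\mathrm{adapt}^{1/9}$). We deliberately schedule spike times
rather than let an integrate-and-fire threshold emit them: the layer
exists to give the extractor *exact* ground truth for spike count,
instantaneous frequencies and AP width, and emergent threshold crossings
would make those quantities uncontrollable. White Gaussian noise is added
last.

What the generator does **not** emulate: conductance-based AP dynamics
(AP shape carries no sodium/potassium channel information), correlated
or 1/f recording noise, electrode artifacts, plaque-proximity effects, or
within-cell nonstationarity. Passing closure tests therefore show that
the extractor recovers what the generator controls — they do not certify
performance on real recordings.

**Sag calibration.** `calibrate_sag()` adjusts a group's conductance
scale and, with two targets, $k_l$, so the group reproduces printed sag
means. Matching the printed strong-amyloidopathy-age wild-type values
(5.6 mV at −200 pA *and* 1.7 mV at −50 pA) requires a much larger
effective conductance with a steep activation switch
($k_l \approx -3$): the printed kinetics are too slow near −70 mV to
build 1.7 mV of sag on a −50 pA, 400 ms step at ~140 MΩ input
resistance. The calibrated group is thus an *effective* parameterization
that reproduces the measured sag phenotype in reduced geometry, not an
estimate of channel biophysics; calibration bounds
($k_l \in [-40, -2]$, scale ∈ [0.05, 400]) are set accordingly. When the
group has between-cell variability the calibrated quantity is the
*expected cohort-mean* sag, estimated on a fixed set of 12 seeded
parameter draws — sag is concave in the parameters, so calibrating the
mean-parameter cell would bias generated cohorts roughly 10% low.
Unattainable targets raise an error listing the achieved values (or a
warning in non-strict mode).

## Classification

`train_eval()` evaluates bagged trees (bootstrap aggregation with
majority vote; `randomForest` with `mtry` = all features, which is pure
bagging) and boosted trees (gradient-boosted shallow trees via
`xgboost`; 100 trees of depth 3, learning rate 0.1, exact split search
for determinism on small tables) under 10-fold cross-validation.
Hyperparameters are unprinted in the source and documented here as
package defaults. Accuracy comes from held-out predictions only; median
imputation is computed on training folds only; when a random split
leaves a class out of a training fold the data are refolded with
stratification (logged). The six-task battery (genotype within each age,
genotype pooled, age within each genotype) reports the better ensemble
per task with its chance level. The default classification unit is the
per-cell feature row; the published analysis classified traces, and a
per-sweep table can be assembled by extracting single-sweep cells. The
published accuracies on real recordings (69–85%) are not reproducible
without the raw data; the classifier is instead property-tested
(perfect separation, permutation null at chance, separable synthetic
cohorts above chance, indistinguishable specs at chance).

## Group statistics

`compare_groups()` mirrors the published testing scheme: Shapiro–Wilk
normality per group at α = 0.05 routes to a two-sided equal-variance
t-test (Welch optional) or a Mann–Whitney rank-sum test; each age is
tested independently; no multiple-comparison correction is applied, by
design, matching the source analysis. The routing rule's type-I error is
calibrated (rejection rate within [0.03, 0.07] at α = 0.05 over 1000
null features, mixed normal and lognormal, at cohort-like group sizes).

## Known limitations

* **The ~20% time-constant modulation is not reproduced by the reduced
  model.** Experimentally, the fitted membrane time constant is about
  20% faster at −200 pA than at −50 pA. Simulating the printed
  parameter sets in reduced geometry and fitting τ by the
  onset-to-sag-peak procedure yields essentially no speed-up (≈ 0% in the
  single compartment, slightly negative in ball-and-stick). The printed
  activation kinetics are simply too slow at the voltages these steps
  reach (τ_l ≈ 60–130 ms against a ~24 ms membrane time constant), so the
  gate barely moves inside the fit window; reproducing the experimental
  modulation would need several-fold faster kinetics at −90 mV or much
  deeper voltage excursions than a ~140 MΩ cell experiences. The
  pipeline computes and reports the honest value; the corresponding
  acceptance check fails and is documented rather than adjusted. Other
  subthreshold conductances absent from the model (e.g. inwardly
  rectifying potassium channels) are plausible contributors to the
  experimental effect.
* Recovered parameters are effective for the reduced geometry; absolute
  kinetic parameters inherit the degeneracy discussed above, which is why
  the start ensemble is part of every fit result.
* The generator's spiking layer is phenomenological (see above).

## Problem sizes used by the tests and the acceptance script

Unit tests run on sweeps at 0.05–0.1 ms sampling with small cohorts
(1–10 cells per group); closure properties are additionally checked over
50 seeded cells. The acceptance script fits all six groups (three
800 ms reference sweeps each at 0.025 ms sampling, 8 starts), calibrates
and generates a 19-cell cohort at full resolution, and evaluates the
τ-modulation and conductance-ratio quantities; these sizes were chosen so
the whole analysis reruns comfortably on a single CPU.
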