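# ihclamp

Current-clamp analysis of CA1 pyramidal neurons with a
hyperpolarization-activated current (I_h), for electrophysiologists and
modellers studying excitability changes in amyloidopathy mouse models.

Whole-cell current-clamp experiments in these studies inject 400 ms
current steps (−200 to +400 pA in 50 pA increments) from a −65 mV holding
baseline and read out passive properties (input resistance, resting
potential, membrane time constant), the I_h signature sag, first
action-potential shape, and firing statistics. `ihclamp` provides the
full computational side of that workflow:

* **Biophysical model** — a reduced (single-compartment or
  ball-and-stick) neuron with leak and I_h:

  `Cm dV/dt = −(V − e_pas)/Rm − ḡ_h·l·(V − E_h) + (I_inj + I_hold)/A`

  with first-order gate dynamics `dl/dt = (l∞(V) − l)/τ_l(V)`,
  `l∞(V) = 1/(1 + exp(−(V − V_l½)/k_l))` (k_l < 0: opens with
  hyperpolarization) and a thermodynamic time-constant law
  `τ_l = β/(q_t·a0t·(1 + α))`, `α = exp(c·ζ_t(V − V_t½))`,
  `β = exp(c·ζ_t·γ_t(V − V_t½))`, at 34 °C. Six optimized group
  parameter sets (wild-type / transgenic at 1, 3–4 and 9–10 months) ship
  with the package (`ih_group_params()`).
* **Feature extraction** — sag, membrane time constant fitted from
  stimulus onset to the sag peak, both input-resistance estimators, spike
  detection at −10 mV, first-AP width/amplitude/onset/max dV/dt,
  phase-plane samples, instantaneous frequencies from the first ten
  inter-spike intervals (`extract_feature_table()`).
* **Parameter fitting** — seeded multi-start Levenberg–Marquardt
  optimization of all passive and I_h parameters simultaneously against
  families of hyperpolarizing sweeps (`fit_cell()`, `fit_all_groups()`).
* **Synthetic cohorts** — labelled sweep sets with exact ground truth
  (spike times, AP width, sag, τ) for extractor validation and power
  studies, including calibration of group-mean sag to published values
  (`generate_cohort()`, `calibrate_sag()`).
* **Statistics & classification** — the per-feature, per-current
  WT-vs-AD testing scheme with normality-based routing
  (`run_comparison_grid()`), and bagged/boosted tree-ensemble
  classification of feature tables under 10-fold cross-validation
  (`train_eval()`, `run_classification_tasks()`).

## Worked example

```r
library(ihclamp)

# 1. simulate a current-clamp family for the 10-month wild-type parameter set
model <- cell_from_group("WT-10m")
sweeps <- run_protocol(model, amplitudes = c(-200, -100, -50), dt = 0.05)
sapply(sweeps, function(tr) c(sag_mV = round(as.numeric(measure_sag(tr)), 2),
                              tau_ms = round(fit_membrane_tau(tr), 1)))
#>         -200 -100   -50
#> sag_mV  4.31  1.7  0.68
#> tau_ms 21.70 22.5 22.90
```

The sag grows with hyperpolarization (4.3 mV at −200 pA vs 0.7 mV at
−50 pA) — the I_h fingerprint — while the fitted membrane time constant
stays near 22 ms.

```r
# 2. refit the model from its own noisy traces (parameter recovery)
set.seed(1)
refs <- lapply(c(-200, -100, -50), function(a) {
  tr <- simulate_step(model, stim_step(a, post = 300), dt = 0.05)
  tr$voltage <- tr$voltage + rnorm(length(tr$voltage), 0, 0.1)
  tr
})
fit_cell(refs, n_starts = 4, seed = 1, subsample = 4)
#> <ih_fit> pooled RMS 0.1005 mV (best of 4 starts, seed 1)
#>           Rm        e_pas         gbar      Vl_half           kl      Vt_half
#> 28202.228416   -60.000000     0.000016   -80.908599   -10.029558   -66.060412
#>          a0t        zetat          gmt
#>     0.003605     2.347534     0.231815
```

The pooled error sits at the 0.1 mV noise floor and the peak conductance
is recovered within ~3% (1.6e-5 vs 1.55e-5 S/cm²). The leak reversal is
weakly identified from clamped sweeps (the fit report carries the full
start ensemble so such degeneracies stay visible; see the methods
vignette).

```r
# 3. a small synthetic two-group cohort, extracted and classified
groups <- default_group_specs(n_cells = c(1,1,1,1,8,8))[c("WT-10m", "AD-10m")]
cohort <- generate_cohort(cohort_spec(groups, amplitudes = c(-200, -50, 300),
                                      dt = 0.05, seed = 42))
ft <- extract_feature_table(cohort$cells)
train_eval(ft, split_group_label(ft$group_label)$genotype,
           kind = "bagged", folds = 4, seed = 1)
#> <class_report> bagged trees, 4-fold CV: accuracy 1.000

run_comparison_grid(ft, features = c("sag_mv_m200", "ap_width_ms_p300"))[,
    c("feature", "age", "test", "p_value", "significant")]
#>            feature age test      p_value significant
#> 1      sag_mv_m200 10m    t 4.872210e-02        TRUE
#> 2 ap_width_ms_p300 10m    t 1.819163e-05        TRUE
```

The two groups differ in sag and AP width by construction; both the
classifier and the comparison grid pick that up from the extracted
features alone.

A command-line wrapper over the same functions is installed at
`exec/ihclamp` (subcommands `simulate`, `make-cohort`, `extract`, `fit`,
`classify`, `compare`, `report`), or callable as `ihclamp_cli()`.

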