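# bedsweep

Radiobiological threshold analysis for **radiation-induced peritumoral brain
edema (PTBE)** after stereotactic radiotherapy of intracranial meningioma.

PTBE is the most frequent toxicity of meningioma radiotherapy, but treatment
schemes range from single-fraction radiosurgery to ten-fraction courses, so
physical dose is not comparable across patients. The linear–quadratic model
puts schemes on a common scale via the biologically effective dose

```
BED = n · d · (1 + d / (α/β))
```

with `n` fractions of `d` Gy and tissue ratio `α/β` (Gy). Tumor control in
meningioma is modelled with α/β ≈ 2–4, but edema is a normal-tissue vascular
response whose effective α/β may be far higher — and the choice directly
changes which prescriptions cross a toxicity threshold. `bedsweep` answers
the question empirically for any cohort:

* **BED engine** — `compute_bed()`, `isoeffective_dose_per_fraction()`
  (exact closed-form inversion), `bed_matrix()` over an α/β grid.
* **Threshold machinery** — `empirical_roc()`, `roc_auc()` (= Mann–Whitney
  concordance), `auc_pvalue()`, `corner_optimal()` (closest-to-(0,1)
  cutoff), `youden_j()`, `sweep_alpha_beta()` across the grid,
  `select_best_alpha_beta()` (highest Youden's J, with a joint
  cohort + subgroup rule).
* **Survival analysis from first principles** — `km_estimate()`,
  `logrank_test()`, `cox_fit()` (Newton–Raphson, Breslow/Efron ties, with
  broom-style `tidy()`/`glance()`), `vif()`, `one_way_anova()`.
* **Synthetic cohorts** — `synthetic_config()` / `generate_cohort()`
  emulate a published 67-tumor registry (23.9% PTBE, dose 27.2 ± 4.4 Gy,
  age 68.1 ± 11.4 y, PTV 9.9 ± 14.6 cc) with proportional-hazards PTBE risk
  driven by BED at a configurable true α/β; `recovery_experiment()`
  validates that the sweep recovers that ratio end to end.
* **Pipeline** — `read_cohort()`/`write_cohort()` (validated CSV schema),
  `run_report()`/`write_report()` for the full analysis suite, `autoplot()`
  methods for ROC curves, sweeps, Kaplan–Meier curves and Cox fits, and a
  thin CLI (`inst/cli/bedsweep`) with `simulate`, `bed`, `sweep`,
  `survival` and `report` subcommands.

## Worked example

```r
library(bedsweep)

co <- generate_cohort(synthetic_config(), seed = 42)   # 67 tumors
sum(co$ptbe_event)
#> [1] 15

sw <- sweep_alpha_beta(co)
dplyr::select(sw, alpha_beta, auc, p_value, optimal_bed_gy,
              youden_j, dose_fx_1, dose_fx_5)[c(1, 9, 13, 19), ]
#>   alpha_beta   auc p_value optimal_bed_gy youden_j dose_fx_1 dose_fx_5
#> 1          2 0.672  0.0438          162.3    0.340      17.0      7.12
#> 2         10 0.676  0.0393           53.2    0.406      18.6      6.47
#> 3         14 0.685  0.0303           45.9    0.387      19.3      6.33
#> 4         20 0.690  0.0260           40.5    0.368      20.2      6.18
```

Each row re-scores the cohort's BED at one α/β ratio, builds the empirical
ROC against the PTBE outcome, and reports the cutoff closest to the
(sens, spec) = (1, 1) corner; `dose_fx_1`/`dose_fx_5` translate that BED
cutoff back into a single-fraction dose and a five-fraction dose per
fraction. At a cohort size of 67 with ~15 events the selected ratio is
noisy by nature; `recovery_experiment()` shows the selection concentrating
around the generating ratio as cohorts grow.

Translating a published cutoff into prescriptions:

```r
isoeffective_dose_per_fraction(40.595, c(1, 5), 14)
#> [1] 17.846126  5.754058
```

i.e. a BED threshold of 40.595 Gy at α/β = 14 corresponds to staying at or
below 17.85 Gy in a single fraction, or 5.75 Gy per fraction over five.

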