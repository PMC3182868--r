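# il21pkpd

Integrated disease/pharmacokinetic/pharmacodynamic (PK/PD) modeling of
systemic interleukin-21 (IL-21) immunotherapy in murine solid tumors (B16
melanoma, RenCa renal carcinoma), built as a tested simulation-and-
calibration pipeline. It is aimed at quantitative pharmacologists and
systems biologists who want to reproduce, probe, or extend regimen-design
analyses for cytokine immunotherapy: which therapy onset, dose level, and
dose fractionation of a fixed total IL-21 budget best suppress tumor
growth.

## The model

**Pharmacokinetics.** Drug amounts `x_i` (µg) move through a
semi-physiological compartment graph — 4 compartments for IV dosing
(plasma exchanging with three secondary tissues), 8 for SC/IP (an
administration-site depot feeding plasma through up to three absorption
compartments, plus the same secondary tissues). Transition and degradation
are saturable:

    J_ij = w · x_i / (1 + α x_i)        (transition, 1/day, saturation α)
    D_i  = d · x_i / (1 + β x_i)        (degradation)

with linear transport recovered as α→0. Plasma concentration is `x₀/V`
(V = 2 ml), and the target-tissue concentration is a route-specific
fraction of it, `u = x₀/(V·s)` with `s ∈ [1, 100]`.

**Pharmacodynamics and disease.** In the target tissue, IL-21 inhibits NK
survival and promotes CTL expansion through a drug-induced memory factor,
while raising the per-cell cytotoxic-protein stores (`p_N`, `p_C`) of both
effectors. The tumor grows logistically and is killed by additive mass
action:

    dT/dt = r·T·(1 − T/K) − (k₁·N·p_N + k₂·C·p_C)·T

with CTL dominance `k₂ = 10·k₁` in the calibrated configuration, and a CTL
ceiling set by `σ` and `D_max`. All drug effects are Michaelis-type
saturable terms in `u`. Cell numbers scale to volume as 10⁶ cells = 1 mm³;
tumors are inoculated at 10⁵ cells on day 0.

**Machinery.** Fixed-step fourth-order Runge–Kutta with bolus dose events
snapped to the step grid (compiled core); Hooke–Jeeves pattern search with
seeded Latin-hypercube multi-starts (10-set ensembles) and a
prediction-consistency acceptance rule; a four-stage sequential calibration
protocol (PK per route → effector affinities from neutralized arms →
logistic growth from PBS controls → route-specific `s`); and a seeded
virtual-cohort generator (measurement noise, animal-level growth
heterogeneity, euthanasia censoring at 1000 mm³) so the whole pipeline is
testable with no external data.

## Worked example

Compare the standard early-onset course (16 × 50 µg SC daily from day 3,
800 µg total) with its twice-daily fractionation:

```r
library(il21pkpd)
model <- default_model("B16-early")

std  <- regimen("SC", 50, onset_day = 3, interval_days = 1,   n_doses = 16)
frac <- regimen("SC", 25, onset_day = 3, interval_days = 0.5, n_doses = 32)

v_std  <- trajectory_at(simulate_therapy(std,  model$pk$SC, model$pd), 20)
v_frac <- trajectory_at(simulate_therapy(frac, model$pk$SC, model$pd), 20)
c(standard = v_std, fractionated = v_frac,
  pct_reduction = endpoint_ratio(v_frac, v_std))
#>      standard  fractionated pct_reduction
#>      725.1914      410.2707      43.42588
```

Splitting the same 800 µg into 25 µg every 12 h ends therapy (day 20) with
a 43% lower tumor volume than the daily 50 µg standard; the PBS control
reaches 1781 mm³ by the same day. The full scans behind this comparison
live in `analysis/`:

| script | what it does |
| --- | --- |
| `analysis/01_pk_profiles.R` | single-dose serum PK per route + synthetic PK training profiles |
| `analysis/02_virtual_cohorts.R` | the full virtual-cohort training/validation bundle |
| `analysis/03_calibration.R` | sequential calibration on a 5%-noise bundle, recovery + held-out R² |
| `analysis/04_regimen_scans.R` | onset, fractionation, and dose-titration scans |

Each writes its tables under `results/`. On the default preset the onset
scan finds a day-1 start ending 56% below the day-3 standard and a day-10
delay 2.2-fold worse, and the dose titration shows similar outcomes across
the 5–50 µg/day range with clear dose dependence outside it.

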