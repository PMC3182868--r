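---
title: "Methods: the IL-21 disease/PK/PD model, its calibration, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the IL-21 disease/PK/PD model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(il21pkpd)
```

This vignette is the package's account of its science: the model equations
and their assumptions, the parameters that matter and how their defaults
were chosen, what the synthetic-data generator does and does not emulate,
the estimation protocol and its numerical choices, and the known
limitations.

## 1. Model structure

### Pharmacokinetics

Drug amounts $x_i$ (µg) live on a compartment graph: for IV dosing, plasma
plus three secondary tissues exchanging bidirectionally with plasma; for
SC/IP dosing, an administration-site depot connected to plasma through a
chain of three absorption compartments plus a direct depot→plasma shortcut,
with the same secondary tissues on the elimination side. The wiring is
data, not code: `pk_topology()` accepts any transition set, including
non-sequential, multi-directional absorption wiring, provided every
compartment is reachable from the dosed one.

Transition and degradation follow Michaelis–Menten-type saturable kinetics,

$$J_{i\to j} = \frac{w\,x_i}{1+\alpha x_i}, \qquad
  D_i = \frac{d\,x_i}{1+\beta x_i},$$

which reduce to linear first-order transport for $\alpha\to 0$ and saturate
at $w/\alpha$ for large amounts. Forward flow depends on the source amount
only; bidirectional exchange is modeled as two enabled transitions. This is
the simplest form consistent with (a) reduction to linear transport for
negligible $\alpha$ and (b) saturation levels governed by $\alpha,\beta$;
it is implemented as a single pluggable function (`transition_rate()`,
`degradation_rate()`), so an alternative algebraic form can replace it
without touching the solver.

Plasma concentration is $x_0/V$ with $V = 2$ ml. Tissue drug concentration
is correlated with plasma as $u = x_0/(V s)$ with the route-specific factor
$s \in [1, 100]$ (blood:tissue concentration ratios of that order are the
physiologically plausible range). The divisive form keeps tissue levels at
or below plasma levels across the whole admissible range of $s$. The
coupling is read-only: no drug mass leaves the system through it, and total
injected dose always equals drug on board plus the cumulative degraded
amount (tracked as an explicit accumulator state; see the mass-balance
tests).

### Pharmacodynamics and disease

Six tissue states: NK cells $N$, CTLs $C$, per-cell cytotoxic-protein
levels $p_N, p_C$, a memory factor $M$, and tumor cells $T$:

$$\begin{aligned}
\dot N &= a_N - \mu_N N - i_N \tfrac{u}{K_N+u}\,N \\
\dot M &= q_M \tfrac{u}{K_M+u} - \mu_M M \\
\dot C &= \sigma M C\,(1 - C/D_{\max}) - \mu_C C \\
\dot p_N &= h_N \tfrac{u}{K_{uN}+u} - \mu_{pN}\,p_N
  \qquad (\text{and likewise } p_C)\\
\dot T &= r\,T(1-T/K) - (k_1 N p_N + k_2 C p_C)\,T.
\end{aligned}$$

The structure encodes the qualitative pharmacology: IL-21 *inhibits NK
survival* (a saturable addition to the NK death rate) while *promoting CTL
expansion* through drug-induced memory, bounded by a ceiling set jointly by
$\sigma$ (expansion intensity) and $D_{\max}$ (maximal CTL numbers); both
effectors' cytotoxic-protein stores rise saturably with drug and decay
within hours; killing is additive mass action weighted by those stores.
All drug effects use Michaelis-type terms in $u$ for consistency with the
PK side, each with its own half-saturation constant. With $\sigma$ and
$D_{\max}$ the ceiling works out to
$C_{ss} = D_{\max}\,(1-\mu_C/(\sigma M_{ss}))$: $D_{\max}$ bounds it,
$\sigma$ sets how closely and quickly it is approached.

At $u \equiv 0$ with $M(0)=0$ the immune states sit at a drug-free steady
state ($N = a_N/\mu_N$, proteins 0) in which the kill term vanishes, so the
untreated tumor follows the scalar logistic solution exactly — this gives
the package an analytic oracle for its integrator. Initial conditions:
baseline immune states, a 10-cell CTL seed so expansion is possible, and
$T(0) = 10^5$ cells at day 0 (the inoculum).

Neutralization experiments map onto the affinities: a T-cell-neutralized
arm is simulated with $k_2 = 0$, an NK-neutralized arm with $k_1 = 0$. The
calibrated-style configuration is CTL-dominant, $k_2 = 10k_1$; an
"equal effector balance" configuration ($k_1=k_2$) is retained as a switch
(`default_pd_params(..., equal_balance = TRUE)`) for sensitivity analyses.

## 2. Default parameter values

The reference parameter tables of the original study are not available in
machine-readable form, so the package ships its own default preset:
plausible-range values fixed once, chosen so that the preset sits in the
qualitative regime the biology dictates, and documented here. They are the
ground truth of the synthetic-data module and the preset on which the
regimen scans run; they are not a fit to any experimental dataset.

* **PK** (per route): plasma elimination fast (half-life well under two
  hours), SC/IP absorption over a few hours through the depot chain,
  modest tissue redistribution so the terminal tail is steep (the drug is
  essentially gone between daily doses). IP absorption is near-linear
  (small α), SC carries mild transition saturation, and some degradation
  steps saturate (large β). $s_{SC} = 40$, $s_{IP} = 12$ — distinct by
  route, both mid-range.
* **Tumor growth**: B16-early $r = 0.6$/day, $K = 2\times10^9$ cells
  (2000 mm³), which takes a PBS control from the 10⁵-cell inoculum past the
  1000 mm³ euthanasia threshold around day 17. Separate growth values per
  tumor type and therapy-onset preset (`default_pd_params()`).
* **Immunity** (shared across tumor types): tissue NK pool $10^6$ cells
  with drug-induced suppression up to several-fold; memory-driven CTL
  expansion fast enough to reach its ceiling within ~1–2 weeks of daily
  dosing; protein turnover $\mu_p = 4$/day (half-life ~4 h), which is what
  makes dosing *frequency* matter. $\sigma, D_{\max}$ are
  tumor-type-specific (B16 non-immunogenic: $5\times10^5$; RenCa
  moderately immunogenic: $10^6$). Half-saturation constants sit at
  tissue-concentration scales reached by a few-µg dose, so the 5–50 µg/day
  range operates in the saturated regime — this produces both the
  mid-range dose plateau and the fractionation benefit (smaller, more
  frequent doses keep the saturable effects and the short-lived proteins
  topped up instead of wasting exposure above saturation).
* **Killing**: $k_1 = 5\times10^{-8}$, $k_2 = 10 k_1$, scaled so the
  standard course roughly halves to one-third the day-20 burden relative
  to control without ever eradicating the tumor.

On this preset the package's scans show: fractionating the 800 µg course
into 25 µg every 12 h ends ~43% below the daily standard, with clearly
diminishing returns beyond 12 h; a day-1 onset outperforms day 3, and a
day-10 delay roughly doubles the endpoint burden; daily doses of
5–50 µg/day give similar outcomes while response is clearly dose-dependent
outside that range. These are properties of the preset regime, recomputed
(never hard-coded) by the tests and the acceptance script.

## 3. The synthetic study design

`make_training_bundle()` emulates the study's data classes from known
ground truth:

* **PK training profiles**: one 50 µg bolus per route, sampled at 10 time
  points over 3 days, n = 6 virtual mice, proportional measurement noise
  (default CV 10%).
* **Tumor cohorts**: measurement ~3×/week (default days
  3, 6, 8, 10, 13, 15, 17, 20), n = 8 mice, 10% proportional measurement
  CV plus an animal-level lognormal growth-rate multiplier (CV 15%);
  an animal is euthanized — and censored from all later cohort
  means/SEMs — once its measured volume reaches 1000 mm³. Arms: PBS
  control, T-cell-neutralized ($k_2=0$) and NK-neutralized ($k_1=0$)
  treated arms, early-onset treated SC and IP arms (training), plus
  fractionated, low-dose, and late-onset arms (held-out validation).
* Everything is a pure function of (specification, ground truth, seed);
  the bundle manifest records all seeds and regenerates the bundle
  identically.

The animal-level noise magnitudes are generator choices: cohort figures
report only means±SEM, so per-animal spread is not recoverable from any
published source. For parameter-recovery exercises the bundle is generated
at 5% *measurement* noise with the animal-level heterogeneity switched off
— "proportional noise" is read as the measurement noise model; the
heterogeneity multiplier is a distinct, correlated perturbation that
shifts each arm's realized growth rate and would confound a recovery
benchmark. What passing recovery tests show is therefore internal
consistency of the estimation machinery under honest sampling noise — not
robustness to model misspecification, assay artifacts (there is no LLOQ),
or real inter-animal biology.

## 4. Calibration protocol

Stages, each a 10-set Hooke–Jeeves ensemble from seeded Latin-hypercube
starts, freezing its best set for later stages:

1. **PK per route** against the single-dose serum profiles, over
   $(\log_{10} w, \alpha, \log_{10} d, \beta)$ with bounds
   $w, d \in [0.1, 100]$/day, $\alpha \in [0, 0.15]$/µg,
   $\beta \in [0, 1]$/µg.
2. **Affinities**: $k_1$ on the T-cell-neutralized arm (with $k_2 = 0$
   enforced), then $k_2$ on the NK-neutralized arm ($k_1 = 0$), on
   $\log_{10} k \in [-10, -4.5]$.
3. **Growth** $(r, K)$ on the PBS control via the analytic logistic
   solution. Because this stage touches no drug parameter, it is computed
   up front and its result frozen for stage 2, which needs a full disease
   model to simulate the treated neutralized arms; results are reported in
   protocol order.
4. **Tissue factor** $s$ per route, constrained to $[1, 100]$
   ($\log_{10} s \in [0, 2]$).

Three protocol details deserve justification:

* **Provisional s and the joint stage 4.** Stage 2 needs a tissue
  concentration before $s$ exists; it runs at the geometric centre of the
  admissible range ($s = 10$). A pure one-dimensional $s$ fit afterwards
  inherits whatever bias that provisional value put into $k_1, k_2$, and
  the three parameters are nearly ridge-coupled (scaling $s$ can largely
  be absorbed by rescaled affinities). Stage 4 therefore estimates
  $s_{SC}$ *jointly* with a re-conditioning of $k_1, k_2$ — confined to
  one decade around their stage-2 values — over all three SC training
  arms, with each arm's neutralization constraint enforced inside its own
  simulation; $s_{IP}$ is then fitted one-dimensionally at the final
  affinities. In recovery experiments the alternating variant drifts along
  the ridge to the bounds of $s$, while the joint step recovers the
  generating values.
* **Weighted residuals.** All stages minimize 1/SEM²-weighted squared
  residuals (a config switch restores unweighted raw-scale least squares,
  which remains the `sse_objective()` default). Tumor curves span four
  orders of magnitude and serum concentrations five; unweighted residuals
  reduce every fit to its largest few points and leave the early,
  shape-informative measurements — which carry essentially all the
  information about $s$ and the drug-effect timing — without influence.
  Each SEM is floored at a fraction of the arm's maximum (2×10⁻⁴ for
  tumor curves, 10⁻³ of Cmax for PK) so that near-zero observations cannot
  dominate either.
* **Saturation sparsity in stage 1.** A single-dose profile cannot
  identify the saturation constants: strongly nonlinear parameter sets fit
  the 50 µg curve to the noise floor yet diverge several-fold in exposure
  at other doses, which wrecks any dose-extrapolating prediction. The
  stage-1 objective therefore adds a mild linear penalty on
  $\sum\alpha$ and $\sum\beta$, admitting nonlinearity only where it buys
  a commensurate drop in misfit — mirroring the observation that only
  some transport steps require nonlinear kinetics.

**Ensemble acceptance.** Following the multiple-modeling principle, all 10
sets of each stage are retained, and `prediction_consistency()` scores the
maximal pairwise relative deviation of their predictions across probe
scenarios; an ensemble is accepted when the score stays within 10%
(configurable — the "unified predictions" criterion has no published
numerical value). The relative deviation uses a denominator floor (default
1 mm³) so that near-zero early volumes cannot inflate the score.
`compare_structures()` applies the same machinery across alternative PK
topologies, ranking accepted structures by misfit and breaking near-ties
(SSE within 5%) toward fewer compartments.

## 5. Numerical choices

* **Integrator**: fixed-step classical RK4 on the joint PK(+accumulator)+PD
  state, default `dt = 0.002` day; halving the step changes the day-20
  volume by <0.1%, and the logistic benchmark shows clean fourth-order
  convergence. Bolus events are snapped to the nearest step and applied as
  instantaneous amount increments before the step. Fitting loops use
  `dt = 0.01` day (tumor) and `dt = 0.002` (PK profiles, whose absorption
  phase is steep); an automatic stability bound shrinks the step when a
  parameter draw makes the linear-regime outflow stiff, and drug amounts
  below −10⁻⁶ µg abort with advice to reduce the step.
* **Optimizer**: exploratory coordinate moves with step halving on
  failure, pattern (extrapolation) moves chained while they make material
  progress (a relative improvement floor of 10⁻¹² prevents
  machine-precision Zeno loops), hard box constraints by clamping, and
  termination when all steps fall below the tolerance or the evaluation
  budget is exhausted. A failed simulation maps to a large finite penalty
  so the search can route around unstable corners.
* **Problem sizes**: the test suite runs reduced ensembles (3–5 sets,
  3 bundle replicates) for the routine checks and the full 10-set protocol
  once in the acceptance suite; the structure-comparison and recovery
  examples use 8–10 sampled time points per arm, matching the ~3×/week
  caliper schedule.
* **Degenerate inputs**: PBS controls are regimens with zero doses; zero
  observed variance makes R² an error rather than a silent NaN; cohorts in
  which censoring removes nearly all animals before the second measurement
  warn; the euthanasia threshold is enforced only by the cohort generator,
  never during pure simulation (the model tracks the mean trajectory).

## 6. Endpoint conventions

The fractionation and dose scans share a fixed endpoint (day 20, end of
the early-onset therapy window). The onset scan keeps dose, interval, and
therapy duration fixed and reads each regimen's outcome at the end of its
own therapy window (onset + 17 days, mirroring the day-3 course measured
at day 20); delayed courses are therefore compared at matched
treatment exposure, not at a shared calendar day. Significance testing
(pooled two-sample t, two-tailed) is reserved for synthetic cohorts that
carry animal-level noise; deterministic trajectories are never tested for
"significance".

## 7. Known limitations

* The PD structure is a minimal six-state realization of the stated
  pharmacology; the original supplementary equations may differ in detail
  (number of protein pools, exact memory mechanism). The RHS sits behind
  one replaceable function, so a transcription can be dropped in.
* $s$ is weakly identified by cohort-level tumor curves alone — by design
  the model is robust to two-fold $s$ changes, which is exactly why the
  recovery benchmark judges the parameter vector by its median error and
  why predictions, not parameters, carry the consistency criterion.
* Secondary PK compartments are not physiologically identified; population
  PK (inter-animal kinetic variability), continuous-infusion dosing,
  receptor-level drug binding, spatial tumor structure, and toxicity
  models are out of scope.
* Synthetic cohorts emulate sampling noise, growth heterogeneity, and
  censoring — not assay detection limits, immunogenicity-driven PK drift,
  or model misspecification; conclusions from passing tests are about the
  machinery, not about mice.
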