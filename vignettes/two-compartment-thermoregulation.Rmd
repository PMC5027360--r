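---
title: "Two-compartment thermoregulation: model, inference and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment thermoregulation: model, inference and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermorun)
```

## The physiological problem

During intense treadmill exercise a rat's skeletal muscles generate far
more heat than the rest of the body can absorb or shed, and the animal
stops running once its core temperature reaches a threshold near 40 °C.
Telemetry gives the core temperature; the muscle temperature, the
partition of heat production between muscle and core, and the rate of heat
loss to the environment are all unobserved. `thermorun` recovers them from
two measured signals — core-temperature telemetry and open-circuit
indirect calorimetry (VO₂, VCO₂) — through a deliberately minimal
heat-balance model, and quantifies the uncertainty of everything it cannot
observe directly.

## The model

The body is two lumped compartments of equal heat capacity, skeletal
muscle and core (skeletal muscle is roughly half a rat's mass once the
skeleton is excluded). Writing temperatures in °C and heat-production
rates per unit heat capacity (°C/min):

$$
\frac{dT_c}{dt} = P_c - \eta\,(T_c - T_m) - \eta_a\,(T_c - T_a), \qquad
\frac{dT_m}{dt} = P_m(t) - \eta\,(T_m - T_c),
$$

with shared initial condition $T_c = T_m = T_0$ at placement on the belt.
The parameters:

| symbol | meaning | units | status |
|---|---|---|---|
| $P_c$ | core heat production | °C/min | fitted |
| $\eta_a$ | core→environment dissipation coefficient | min⁻¹ | fitted |
| $P_m(t)$ | muscle (exercise) heat production | °C/min | derived from calorimetry |
| $\eta$ | muscle↔core transfer coefficient | min⁻¹ | fixed, 0.125 |
| $T_a$ | ambient temperature | °C | known, 24 |
| $T_0$ | baseline temperature | °C | from pre-placement telemetry |

Only the environment term removes heat, so $\eta_a$ is the single knob
controlling how fast the animal can unload the exercise heat; it is the
parameter of interest when comparing treatments.

### From gas exchange to forcing

Almost all metabolic energy comes from oxidation, so total heat production
tracks oxygen consumption. With the respiratory exchange ratio
$\mathrm{RER} = \mathrm{VCO_2}/\mathrm{VO_2}$, the energy yield of oxygen
is $CV = 3.815 + 1.232\,\mathrm{RER}$ kcal/L, and the mechanical work of
climbing the belt at speed $v$ (m/min) and incline $\theta$ is
$MW = 9.8\, v \tan\theta / 4.184$ cal/kg/min. Equal compartment heat
capacities give

$$
P_m + P_c \;=\; \frac{2\left(CV \cdot \mathrm{VO_2} - MW/1000\right)}{c},
\qquad c = 0.8\ \mathrm{kcal/(kg\,°C)}.
$$

One unit choice deserves a remark: $CV\cdot\mathrm{VO_2}$ is in
kcal/kg/min while the mechanical-work formula yields cal/kg/min, and the
division by the specific heat $c$ is required to land on °C/min. The
bracket above (MW divided by 1000, whole bracket divided by $c$) is the
only dimensionally consistent combination, and `total_heat_production()`
implements exactly that.

Given total heat production, fixing $P_c$ determines the muscle share
$P_m(t) = \mathrm{total}(t) - P_c$ (`partition_heat()`). A negative $P_m$
is tolerated with a warning — it can legitimately appear before the run if
a proposed $P_c$ exceeds resting metabolism — because rejecting it would
bias the sampler's exploration.

### Solving the ODE

Calorimetry is sampled once per minute, so the forcing is held constant on
each one-minute interval (sample-and-hold; inventing an interpolation the
measurement cadence cannot support would add nothing). On each segment the
system is linear with constant coefficients and a symmetric system matrix,
so `simulate_temperatures()` uses the analytic eigendecomposition of

$$
A = \begin{pmatrix} -(\eta+\eta_a) & \eta \\ \eta & -\eta \end{pmatrix}
$$

to propagate the state in closed form — there is no truncation error, only
floating point. The $\eta_a = 0$ limit (zero eigenvalue) is handled by the
$\lim_{\lambda\to 0}(e^{\lambda dt}-1)/\lambda = dt$ branch. The test
suite checks the solver against two independent oracles (an
augmented-matrix exponential and a fixed-step RK4 at $dt = 0.01$ min) on
100 random parameter draws, and against the analytic equilibrium
$T_c^* = T_a + (P_c+P_m)/\eta_a$, $T_m^* = T_c^* + P_m/\eta$ after
long-horizon integration.

## Inference

The data are group-mean temperature series $T_k(t)$ with per-time
across-animal sample SDs $\sigma_k(t)$, on a one-minute grid from
placement ($t=-12$) to the truncation point. Measurements are treated as
independent Gaussians around the model trajectory:

$$
\log L(P_c, \eta_a) = -\tfrac12 \sum_t
\frac{\left(T_k(t) - T_c(P_c, \eta_a, t)\right)^2}{\sigma_k^2(t)} .
$$

Choices worth making explicit:

* **Summation window.** The sum runs over the full series including the
  twelve pre-run minutes (a `window = "run_only"` switch restricts it).
  The pre-run points are what separate $P_c$ from $\eta_a$: before the
  belt starts, $dT_c/dt \approx P_c - \eta_a (T_0 - T_a)$, so they pin
  down the baseline balance that the run-phase data alone leave nearly
  unidentified.
* **Variance.** $\sigma_k(t)$ is the across-animal *sample SD*, not the
  SD of the mean. This makes the posterior conservative (the group mean
  itself fluctuates by roughly $\sigma_k/\sqrt{n}$), which we accept: it
  is how the weighting is conventionally written for this analysis, and
  widening rather than narrowing uncertainty is the safe failure mode.
* **SD flooring.** $\sigma_k(t) < 0.05$ °C (telemetry resolution scale)
  is floored to 0.05 so a coincidentally tight time point cannot dominate
  the fit; flooring is reported when applied.
* **$T_0$.** The mean of samples taken at or before placement when
  present, else the first sample. It is a constant of the fit, not a free
  parameter.

Sampling is plain random-walk Metropolis–Hastings with independent
Gaussian proposals per coordinate and a flat prior on a support box
($P_c \in [0,1]$ °C/min, $\eta_a \in [0, 0.1]$ min⁻¹ — an order of
magnitude around all plausible values). Defaults are 50,000 draws with
5,000 burn-in, proposal SDs (0.01 °C/min, 5×10⁻⁴ min⁻¹), chain started at
the box center; on series of the scale this model is fit to this lands
acceptance around 0.3–0.6. Posterior means and SDs of the retained draws
are the reported estimates, the maximum-likelihood draw defines the
best-fit trajectory, and groups are compared with a two-sample z-test on
mean ± SE. Everything is seeded and bit-reproducible.

Muscle temperature is reconstructed by pushing up to 2,000 evenly
subsampled posterior draws through the model and summarizing $T_m(t)$ by
per-time mean and SD (`reconstruct_muscle_temperature()`); reconstruction
stays inside the fitted window — extrapolating $P_m$ past the last
calorimetry sample would require inventing forcing the data do not
contain.

## The synthetic cohort generator

No public telemetry/calorimetry recordings accompany this kind of
experiment, so the package generates cohorts carrying the statistical
structure the analysis assumes, and every downstream stage is tested
against that ground truth.

What it emulates: a 12-minute pre-run period with constant VO₂; 3-minute
incremental workload stages ramping to the familiarization maxima of
26 m/min and 20°; cohorts of n = 6; per-animal baseline temperatures
(37.5 ± 0.3 °C), thermal parameters, and exhaustion thresholds
(40.0 ± 0.2 °C); per-minute telemetry noise (0.15 °C); and the group
truncation rule — the group series ends when its first animal drops out.
VO₂ relaxes first-order (τ = 1 min) toward a workload-proportional target
(baseline 0.02 L/kg/min, gain 0.0017 per unit of
$v\tan\theta + v$, spanning roughly 0.02–0.08 L/kg/min over the ramp —
resting to maximal rates typical of running rats), and RER drifts linearly
from 0.85 to 1.0 over the run as fuel shifts toward carbohydrate.
Between-animal SDs of $P_c$ (0.02 °C/min) and $\eta_a$ (0.001 min⁻¹) are
set to the scale of the group-level spread such experiments report.

What it does not emulate: the brief "anticipatory" temperature dip after
placement (a transient drop in core heat production — here $P_c$ is
constant); thermoregulatory feedback on $\eta_a$ (held constant, defensible
below ~39 °C core temperature); amphetamine pharmacokinetics (a treatment
is represented purely as a shift in generating $\eta_a$ and/or $P_c$); and
any per-animal correlation between VO₂ and thermal parameters. Passing
recovery tests therefore show that the estimator is correct *for data the
model describes*, not that the model captures every feature of real
telemetry.

Exhaustion is evaluated on the noiseless trajectory by default so that
exhaustion-time distributions remain interpretable (a flag switches to
noisy crossing). A group-mean series assembled from n animals with
per-animal noise σ carries mean-level noise $\sigma/\sqrt{n}$; the
recovery tests generate their series with exactly that structure while the
likelihood keeps weighting by the full sample SD, mirroring how the real
group data arise and are fit.

## Problem sizes and numerical conventions

* Fitted series: 26–30 one-minute points; fits use the default 50k-draw
  chain (≈2–3 s each); the bundled two-group analysis
  (`run_full_analysis()`) completes in well under a minute.
* Recovery is verified over 20 seeded replicates per group with 20k-draw
  chains; directional treatment effects over 20 seeded two-group
  experiments with 4k-draw chains — sizes at which every property tested
  is stable from seed to seed.
* Stage intervals are left-closed/right-open: at a stage boundary the new
  workload applies. Pre-run workload is identically zero.
* Proposals falling outside the support box are rejected without
  evaluating the likelihood (the flat prior's density is zero there);
  a chain with no accepted post-burn-in moves raises an error with
  diagnostics rather than returning a degenerate ensemble.
* RER outside [0.7, 1] warns but proceeds (transients near exhaustion
  exceed 1); negative muscle heat warns but proceeds.

## Known limitations

Two compartments cannot resolve skin or tail heat flow, so $\eta_a$ lumps
every dissipation route into one first-order coefficient; the constant-
$\eta_a$ assumption fails once thermoregulatory vasodilation engages
(plateauing core temperature), and fits should not be extended past such a
plateau. $P_c$ and $\eta_a$ are strongly correlated in the posterior —
their separation rests on the pre-run baseline and the growing core–
ambient gradient — so short or truncated series widen both posteriors
considerably. Finally, the z-test compares group-level posterior
summaries; it does not model between-animal variance hierarchically.
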