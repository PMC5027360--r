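# thermorun

Two-compartment heat-balance analysis of core-temperature telemetry from
small animals running an incremental treadmill protocol.

## The problem

A running rat's skeletal muscles produce heat far faster than it can be
dissipated, and the animal quits once its core temperature hits a
threshold near 40 °C. Telemetry measures core temperature and open-circuit
calorimetry measures oxygen uptake, but the quantities that decide
endurance — the heat dissipation rate, the partition of heat production
between core and muscle, and the muscle temperature itself — are
unobservable. `thermorun` is for exercise physiologists and
thermoregulation modelers who want to estimate those hidden quantities,
with honest uncertainty, from the two measured signals.

## The model

Body = two lumped compartments of equal heat capacity (skeletal muscle,
core):

```
dTc/dt = Pc − η (Tc − Tm) − ηa (Tc − Ta)
dTm/dt = Pm(t) − η (Tm − Tc)
```

with `Tc = Tm = T0` at placement on the belt. Indirect calorimetry fixes
the total forcing through `Pm + Pc = 2 (CV·VO2 − MW/1000) / c`, where
`CV = 3.815 + 1.232·RER` kcal/L, `MW = 9.8·speed·tan(incline)/4.184`
cal/kg/min is the climbing work, and `c = 0.8` kcal/(kg·°C) is the body's
specific heat. The muscle–core transfer coefficient is fixed at
`η = 0.125 min⁻¹`; the free parameters `(Pc, ηa)` are sampled by
random-walk Metropolis–Hastings from the Gaussian likelihood

```
log L = −½ Σt (Tk(t) − Tc(Pc, ηa, t))² / σk²(t)
```

over the group-mean series. The linear ODE is solved in closed form per
one-minute forcing segment (analytic eigendecomposition — no integration
error), and muscle temperature is reconstructed by propagating posterior
draws through the model. A synthetic cohort generator (protocol-driven
VO₂, per-animal variability, exhaustion thresholds, first-dropout group
truncation) stands in for animal recordings and provides ground truth for
recovery tests.

## Worked example

Simulate a saline-like and a treated-like group (the treatment raises the
dissipation coefficient ~24 %), fit both, and compare:

```r
library(thermorun)

config <- list(
  seed = 42,
  mcmc = list(n_samples = 20000, burn_in = 2000),
  synthetic = list(
    cohort = list(n_rats = 6),
    groups = list(saline = list(Pc = 0.25, eta_a = 0.0156),
                  amph   = list(Pc = 0.24, eta_a = 0.0194))
  )
)
res <- run_full_analysis(config)
print(res$fits$saline)
print(res$report)
```

```
Group fit: saline (T0 = 37.65 degC, VO2max = 0.0766 L/kg/min)
  Pc    = 0.227 +/- 0.031 degC/min
  eta_a = 0.0154 +/- 0.0008 1/min
  acceptance rate 0.49 over 18000 retained draws
  muscle T at end of fit window: 41.84 +/- 0.26 degC
Group comparison: saline vs amph
  Pc     0.2268 +/- 0.031  vs  0.2621 +/- 0.036   z = -0.75, p = 0.456
  eta_a  0.01537 +/- 0.0008  vs  0.01974 +/- 0.00079   z = -3.90, p = 9.82e-05
  Tm_end 41.84 +/- 0.26  vs  41.75 +/- 0.29   z = +0.23, p = 0.819
```

Reading the output: both fits recover their generating parameters within
one posterior SD; the dissipation coefficient difference is highly
significant while core heat production is not — the signature that the
treatment acts on heat *removal*, not heat *generation*. The muscle
temperature at the end of each group's fitted window is similar here
because both groups ran the same 18-minute ramp; giving the protocol more
headroom (`protocol = list(run_length = 30)`) lets the higher-dissipation
group run meaningfully longer and finish with hotter muscles.

Single-group fits (`fit_group()`), muscle reconstruction
(`reconstruct_muscle_temperature()`), CSV I/O (`read_gas_csv()`,
`read_group_csv()`), and a command-line wrapper
(`inst/exec/thermorun simulate|fit|reconstruct|compare|run-all`) are also
exported; see the vignette in `vignettes/` for the model's assumptions,
defaults and limitations.

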