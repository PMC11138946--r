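# bseir — behavior-coupled SEIR epidemic dynamics with delayed risk information

`bseir` is for epidemic modellers who want to study the feedback loop
between an outbreak and the protective behavior it triggers. It simulates
a community of 100,000 in which the fraction of susceptibles behaving
prophylactically (e.g. wearing masks) reacts to *delayed* case
information, and transmission depends in turn on that fraction — a
mechanism that by itself, with no waning immunity and no reseeding, can
generate multiple epidemic waves.

## The model

The epidemic side is an SEIR-type compartmental system with two
susceptible groups S₋₁, S₊₁ (distinguished by how they interpret risk
information), exposed E, asymptomatic Iₐ and symptomatic Iₛ infectious,
detected-and-isolated I_d, and removed R. The observable incidence is
C = πθE + γₐIₐ + γₛIₛ (early-detected exposed plus infectives identified
by testing). Each group sees two signals, delayed by the reporting delay
τ:

- perceived prevalence **P**(t) = I_d(t−τ)/N, and
- the incidence trend **Q**(t) = Ċ(t−τ)/C(t−τ),

aggregated as η = aP + bP² + cPQ + dQ² + eQ with group-specific
non-negative weights. The group's prophylactic proportion is a
generalized-logistic (Richards) response

  m = [1 + exp{δ − η}]^(−1/α),  δ = log(m₀^(−α) − 1),

where m₀ is the baseline proportion (0.05) and α is the in-group
pressure parameter (α < 1: engaged minorities recruit fast; α > 1: the
non-engaged majority drags). Behavior feeds back through the
quarantine-adjusted force of infection
λᵢ = β₀[1 − κmᵢ](φₐIₐ + φₛIₛ)/(N − I_d). Because Q involves a delayed
derivative, the system is a **neutral delay differential system**; it is
solved with `deSolve::dede` (method of steps). See the vignette
(`vignettes/behavior-seir-model.Rmd`) for the complete model, parameter
table, and numerical choices.

On top of the simulator the package provides:

- an epidemic **wave detector** (`detect_waves()`) using peak-prominence
  and trough rules on daily counts;
- **severity measures** (`summary()` on a fit): wave count, peak height
  H_p and day T_p, time T_c1 at which the effective reproduction number
  R(t) falls through 1, final size F_T = 1 − S(T)/N₀;
- the **simulation experiment** (`experiment_design()`, `run_grid()`,
  `descriptive_stats()`): a deterministic 34,560-run factorial grid over
  transmission β₀, early detection π, delay τ, protection κ, response
  profiles and in-group pairs;
- **summary regressions** (`fit_summary_models()`): Poisson (secondary
  waves), gamma (peak size) and a hand-written one-inflated beta MLE
  (final size), with deviance-based pseudo-R².

## Worked example

```r
library(bseir)
fit <- bseir("0xD", alpha = 0.1, horizon = 1000)  # half prevalence-only,
print(fit)                                        # half trend-responsive
summary(fit)
```

```
Behavior-SEIR simulation
  population: 0 x D (alpha = 0.1, 0.1), N0 = 100000
  horizon 1000 d, tau = 3 d, beta0 = 1, kappa = 0.9, pi = 0.5
  R_o = 7.000, R(0) = 6.685
  peak daily incidence 1376.9 cases/day at day 59
Epidemic severity summary
  epidemic:          yes
  waves (secondary): 2 (1)
  peak:              1376.88 cases/day at day 59
  time to curb:      63.15 d
  final size F_1000:   0.8942
```

Reading: with strong pro-prophylactic in-group pressure (α = 0.1) this
mixed population peaks at ~1,377 daily detected cases around day 59 —
*below both* corresponding homogeneous populations (profile 0 peaks at
~1,814, profile D at ~1,486) — the effective reproduction number first
drops below 1 at day 63, a behavioral relaxation later ignites one
secondary wave, and by day 1,000 89% of the community has been infected.

`plot(fit)` draws the incidence curve, the two groups' prophylactic
proportions, and R(t). A thin command-line wrapper for single runs and
wave detection lives in `inst/cli/bseir` (see
`inst/extdata/example-config.yaml`).

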