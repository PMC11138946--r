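---
title: "Coupled behavior-epidemic dynamics: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled behavior-epidemic dynamics: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bseir)
```

## The model

**bseir** simulates an epidemic in a closed, well-mixed community in which
the fraction of susceptibles engaging in prophylactic behavior (mask
wearing is the motivating example) reacts to *delayed* case information,
and transmission in turn depends on that fraction. The epidemic side is an
SEIR-type compartmental system with differentiated infectious states:

* two susceptible groups $S_{-1}, S_{+1}$ distinguished by how they
  interpret risk information,
* exposed $E$ (latent, non-infectious; mean duration $1/\theta$),
* asymptomatic $I_a$ and symptomatic $I_s$ infectious, detected at rates
  $\gamma_a < \gamma_s$,
* detected-and-isolated $I_d$ (removed from the mixing pool), and
* removed $R$.

A fraction $\pi$ of exposed individuals is detected early (contact
tracing / targeted testing) and moves straight to $I_d$; of the rest, a
fraction $\sigma$ becomes symptomatic. There are no vital dynamics, no
waning immunity, and no disease-induced mortality, so the population size
$N_0$ is constant. The force of infection on group $i$ uses the
quarantine-adjusted denominator,
$$\lambda_i = \beta_0\,[1 - \kappa m_i]\,
  \frac{\phi_a I_a + \phi_s I_s}{N_0 - I_d},$$
where $\kappa$ is the protection efficiency of the behavior and $m_i$ the
group's prophylactic proportion.

### Risk information

The observable quantity is the daily rate of new detected cases
$C = \pi\theta E + \gamma_a I_a + \gamma_s I_s$, which feeds the detected
class through $\dot I_d = C - \rho_d I_d$. Susceptibles see two signals,
both delayed by the reporting delay $\tau$:

* perceived prevalence $P(t) = I_d(t-\tau)/N$ (zero before $t = \tau$), and
* the relative trend $Q(t) = \dot C(t-\tau)/C(t-\tau)$, i.e. the
  instantaneous exponential growth rate of observed incidence ($Q = 1$ is
  doubling per day, $Q = -1/2$ halving per day; we follow the formula, not
  the loose "doubling" gloss, which is exact only in the linearized sense).

Each group aggregates them as
$\eta_i = a_iP + b_iP^2 + c_iPQ + d_iQ^2 + e_iQ$ with non-negative weights.
The named presets are: profile **0** ($a=20$, prevalence only), **A**
($b=50$, accelerated response at high prevalence), **B** ($c$, trend
response proportional to prevalence), **C** ($d=50$, sign-blind trend
response), **D** ($e=10$, early engagement and early disengagement).
Source materials disagree on profile B's weight: the experiment-grid
definition uses $c = 50$ while the illustration figures use $c = 150$.
`preset_profile("B")` follows the grid; `variant = "figure"` selects the
figure value.

### Behavior response

The prophylactic proportion follows a Richards (generalized-logistic)
growth law in the information aggregate,
$\partial m_i/\partial\eta_i = m_i(1-m_i^{\alpha_i})/\alpha_i$, whose
closed form is
$$m_i = \left[1 + \exp\{\delta_i - \eta_i\}\right]^{-1/\alpha_i},
\qquad \delta_i = \log(m_{i0}^{-\alpha_i} - 1).$$
$m_{i0}$ is the baseline proportion behaving prophylactically with no
evidence of disease (default 0.05). The in-group parameter $\alpha_i$
tilts attention between those already behaving prophylactically and those
not: growth in $m_i$ per unit information is fastest at
$m_i = (1+\alpha_i)^{-1/\alpha_i}$, so $\alpha_i < 1$ lets small engaged
minorities recruit quickly while $\alpha_i > 1$ makes the non-engaged
majority a drag. At fixed positive $\eta$, $m$ is strictly decreasing in
$\alpha$ (the package exposes the analytic derivative `dm_dalpha()`,
verified against finite differences).

During simulation the closed form is used directly; the differential form
is retained only as a test oracle (the suite integrates it along smooth
$\eta$ paths and checks agreement to 1e-6). The exponent
$\delta_i - \eta_i$ is clamped to $[-700, 700]$ before exponentiation —
pure overflow protection, unreachable in realistic runs.

### The delay system and its solution

Because $Q$ involves the delayed *derivative* of state variables, the
coupled system is a neutral delay differential system. It is solved with
`deSolve::dede`, which implements the method of steps with dense history
interpolation. The delayed derivative $\dot C(t-\tau)$ is read from the
solver's stored derivative history (`lagderiv`), which avoids both the
neutral-term recursion into $t - 2\tau$ and the choice of a
finite-difference step; a central-difference evaluation of the
interpolated incidence history is available as
`solver_settings(q_method = "fd")` and agrees with the default to within
$5\times 10^{-4}$ in the trend signal (sup-norm) and $10^{-4}$ relative
in the peak on the reference run (the test suite checks both routes and
a step-halving).

Numerical choices, all adjustable through `solver_settings()`:

* tolerances `rtol = 1e-8`, `atol = 1e-5` individuals (1e-10 of the
  default population); halving them moves the reference peak by well
  under 0.1%;
* output grid 0.5 day (the experiment's summary tables report half-day
  medians), with the daily incidence series extracted at integer days;
* the trend signal is floored: $C(t-\tau) \le 10^{-9}$ cases/day is
  treated as no observable incidence, giving $Q = 0$ — the mathematical
  guard only covers $C \le 0$, but floating-point underflow near
  extinction needs a floor;
* $\tau = 0$ is accepted for testing and treated as instantaneous
  information; the circular dependence of $Q$ on the current derivatives
  is broken with a single fixed-point pass (derivatives first evaluated
  with $Q = 0$). The experiment grid never uses it.

Before information arrives ($t < \tau$) both signals are zero by
definition, so the early trajectory is independent of the behavior
weights — a property the test suite checks, along with exact agreement
(to 1e-6 relative) with an independent non-delayed integration when all
information weights are zero.

### Reproduction numbers

The next-generation behavior-free number is
$$\mathcal{R}_o = \beta_0(1-\pi)\left[
  \frac{\phi_a(1-\sigma)}{\gamma_a+\rho_a} +
  \frac{\phi_s\sigma}{\gamma_s+\rho_s}\right],$$
equal to 7 under the default rates. At outbreak
$\mathcal{R}(0) = \mathcal{R}_o \sum_i (S_{i0}/N_0)(1-\kappa m_{i0})$, and
along a trajectory each group has
$\mathcal{R}_i(t) = \mathcal{R}_o\, S(t)/(N_0 - I_d(t))\,[1-\kappa m_i(t)]$
with $\mathcal{R}(t)$ their susceptible-weighted average (the `Rt` column
of the trajectory). Stability and bifurcation analysis of the delay
system is out of scope.

## Severity measures and wave detection

`summary()` on a solved model reports: the epidemic indicator, the number
of waves $n_w$, the overall daily peak height $H_p$ and day $T_p$, the
time $T_{c1}$ at which $\mathcal{R}(t)$ first falls through 1 (linear
interpolation between output knots; undefined when
$\mathcal{R}(0) \le 1$), and the final size $F_T = 1 - S(T)/N_0$.

The wave detector operates on daily counts. The disease "dies out"
(no wave) when the series never exceeds one plus the initial number of
infected individuals (4 under the default initial state: $E_0 = 2$,
$I_{a0} = I_{s0} = 1$). Otherwise candidate peaks are local maxima
(plateaus resolved to their first day) screened by topographic prominence
— at least 10 cases/day above the higher of the flanking troughs *and* at
least half the peak height; waves separated by an inadmissible trough
(500 cases/day or higher, or closer than 5 days to the preceding peak)
are merged; waves shorter than 7 days are dropped. The rule *order*
(prominence screen, then trough merging, then the duration rule) and the
plateau convention are this package's choices — the rules themselves do
not prescribe an order — and are exposed as arguments of
`detect_waves()`. One more boundary decision: when the epidemic threshold
is met but screening eliminates every candidate (e.g. a monotone series),
the global maximum is reported as the single wave, so "epidemic" and
"$n_w \ge 1$" remain equivalent. No smoothing is applied: the rules are
meant for simulated (noise-free) daily counts, and an empirical series
would need denoising first.

## The simulation experiment

`experiment_design()` enumerates the study grid: populations 0, A-D and
the half-and-half mixtures 0xA-0xD (the reference profile on group $-1$),
in-group pairs $(\alpha_{-1}, \alpha_{+1})$, and
$\beta_0 \in \{0.5, 1, 2, 3\}$, $\pi \in \{1/4, 1/2, 2/3, 3/4\}$,
$\tau \in \{1, 3, 5, 7\}$ days, $\kappa \in \{0.5, 0.6, 0.75, 0.9, 0.95,
1\}$ — 384 runs per profile/pair cell, 34,560 in total, each over 1,000
days. The default in-group pairs are all 10 unordered pairs from
$\{0.1, 1, 2, 3\}$; the source table prints only 7 of them, so the
remaining 3 are a reconstruction (flagged, since block counts of
3,840 = 10 x 384 require exactly ten). Heterogeneity is measured by
$\Delta\alpha = \alpha_{-1} - \alpha_{+1}$; the opposite sign convention
appears in one footnote of the source materials, so
`fit_summary_models(delta_alpha_sign =)` supports both.

Everything is deterministic — there is no randomness anywhere in the
model — so `run_grid()` needs no seed and supports checkpoint/resume.
The full grid takes hours on one CPU (`scripts/reproduce_grid.R`); the
package's test suite exercises the pipeline on small sub-grids and
reduced horizons (250-400 days) chosen so the suite completes in about a
minute, and validates the *full-scale* behavior through the single-run
reference peaks instead.

Severity results are summarized two ways:

* `descriptive_stats()` — median/mean/SD per measure by profile or by
  in-group pair (a single-run cell reports SD 0);
* `fit_summary_models()` — Poisson regression (log link) on the number
  of secondary waves, gamma regression (log link) on the peak size
  (runs peaking below 1 case/day are excluded for support and counted),
  and a one-inflated beta regression (logit mean link) on the final
  size. Predictors: profile indicators (reference 0), $\alpha_{-1}$,
  $\Delta\alpha$, $\kappa$, $\tau$, $\pi$, $\beta_0$.

No installed package provides one-inflated beta regression, so it is fit
by direct maximum likelihood (`oibeta_reg()`): constant precision
$\phi$, constant inflation mass $\nu$ at 1 (fixed to 0 when the response
never reaches 1, which reduces the model to ordinary beta regression),
BFGS on the analytic log-likelihood, standard errors from the numerical
Hessian. The deviance-based pseudo-$R^2$ for all three models is
$1 - D/D_0$; for the beta mixture both deviances are computed against the
same saturated reference with $\phi$ and $\nu$ held at the full-model
estimates (mixing per-model dispersions would make the ratio
meaningless). Exact reproduction of published standard errors is a
non-goal — they depend on fitting-machinery details — the coefficients
are the comparison surface.

## Synthetic forcing fixtures

`logistic_pulse()` generates the single-wave incidence curve
$C(t) = N_0 e^v/(1+e^v)^2$, $v = (t-50)/8$ (peak $N_0/4 = 25{,}000$
cases/day at day 50), and `behavior_under_forcing()` drives the behavior
pathway with it: $I_d$ reconstructed by quadrature with $\rho_d = 1/14$
(the figure-fixture value; the full model's default is $\rho_d = 1/70$ —
the two are used in different contexts by the source materials and are
not reconciled there), then $P$, $Q$, $\eta$, $m$ through exactly the
same functions as the coupled model. This pathway emulates what a
behavior group would see during a clean single-wave epidemic: a smooth
symmetric pulse with a known analytic peak. It does not emulate
observation noise, weekly reporting artifacts, overlapping waves, or the
feedback of behavior on incidence — so tests passing on it validate the
behavioral response surface, not epidemic realism; realism checks come
from the coupled runs.

## Fatigue extension (experimental)

`prophylactic_proportion_fatigue()` implements the proposed extension in
which in-group behavior carries information even under constant risk
(weight $\omega$) and engagement decays with accumulated effort $M_i$
(fatigue $f_i = 1 - e^{-\epsilon M_i}$). It reduces exactly to the base
model at $\omega = \epsilon = 0$ and is off by default and not wired into
the epidemic solver. One analytic subtlety worth recording: with
$\omega = 0$ and a *constant* positive $\eta$, fatigue has no visible
effect at all — the correction term $\zeta_i$ exactly cancels the
discount ($d[\eta(1-f)+\zeta]/dt = (1-f)(\dot\eta + \omega\eta) = 0$) —
so fatigue only manifests while information is changing (or $\omega >
0$). The test suite therefore probes fatigue with a rising $\eta$ path,
where the fatigued response provably lags the base model with a widening
gap. The "engagement-only" variant (fatigue discounts engagement but not
disengagement) has no closed form and is integrated directly in $m$; its
indicator uses $g = 1$ when $d\eta/dt \ge 0$, ties counting as
engagement.

## Default parameter values

| Parameter | Meaning | Default | Grid values |
|---|---|---|---|
| $\beta_0$ | baseline contact rate (/day) | 1 | 0.5, 1, 2, 3 |
| $\phi_a, \phi_s$ | transmission probability on contact | 1 | — |
| $\kappa$ | protection efficiency | 0.9 | 0.5, 0.6, 0.75, 0.9, 0.95, 1 |
| $1/\theta$ | latent period (days) | 4 | — |
| $\pi$ | early-detection probability | 1/2 | 1/4, 1/2, 2/3, 3/4 |
| $\sigma$ | symptomatic fraction | 1/2 | — |
| $\gamma_a, \gamma_s$ | detection rates (/day) | 2/70, 4/70 | — |
| $\rho_a, \rho_s, \rho_d$ | removal rates (/day) | 3/70, 1/70, 1/70 | — |
| $\tau$ | information delay (days) | 3 | 1, 3, 5, 7 |
| $\alpha_i$ | in-group parameter | 1 | 0.1, 1, 2, 3 |
| $m_{i0}$ | baseline prophylactic proportion | 0.05 | — |

Rates are entered as exact fractions over $14 \times 5 = 70$ to avoid
decimal drift. The default initial state is $S_{-1,0} = S_{+1,0} =
49{,}998$, $E_0 = 2$, $I_{a0} = I_{s0} = 1$, $I_{d0} = R_0 = 0$
($N_0 = 100{,}000$).

## Known limitations

* Well-mixed, two-group population: no spatial, network, or age
  structure, and no movement between the susceptible groups.
* Single pathogen, no reinfection or waning immunity: late-horizon
  dynamics are entirely behavioral.
* The quadratic information aggregate is an approximation to an unknown,
  likely non-linear appraisal process; its weights are not fitted to
  behavioral data here.
* The solver reports, but does not prove, non-negativity: compartments
  are clamped at zero within an absolute tolerance of $10^{-6} N_0$ and
  integration aborts beyond it.
* A handful of extreme grid corners (sign-blind trend response with
  near-perfect protection, short delay, strong pro-prophylactic
  pressure) drive the solver into such fast behavioral oscillation that
  the step size collapses; there the cyclic history buffer stops
  spanning the delay window and the run aborts with a recorded error
  rather than grinding indefinitely. `run_grid()` records these per row
  (the `error` column) and carries on; about 0.1% of the grid is
  affected.
* One reference value resists reproduction: with all defaults the
  homogeneous profile-D run peaks at 1,486 daily cases in this
  implementation (robust across tolerances and both neutral-term
  schemes), while the companion reference runs (profile 0, and the 0xD
  mixture) match to under 0.5%. A profile-D run with $\tau = 5$ peaks at
  1,658. The discrepancy is documented rather than papered over.

```{r example, eval = FALSE}
fit <- bseir("0xD", alpha = 0.1, horizon = 1000)
summary(fit)
plot(fit)
```
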