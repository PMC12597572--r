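---
title: "The remimazolam/CNS7054 PK-PD model: structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The remimazolam/CNS7054 PK-PD model: structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remipkpd)
```

remipkpd implements a population pharmacokinetic–pharmacodynamic model of
the intravenous benzodiazepine remimazolam and its carboxylic-acid
metabolite CNS7054, together with the machinery a pharmacometrician needs
around such a model: covariate-based individualisation, exact simulation of
dosing schedules, target-controlled-infusion (TCI) planning, virtual-cohort
generation and desk-scale parameter recovery. This vignette documents the
model itself, the assumptions baked into each module, and the design
decisions that were genuinely open.

## Structural pharmacokinetic model

Remimazolam disposition follows a three-compartment mammillary model
(central volume $V_1$, peripheral $V_2$, $V_3$; elimination clearance $CL$;
intercompartmental clearances $Q_2$, $Q_3$). Amounts are in mg, volumes in
L, clearances in L/min, so concentrations are in mg/L = µg/mL throughout.

Arterial concentration is $C_{art} = A_1/V_1$. Venous observations lag the
arterial signal: a mass-less delay tracer obeys
$\dot C_{del} = k_{delay}(C_{art} - C_{del})$ and the venous concentration
is the convex combination

$$C_{ven} = F_{ven}\,C_{art} + (1 - F_{ven})\,C_{del},
\qquad F_{ven} = 0.132,\; k_{delay} = 0.0144\ \mathrm{min}^{-1}.$$

The fraction of remimazolam metabolised is taken as 100%: all eliminated
parent mass enters a metabolite formation depot and transfers to the
CNS7054 central compartment at first order ($k_{depot}$), from which the
metabolite distributes over two compartments and is cleared. The same
arteriovenous delay model (same $F_{ven}$, $k_{delay}$) is reused for
CNS7054, which mirrors how the model was estimated — no separate venous
parameters exist for the metabolite. The delay compartment is a pure
tracer: no distributional mass is assigned to it, because no venous volume
is identified. Parent-to-metabolite transfer is mass-to-mass with a
configurable conversion factor (default 1; no molar correction is applied
anywhere in the estimates, so applying one here would be inconsistent).

Two mass-less effect sites, one per pharmacodynamic endpoint, equilibrate
with the arterial concentration as $\dot C_e = k_{e0}(C_{art} - C_e)$.

## Covariate model

All fixed effects refer to a reference individual: a 70-kg, 35-yr-old male
without concomitant opioids and with normal hepatic and renal function.
Scale conventions follow the estimates exactly, despite being inconsistent
across parameter blocks:

* weight: linear for remimazolam volumes, exponent 0.75 for clearances, and
  an estimated exponent ($K_{scale} = 0.518$) for CNS7054 volumes;
* age: $\exp(K/1000 \cdot (\mathrm{age} - 35))$;
* binary covariates (sex, opioids, Pugh–Child > 8, end-stage renal
  disease): $\exp(K/100)$;
* ECMO/ICU adjustments: direct multiplicative factors, applied to the
  already-individualised parameters.

Peripheral distribution uses compartmental allometry,
$Q_x = Q_{x,ref}(V_x/V_{x,ref})^{0.75}$, so covariate effects on $V_3$
(age, sex, hepatic dysfunction) propagate into $Q_3$. Interindividual
variability is log-normal, $\theta_i = \theta\,e^{\eta_i}$ with
$\eta_i \sim N(0, \omega^2)$; the remimazolam $CL$ variance is inflated
1.86-fold for individuals contributing only venous samples. The implied
coefficient of variation is $CV(\%) = 100\sqrt{e^{\omega^2} - 1}$ — this is
the form that reproduces the reported CV column (e.g. $\omega^2 = 0.0631
\rightarrow 25.5\%$, $0.145 \rightarrow 39.5\%$), and `cv_from_omega2()` /
`omega2_from_cv()` implement the pair.

`simplified_remi_params()` transcribes, digit for digit, the published
simplified population-prediction code intended for TCI pumps; a
property-style test holds the full covariate engine to within 0.2% of it
across the demographic envelope (ages 6–93 yr, weights 21–171 kg), the
residual being rounding of the published estimates.

ECMO and ICU adjustments deserve a caveat: they were estimated post hoc on
poorly predicted subgroups, and `apply_ecmo_icu()` applies them exactly as
reported (e.g. remimazolam $V_1 \times 46.1$ while ECMO runs, $\times
0.189$ for ECMO subjects overall; $CL \times 0.264$ after 24 h in ICU).
Predictive accuracy in those groups is known to be poor, so TCI use there
should rely on the unadjusted population model with titration to effect.

## Pharmacodynamic models

Both endpoints share a competitive-interaction Hill kernel,

$$f(C_e, C_a) = \frac{(C_e/Ce_{50})^\gamma}
{1 + (C_e/Ce_{50})^\gamma + (C_a/Ca_{50})^\gamma},$$

in which the metabolite concentration $C_a$ (arterial, not effect-site —
an effect site for CNS7054 did not improve the fitted model) enters only
the denominator. CNS7054 is pharmacologically inactive: at $C_e = 0$ it has
no effect whatever its concentration. Because metabolite clearance is about
twenty-fold lower than the parent's, $C_a$ accumulates during an infusion
and the drug effect at constant $C_e$ wanes — the model's representation of
tolerance. The drift is stronger in the young (higher clearance relative to
metabolite clearance, higher targets) and dissipates after dosing stops.

**MOAA/S** (Modified Observer's Assessment of Alertness/Sedation, ordinal 0
= unresponsive to noxious stimulus … 5 = responds readily to name) follows
a proportional-odds model. The drug effect enters the logit of the deepest
category, $l_{S=0} = b_0 + D_{EFF} f(C_e, C_a)$, and the cumulative logits
accumulate the non-negative cut-point differences $d_{01}, d_{12}, d_{23},
d_{34}$. Opioid co-administration shifts probability density from score 1
to score 0 with the other scores untouched. The published estimates list
the opioid-adjusted values only as derived quantities; the reconstruction
used here is

$$d_{01}^{op} = d_{01} e^{-K},\qquad b_0^{op} = b_0 + d_{01} - d_{01}^{op},$$

chosen because it (a) leaves the $S \le 1$ cumulative logit exactly
invariant, which is what "shifting density from 1 to 0" means in a
proportional-odds chain, and (b) reproduces both reported derived values
($b_0^{op} = -14.4$ exactly; $d_{01}^{op} = 0.499$ against a reported
0.500, the residual being the printed rounding of $K$ and $d_{01}$).

**BIS** (bispectral index) is a sigmoidal Emax model,
$BIS = BIS_0 (1 - f(C_e, C_a))$ with baseline 93.7. Both the BIS $Ce_{50}$
and $k_{e0}$ decline with age; the MOAA/S $k_{e0}$ (0.298 min⁻¹) carries
no covariates.

The Hill exponent $\gamma$ is not reported for either endpoint (its
estimation was judged not to improve the BIS model), so both default to 1
and are exposed in the configuration. Every closed-form check in the test
suite that depends on $\gamma$ is written at $\gamma = 1$.

## Numerics

The coupled system is linear with constant coefficients within any interval
of constant infusion rate, so simulation is exact: the state (augmented
with the input) is propagated by matrix exponentials per interval, with
boluses as instantaneous increments. Matrix exponentials are cached per
step length, so regular grids cost one factorisation. An adaptive ODE
solution (`deSolve::lsoda`, rtol 1e-10) serves as an independent oracle in
the tests — never as the simulation path — and the two agree to better than
1e-6 relative over randomised schedules and covariates. Two bookkeeping
states accumulate eliminated parent and metabolite mass, so mass balance
(administered = in body + eliminated; eliminated parent = total metabolite
produced) is checked to 1e-8 rather than assumed.

Time to peak effect after a bolus is located by coarse bracketing plus
golden-section refinement of the continuous solution (tolerance 1e-4 min).
For the reference adult it is 2.40 min; under the simulation conditions
used for dosing guidance (opioids present, hence ~13% lower clearance) it
is 2.48 min — the "about 2.5 min" figure. This sensitivity of $t_{peak}$
to $CL$ is worth knowing when comparing against clinical measurements.

## TCI controller

Plasma targeting is analytic: a $T \cdot V_1$ loading bolus followed by the
linear-system-inverse rate profile $r(t) = T(CL + Q_2 e^{-k_2 t} + Q_3
e^{-k_3 t})$, averaged exactly over each control tick. Effect-site
targeting uses a discrete-time law (1-s ticks by default): at every tick
the controller computes, from the cached step propagator and a look-ahead
map of future effect-site responses, the largest pump rate for which the
predicted future peak of $C_e$ does not exceed the target. The solution is
closed-form per tick (a minimum over look-ahead rows), so $C_e$ rises
monotonically to the target with zero overshoot and the law degenerates
gracefully into a hold once the target is reached. The pump cap defaults to
600 mg/h; targets unattainable under the cap are flagged, not silently
missed. The sedation-score $k_{e0}$ drives the controller in both
scenarios; BIS is evaluated as a passive output with its own $k_{e0}$.

Scenario targets are criterion-derived by simulation of the full system
(so metabolite build-up during induction and the opioid cut-point shift are
included): sedation maximises $P(S \in \{2,3\})$ at 10 min; anaesthesia is
the minimal target giving $P(S = 0) \ge 0.9$ at first target attainment.
The induction dose is defined as the cumulative dose when the targeted
signal first reaches 99% of target (no published definition exists), and
the maintenance rate is averaged over minutes 30–60 of a 60-min simulation.
Dosing-guidance simulations assume opioids present and normal hepatic and
renal function. Under these definitions both the induction dose and the
maintenance rate decline monotonically over ages 20–90, and the young-adult
anaesthesia induction dose (~0.23–0.27 mg/kg at 70 kg) sits inside the
0.14–0.37 mg/kg envelope reported across clinical induction studies.

## The synthetic-data generator

`population_spec()` / `sample_population()` / `generate_observations()`
produce NONMEM-style long-format datasets with the statistical structure
the analysis assumes, so every downstream stage is testable without the
(unavailable) clinical data. What it emulates:

* covariates drawn over the modelled demographic envelope (uniform age
  6–93 yr, weight 21–171 kg by default; sex split 365/933 female as in the
  PK cohort; opioid prevalence 0.5; hepatic/renal/ECMO/ICU/venous-only
  prevalence 0 unless requested — the main PK population excluded the
  ECMO/ICU studies);
* independent log-normal random effects per parameter with the reported
  $\omega^2$, and the 1.86-fold $CL$-variance inflation for venous-only
  subjects;
* proportional (transform-both-sides, i.e. multiplicative log-normal) PK
  residual error; categorical MOAA/S draws from the model probabilities;
  BIS as the noise-free prediction delayed 15 s, a per-subject baseline
  shift with variability equal to the residual variability, 1-Hz additive
  noise, then median filtering in 10-s epochs;
* the 2-min (remimazolam) and 3-min (CNS7054) post-dose-start exclusion
  windows, applied at observation generation — they are data-analysis
  conventions, not simulation truths.

Residual-error magnitudes are not reported with the model estimates, so
the defaults ($\sigma_{PK} = 0.20$ log-scale, $\sigma_{BIS} = 4$ BIS units)
are package choices of clinically plausible magnitude, recorded in the
dataset attributes and exposed in the spec. What the generator does *not*
emulate: the twenty source studies' individual designs, dropout or
missingness beyond the exclusion windows, assay limits, or model
misspecification of any kind. Passing recovery tests on these cohorts
therefore demonstrates internal consistency of the implementation — that
the estimation machinery inverts the generator — not that the model fits
real patients.

## Parameter recovery

Full nonlinear mixed-effects estimation (FOCE/LAPLACE) is deliberately out
of scope. Two desk-scale tools are provided. `map_etas()` computes
empirical-Bayes (MAP) individual etas with known $\theta$, $\omega^2$,
$\sigma$: the penalised least-squares problem (scaled log-residuals stacked
with prior-scaled etas) is solved by Levenberg–Marquardt, which polishes to
machine precision where quasi-Newton on the summed objective stalls in flat
directions. On noise-free, richly sampled cohorts (samples through 360 min,
so the slow compartment is informed) it recovers the true etas to 1e-3 and
better. `pooled_ml()` estimates a chosen subset of fixed effects with etas
pinned at zero, on low-variability designed cohorts; structural parameters
are searched on the log scale, covariate coefficients on their natural
scale. A 50-subject, 5%-noise cohort recovers $CL_{ref}$ and $V_{1,ref}$
within 5% from deliberately mis-set starting values. MdPE/MdAPE predictive
performance metrics use proportional scaling for concentrations and
additive scaling for BIS.

## Problem sizes and tolerances

Test and acceptance workloads are sized for a laptop-class single core:
oracle equivalence over 100 random schedules, covariate-engine equivalence
over 1000 random draws, 1e5 random inputs for the distribution invariants,
a 50-subject cohort for pooled recovery and 3 subjects for MAP recovery.
Controller tolerances: 1% overshoot allowance (never consumed in
practice), 1e-3 µg/mL target-search tolerance, 1e-4 min peak-time
tolerance. The TCI look-ahead horizon is 15 min, comfortably beyond the
~2.5-min peak-effect time.

## Known limitations

* $\gamma = 1$ is an assumption, not an estimate; reported MOAA/S fit
  improvements from a "sigmoidal drug effect" suggest the original
  exponent may differ.
* The ECMO/ICU adjustments reproduce reported point estimates for
  subgroups in which even the original model predicted poorly.
* The competitive-antagonist tolerance mechanism is a phenomenological
  choice (CNS7054's receptor affinity is far too low for literal receptor
  competition); alternative mechanisms are not implemented.
* Opioid co-administration is a binary covariate; no opioid
  concentration–effect model is included.
* Residual-error magnitudes in the generator are stand-ins; recovery
  experiments quantify internal consistency only.
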