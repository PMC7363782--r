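---
title: "Virtual closed-loop glucose-control trials in extremely preterm infants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual closed-loop glucose-control trials in extremely preterm infants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoloop)
```

## The problem

Extremely preterm infants (birth weight below 1200 g) are prone to both
hyperglycaemia and hypoglycaemia in the first week of life. Insulin
production and glycogen stores are deficient, parenteral nutrition delivers
a continuous dextrose load of around 8–10 mg/kg/min, and insulin
sensitivity varies strongly over hours, so nurse-titrated sliding-scale
insulin is laborious and risky. Closed-loop control — a model predictive
controller (MPC) reading subcutaneous continuous glucose monitoring (CGM)
every few minutes and commanding intravenous insulin, or at low glucose 20%
dextrose — is a candidate replacement for paper-guideline titration.

`neoloop` reproduces this setting entirely in silico: a virtual cohort with
the demographics of such a trial, a glucose–insulin compartment model with
stochastic insulin sensitivity, a CGM error/calibration model, the adaptive
MPC controller, a reconstructed guideline comparator, covariate-adaptive
randomisation, and the glycaemic outcome statistics. The virtual trial runs
both arms over a prespecified 48–72 h intervention window inside 160 h of
monitoring and summarises time in the 4.0–8.0 mmol/L target range, the
wider 2.6–10.0 band, hyperglycaemia (> 10.0) and hypoglycaemia (< 2.6).

## The virtual patient

The physiology module is a Hovorka-family two-compartment glucose model
with remote insulin action, adapted to the intravenous route used in
neonatal intensive care. Per kg of body weight, with glucose masses $q_1$
(accessible) and $q_2$ (non-accessible, mg/kg), plasma insulin $I$ (mU/L),
remote insulin action $x$ (min$^{-1}$) and interstitial glucose $G_{isf}$
(mmol/L):

$$
\begin{aligned}
\dot q_1 &= u_G + \mathrm{EGP}(x) - F_{01} - s(t)\,x\,q_1
             - k_{12} q_1 + k_{21} q_2\\
\dot q_2 &= k_{12} q_1 - k_{21} q_2\\
\dot I   &= u_I / V_I - k_e I\\
\dot x   &= k_a (S_I I - x)\\
\dot G_{isf} &= (q_1 / (V_G \cdot 18.016) - G_{isf}) / \tau_{isf}
\end{aligned}
$$

where $u_G$ sums maintenance dextrose, 20% dextrose rescue
(1 mL/kg/h of 20% dextrose $=200/60$ mg/kg/min) and trophic-feed
carbohydrate, and EGP is suppressed linearly in $x$, vanishing at
$x_{egp}$. Clinical neonatal closed-loop controllers do not publish their
compartment models, so this structure is this package's own documented
stand-in from the same model family.

Defaults (all configurable, none a clinical measurement): $V_G = 1.6$
dL/kg, $F_{01} = 2.5$ and $\mathrm{EGP}_0 = 4$ mg/kg/min, insulin
half-life 10 min ($k_e = \ln 2/10$), $k_a = 1/40$ min$^{-1}$,
$V_I = 0.12$ L/kg, $\tau_{isf} = 10$ min, $x_{egp} = 0.05$ min$^{-1}$.
Baseline sensitivity $S_I$ is log-normal across infants with median
$5\times10^{-4}$ min$^{-1}$ per mU/L — one quarter of a term reference of
$2\times10^{-3}$, reflecting extreme prematurity — and between-infant CV
50%. These choices are mutually calibrated: holding 6 mmol/L under an
8.4 mg/kg/min dextrose load then requires ≈ 0.04 U/kg/h of insulin, the
median dose such infants actually receive.

Within an infant, the sensitivity multiplier $s(t)$ (median 1) follows a
log-Ornstein–Uhlenbeck process, the package's model of "notoriously
variable" insulin sensitivity. Its `volatility` parameter is the CV the
diffusion would accumulate over 24 h without mean reversion (default 1.0)
and `reversion_time` defaults to 6 h, giving a stationary within-infant CV
of ≈ 30% (`sensitivity_stationary_cv(1, 360)`). The exact OU transition is
used, so the step size does not bias the process.

A deliberate consequence of the chosen utilisation form ($F_{01}$ constant,
insulin-mediated clearance only): with insulin off, glucose rises quickly
under full nutrition, and there is no glucose-dependent (insulin-
independent) clearance or endogenous insulin secretion to bound it. The
model is therefore most faithful in the 3–12 mmol/L range where the
controllers operate; untreated hyperglycaemic plateaus are exaggerated.

## Sensing

The CGM applies a per-sensor gain (log-normal, 5% SD), linear drift
(uniform ±2%/h) and multiplicative log-normal noise (mean 1, CV 7%) to
interstitial glucose, quantised to the clinically displayed 0.1 mmol/L.
No CGM accuracy statistics are reported for this population, so these are
typical figures for the sensor generation, shipped as defaults.
Calibration against a point-of-care meter reading (unbiased Gaussian
error, SD 0.3 mmol/L) rescales the gain so the post-calibration reading
equals the reference; gains are clamped to [0.5, 2]. Ward practice
calibrates every 12 h, the closed loop every 6 h. Sensor dropouts arrive
as a Poisson process (one per 72 h) with lengths uniform up to 210 min,
the longest signal loss such a trial reports.

## The controller

The MPC runs on a 15-min cycle and is initialised from the baby's weight
alone; nutrition is never disclosed to it. It carries an internal copy of
the compartment model at nominal (population-median) parameters and adapts
two quantities:

* **`d_fast`** — a rapidly changing glucose-flux correction (mg/kg/min,
  time constant 30 min). Each ingested reading's innovation is converted
  to the flux that would explain it and blended in; because the controller
  is nutrition-blind, `d_fast` also carries the entire dextrose load.
  On the first reading the observer is initialised stationary at the
  observed glucose under the running insulin rate, so adaptation starts
  from "the baby is steady where we find it" rather than from the
  setpoint.
* **`b_slow`** — a slowly changing estimate (time constant 6 h) of the
  basal insulin rate maintaining normoglycaemia, pulled toward the rate
  implied by the internal model plus its current flux correction.

Insulin is chosen by exhaustive grid search over every deliverable rate in
[0, 0.5] U/kg/h at the pump resolution (0.01 U/kg/h at the closed-loop
5 U/kg per 50 mL dilution), minimising the squared deviation of the
predicted 90-min trajectory from the 6.0 mmol/L reference, weighted 4-fold
below 4.0 mmol/L. The horizon is short enough that grid search is exact
and oracle-testable; ties go to the lower rate. Clinically deployed controllers of this family do not publish their cost
functions, gains or caps, so these are explicit design choices of this
package.

Dextrose rescue inspects the predicted minimum over minutes 30–40 under
zero insulin: below 3.5 mmol/L it returns the smallest grid rate
(≤ 1.0 mL/kg/h, step 0.01) lifting that minimum above 4.0, and takes
priority — insulin is forced to zero whenever dextrose runs, so no action
ever mixes the two. As a further safety rule, insulin is withheld whenever
the 40-min predicted minimum under the chosen rate falls below 4.0. If the
sensor fails, hourly blood-glucose values sustain dosing for up to 4 h, at
which point the controller holds the last rates and raises an alarm
(dosing on no data was ruled out); advice continues every 15 min
throughout.

A practical note on the cost shape: because the sub-4 penalty is heavy and
intravenous insulin in this model is potent, the cost-optimal dose
saturates at the 0.5 U/kg/h cap only when hyperglycaemia is too severe to
correct within the horizon; ordinarily the optimum is interior, which is
the behaviour the asymmetric design intends.

## The comparator

The guideline arm reconstructs nurse-executed titration from the absolute
sensor glucose and its trailing one-hour least-squares trend: start
0.02 U/kg/h above 10 mmol/L (unless already falling fast), ±50% steps,
stop below 4.0, stop plus a dextrose review below 3.5. No unit's
actual guideline document is shipped here, so this table is an explicit
reconstruction provided as an editable configuration;
its quantitative behaviour is deliberately *not* asserted against the
clinical control arm's numbers — only the direction and size of the
between-arm contrast is used. Evaluations run hourly plus at
threshold-crossing alarms; spot blood-glucose checks arrive at ~5.5/day.
On the ward the 25 U/kg per 50 mL syringe makes the deliverable dose grid
five times coarser (0.05 U/kg/h), so small commanded rates may round to
zero until escalation — one reason coarse titration controls poorly.

## Trial orchestration and randomisation

Each infant is simulated at 1-min physiology steps with 5-min CGM
sampling; both arms run the guideline outside the half-open [48 h, 72 h)
window (so the closed-loop arm emits exactly 96 MPC actions). Arms are
assigned by Pocock–Simon minimisation on gestational age
(< 26 / 26–28 / > 28 wk) and birth weight (< 750 / 750–1000 / ≥ 1000 g) —
cut-points are not reported by the study, so these clinically conventional
strata are the package default and configurable. Assignment goes
deterministically to the arm minimising the summed post-assignment
category imbalance, ties by seeded coin flip.

A known limitation, verified here by enumeration: *sequential*
minimisation cannot guarantee a final per-category imbalance of at most 1.
If the gestational-age category of an arriving infant is one ahead in one
arm while its weight category is one ahead in the other, either choice
pushes some category to 2; about a quarter of seeds end an n = 20
assignment with a worst-category imbalance of 2. The audit
(`assignment_imbalance()`) reports this honestly rather than hiding it.

Runs starting mid-protocol (the window-only surrogate below) initialise
each infant at the steady state matching a baseline sensor glucose drawn
log-normal with median 8 mmol/L — anchored to the baseline row of such
trials — standing in for the preceding 48 h of guideline management.
Maintenance dextrose is drawn per infant from N(8.4, 1.5) mg/kg/min;
40% of infants receive minimal trophic feeds; protein and lipid are
recorded but metabolically inert. Day-boundary fluid changes that
transiently perturb delivered dextrose can be switched on
(`protocol(fluid_change = TRUE)`); they default off so that controller
behaviour is isolated from care events.

## Outcomes

Time-in-band metrics are sample-hold percentages of CGM readings — target
band inclusive ([4.0, 8.0]), hyperglycaemia strict (> 10.0), hypoglycaemia
strict (< 2.6) — matching printed clinical inequalities and keeping bands
non-overlapping at the edges. Hypoglycaemia episodes are maximal runs of
readings below 2.6 mmol/L lasting at least 10 min (two consecutive 5-min
readings, suppressing single-sample noise). Summaries use mean/SD (n − 1)
and type-7 median (IQR); between-arm tests are Mann-Whitney U (exact by
enumeration when min(n) ≤ 8 without ties, otherwise normal approximation
with tie and continuity corrections) and the pooled-variance t test, with
0.05 significance and no multiplicity adjustment, as in the trial
analyses this mirrors.

## Problem sizes, numerics, determinism

The surrogate trial (`surrogate_trial()`) runs 20 infants (≈ 10/arm) over
the 24-h window for five seeds — the study's own scale — in well under a
minute per seed; the full 160-h protocol takes ≈ 2 s per infant. The
integrator is classical fixed-step RK4 (1-min physiology, 5-min controller
predictions), agreeing with a 10×-finer reference to < 10⁻⁴ mmol/L over
24 h; any state component that would go negative is clamped to zero so
long trials never abort. Every stochastic element (cohort, sensitivity
process, sensor, schedules, tie-breaks) is driven by a single seed per
run, and a repeated `simulate → analyse` pass is byte-identical.

## What passing the in-silico trial does and does not show

The generator emulates the study conditions — demographics, nutrition,
sensing cadence, calibration schedules, the intervention window — but it
cannot manufacture clinical truth: the virtual patient is the same model
family the controller uses internally (with individual parameters,
stochastic sensitivity and nutrition hidden from it), real sensor error
structure in this population is unreported, counter-regulatory hormones,
inotropes and sepsis are representable only through sensitivity scenarios,
and the comparator guideline is a reconstruction. Good virtual-trial
glycaemia therefore demonstrates internal consistency and controller
robustness to the modelled disturbances, not clinical performance.
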