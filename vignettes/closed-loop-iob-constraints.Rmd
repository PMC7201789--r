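---
title: "Methods: dynamic insulin-on-board constraints in a hybrid closed loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic insulin-on-board constraints in a hybrid closed loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apsafe)
```

## The problem

Hybrid artificial-pancreas (AP) systems for type 1 diabetes close the loop
between a continuous glucose monitor (CGM) and an insulin pump, with the
patient still announcing meals. Because subcutaneous insulin acts far more
slowly than meal glucose appears, an aggressive controller stacks insulin
during the postprandial rise and pays for it with late hypoglycemia. A common
defence is to bound the *insulin on board* (IOB) — insulin delivered but still
active — below a constraint $\overline{IOB}$ enforced by an outer safety
layer. The constraint's value is the crux: too low and hyperglycemia is never
corrected; too high and the layer never engages. `apsafe` implements a control
stack in which that constraint is tuned *dynamically* by a rule-based (DRB)
algorithm — a basal-profile-derived baseline while fasting, and a transient,
glucose-triggered raise after meals — together with everything needed to
exercise it: the inner PD controller with insulin feedback, the sliding-mode
safety layer, a surrogate virtual-patient cohort, a scenario engine and CGM
outcome metrics.

## The control stack

**IOB estimator.** Two compartments with a single rate constant
$K_{DIA}$ (default 0.013 min$^{-1}$):
$$\dot C_1 = u_d - K_{DIA} C_1,\qquad
  \dot C_2 = K_{DIA}(C_1 - C_2),\qquad
  \widehat{IOB} = C_1 + C_2 .$$
Boluses are impulses into $C_1$. Under a constant rate $u$ the estimate
settles at $2u/K_{DIA}$. The default integrator is a fixed-step explicit Heun
update at 1-min substeps (pump resolution); a closed-form update of the
linear system is available as the `exact` backend and serves as the
integration oracle in the tests. Plain first-order Euler was rejected: its
relative error on transient-dominated day-long traces is a few tenths of a
percent and grows without bound on pure bolus decay, while Heun tracks the
closed form to ~0.05% and preserves the exact steady state.

**PD controller with insulin feedback.** The inner loop commands
$$u_{pd} = K_p\left[(G - G_{rf}) + T_d\,\dot G\right],\qquad
  u_d = \max\!\big(0,\; u_{pd} + u_{basal} - \gamma\,\hat I_p\big),$$
with $K_p = TDI/2250$ U/min per mg/dl, $T_d = 90$ min, reference
$G_r = 100$ mg/dl and insulin-feedback gain $\gamma = 0.42$. Two
interpretation choices deserve emphasis:

* *Sign convention.* The control law is implemented so that glucose **above**
  the reference produces **positive** insulin action. Only with this
  orientation does raising the conditioned reference $G_{rf}$ cut insulin,
  which is the entire mechanism by which the safety layer acts.
* *Insulin feedback.* $\hat I_p$ is the estimated deviation of
  plasma-proximal insulin from basal steady state, produced by a
  two-compartment deviation chain driven by $u_d - u_{basal}$ (boluses enter
  as impulses). Its rate constant defaults to 0.05 min$^{-1}$ — a ~20-min
  plasma-insulin time scale. With the absorption-scale constant
  (0.013 min$^{-1}$) the suppression lags more than an hour behind delivery
  and cannot restrain a postprandial burst; with the faster constant the term
  behaves like beta-cell suppression and keeps even the unconstrained
  controller bounded (oscillatory and hypo-prone, but not divergent). Both
  the gain and the rate are configurable.

**Meal bolus.** An announced meal of $M_{CHO}$ grams triggers the augmented
feed-forward bolus
$$u_{bolus} = \frac{M_{CHO}}{I2C} + \frac{G - G_r}{CF}
  + \int_t^{t+M_{CHO}} u_{basal}\,\frac{dt}{60},$$
i.e. the carb dose, a correction term, and the basal insulin scheduled over
the next $M_{CHO}$ minutes. The correction may be negative; the total is
clamped at zero (the pump cannot withhold already-scheduled insulin at a
negative dose). The deliberate augmentation violates the IOB constraint at
once, engaging the safety layer and suspending further delivery while the
bolus acts.

**SAFE layer.** A sliding function
$\sigma = (\widehat{IOB} - \overline{IOB}) +
 \tau(\dot{\widehat{IOB}} - \dot{\overline{IOB}})$
(with $\tau = 10$ min) feeds a switching law $\omega = W\,[\sigma > 0]$
($W = 350$ mg/dl) and a first-order filter
$\dot G_{rf} = -\lambda(G_{rf} - G_r) + \omega$. The table of published
parameters prints $\lambda$'s unit as minutes; the filter equation requires a
rate, so it is implemented as $\lambda = 0.1$ min$^{-1}$. The limit
$\overline{IOB}$ is piecewise constant (every change is a step), so its
derivative term is identically zero at the sampling instants.

*Discretisation.* The CGM and the glucose derivative are sampled every 5 min,
and the DRB rules run at that cadence (they act on BG readings). The
switching law, filter, PD arithmetic, insulin feedback and the commanded
delivery, however, are evaluated every internal minute. The layer is a
continuous-time sliding-mode design: evaluated only at the CGM period, a
single sample's delivery (up to $5 u_d$ units) can overshoot the constraint
by a bolus-sized amount before the next check, and $\omega = W$ held for
whole 5-min blocks winds the filter toward $G_r + W/\lambda$ (≈3600 mg/dl),
over-suppressing for an hour after release. At the 1-min internal step the
loop chatters along $\sigma \approx 0$ as the design intends, and the mean
delivery on the surface settles near $K_{DIA}\overline{IOB}/2$ — for the
fasting limit below, exactly $K_{IOB}$ times the programmed basal rate.

## The DRB tuner

**Fasting baseline.** From the patient's open-loop basal profile,
$$\overline{IOB}_{bl}(t) = K_{IOB}(t)\,\frac{2\,u_{basal}(t)}{60\,K_{DIA}},$$
with $u_{basal}$ in U/h — $K_{IOB}$ times the steady-state IOB of the
programmed basal rate, so $K_{IOB} = 1$ reproduces open-loop insulin
exposure exactly. $K_{IOB}$ is 1.3 in the daytime window (06:00–23:00) and
1.1 at night (23:00–06:00), applied as a step change by local clock.

**Postprandial rules.** On a meal announcement the tuner records the meal
time and the evaluation delay $T_{IOB} = 1.5\,M_{CHO}$ minutes (45 g →
67.5 min), using the *announced* grams — the controller cannot know the true
ones. Until $T_{IOB}$ elapses the limit stays at the baseline. From then on,
at each CGM sample: the first time BG exceeds the trigger threshold
(150 mg/dl), the limit is raised to
$\max(\widehat{IOB}(t-1), \overline{IOB}_{bl})$ — the previous-sample IOB
estimate or the baseline, whichever is larger — and frozen; a per-meal flag
guarantees a single raise. The raised limit is held while BG stays above the
release threshold (140 mg/dl) and released the first sample at or below it,
closing the window. Decisions taken where the rule set leaves the behaviour
open:

* The trigger check repeats every sample until the window resolves; a window
  in which BG never exceeds 150 closes the first time BG falls to 140 or
  below. If BG lingers in (140, 150] indefinitely the window stays open with
  the limit at baseline — harmless, since the baseline is what a closed
  window would apply anyway.
* The threshold pair is assigned raise = 150, release = 140 (the raise rule
  fires when BG is *greater than* its threshold, the release when BG
  *returns below* the other).
* A meal announced during an active window resets the window to the new meal
  and clears the raise flag.

**Fixed comparator.** The clinically validated fixed constraint is computed
offline per patient: from the basal steady state, inject the augmented 60-g
bolus (carb dose plus the next hour of basal) and read the estimate 90 min
later with delivery at zero. Lacking a published reference clock time, the
package evaluates it at 12:00.

## The surrogate virtual patient

The licensed simulator used in the original evaluation is not available, so
the cohort is a surrogate minimal model — deliberately public and simple,
chosen to exercise every controller pathway rather than to reproduce any
proprietary cohort's numerics:

$$\begin{aligned}
\dot G &= -(p_1 + X)\,G + p_1 G_b + \tfrac{f\,k_{abs}}{V} Q_2
          + k_{cr}\,(G_{cr}-G)^+ ,\\
\dot X &= -p_2\big(X - S_I(t)\,(I_p - I_{p,b})\big),\\
\dot I_p &= k_{sc} I_{sc,2} - k_e I_p,\qquad
\dot I_{sc,1} = u_d - k_{sc} I_{sc,1},\quad
\dot I_{sc,2} = k_{sc}(I_{sc,1} - I_{sc,2}),\\
\dot Q_1 &= -k_{emp} Q_1,\qquad \dot Q_2 = k_{emp} Q_1 - k_{abs} Q_2 .
\end{aligned}$$

Meals are impulses into the stomach $Q_1$; the two-compartment gut makes
glucose appearance ramp up and peak tens of minutes after ingestion (a
single-compartment gut puts the peak appearance at $t=0^+$ and produces
unphysiological >5 mg/dl/min rises). The counterregulatory term
$k_{cr}(G_{cr}-G)^+$ (defaults 0.04 min$^{-1}$ below 75 mg/dl) is a crude
stand-in for the hormonal defence against hypoglycemia, without which
insulin stacking drives the model unrealistically deep. Glucose uses an
exponential (positivity-preserving) update; the linear states use 1-min
explicit Euler.

**Intra-patient variability** mirrors the study conditions: the insulin
sensitivity is modulated by a 24-h sinusoid of amplitude 30% with one
uniform random phase per patient per simulation,
$q(t) = q_0 + 0.3\,q_0 \sin(2\pi t/1440 + 2\pi\,\mathrm{rand})$, and at every
meal the gut and subcutaneous absorption rates are independently rescaled by
uniform draws in $[0.7, 1.3]$, held until the next meal.

**Cohort generation** samples, per patient: basal glucose
$G_b \sim U(110, 140)$ mg/dl; a four-segment basal profile around a base
rate $U(0.6, 1.4)$ U/h; $k_{sc} \sim U(0.02, 0.03)$,
$k_{emp} \sim U(0.025, 0.045)$, $k_{abs} \sim U(0.008, 0.015)$ min$^{-1}$;
volume $V \sim U(120, 180)$ dl; $p_2 \sim U(0.025, 0.04)$ min$^{-1}$. The
therapy block is derived from the sampled physiology: daily basal is taken
as half of TDI, the carb ratio by the 450 rule ($I2C = 450/TDI$) and the
correction factor by the 1700 rule ($CF = 1700/TDI$). Internal consistency
is imposed rather than fitted: $S_I = CF\,k_e/G_b$ makes a 1-U bolus drop
glucose by roughly the correction factor, and $p_1$ is drawn as
$U(1.2, 1.8)\times 1.3\,S_I I_{p,b}^{max}$ so the insulin-free equilibrium
is finite (a bounded 200–400 mg/dl ceiling under insulin deprivation). The
absorption ranges were chosen once so that an open-loop 60-g meal with a
standard bolus produces a postprandial excursion of roughly 60–120 mg/dl,
the range reported for adult cohorts; they are not adjusted per scenario.
Patients failing to hold basal glucose within ±10 mg/dl over 24 h under
their own basal schedule are rejected and resampled. Everything is
deterministic given the master seed, with per-patient and per-meal
substreams derived by integer hashing, independent of the treatment arm —
so arms are compared pairwise under identical disturbances.

**What the surrogate does not emulate:** carbohydrate-composition effects
(mixed-meal model libraries are replaced by the per-meal parameter
perturbation), renal clearance and dawn-phenomenon asymmetries, CGM sensor
artefacts (noise is optional additive Gaussian, default off), and the
licensed simulator's validated population distributions. Passing the
cohort-level tests therefore demonstrates the *mechanisms* — IOB
containment, hypoglycemia reduction by dynamic limits — not clinical
performance on real patients.

## Scenarios and metrics

Three stress scenarios are provided: A (7 days, one 60-g meal/day between
10:00 and 16:00, exact announcement; dynamic vs fixed limit), B (45 days,
one meal/day of 40–120 g between 08:00 and 19:00 — the gram law over the
range is not stated in the source description; uniform per day was chosen),
and C (14 days; 45 g at 07:30, 90 g at 13:00, 50 g at 18:30, announced with
uniform ±15% carb-counting error; all four arms, including baseline-only and
unconstrained).

Metrics follow consensus CGM reporting: mean glucose; time in 70–140 and
70–180 mg/dl (closed intervals) and strictly below 70/54 or above 180 —
boundary conventions the source leaves implicit; hypoglycemic events (≥15
consecutive minutes strictly below 70 mg/dl, a run ending at the first
sample at or above it, attributed to the day/night window of its onset);
4-h postprandial excursion (peak minus premeal) and controller-delivered
insulin after the bolus; GMI $= 3.31 + 0.02392 \times$ mean glucose; and
CVGA zones from each patient-day's (min, max) pair on the standard grid
(axis breakpoints 110/90/70/50 on minima and 110/180/300/400 on maxima,
values clamped at the ends; A is the best-in-both cell, E the worst corner).
Cohort aggregation is median (25th–75th percentile), with the day window
06:00–23:00 and night 23:00–06:00, matching the day/night gain schedule of
the fasting baseline.

## Problem sizes, numerics, and limitations

The package's own study configuration is 10 surrogate patients × 14 days ×
4 arms × 5 seeds for the cohort-level safety properties (a few minutes on
one CPU), with the plant on a 1-min internal step and the controller at
5 min. These sizes give stable orderings of the arm-level outcomes (total
and night-time hypoglycemic events, daytime hyperglycemia) while remaining
desk-scale; published cohort-level outcome values are deliberately not
reproduced numerically, since they depend on a licensed simulator and its
specific adult cohort.

Degenerate inputs are handled conservatively: zero-gram announcements are
rejected; a zero basal profile yields zero baselines (the layer then only
ever permits bolus insulin); non-finite plant states abort a run with a
recorded per-run failure rather than silently continuing; overlapping meals
reset the postprandial window to the latest meal — behaviour for overlapping
meals is unspecified in the source and flagged here as a design choice.

Known limitations: the insulin-feedback internals are a reconstruction (the
original estimator's model and units are not recoverable); the surrogate
plant is not a validated population model; exercise, meal-announcement
omissions, and dual-hormone control are out of scope.
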