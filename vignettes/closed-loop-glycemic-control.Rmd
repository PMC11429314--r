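---
title: "Closed-loop glycemic control: the virtual patient, the sensor and meal models, and the PPO controller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop glycemic control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyco)
```

## The problem

In type 1 diabetes the pancreas produces no insulin, and blood glucose must
be regulated by exogenous insulin delivery. An *artificial pancreas* closes
the loop between a continuous glucose monitor (CGM), an insulin pump and a
control algorithm. This package is an in-silico testbed for such control
algorithms: a virtual-patient simulator with realistic sensing and meal
disturbances, wrapped as a reset/step reinforcement-learning environment,
plus a proximal policy optimization (PPO) controller and the standard
evaluation metrics of the field (time in range, RMSE from reference,
control variability grid analysis).

Everything is simulated; no human data are involved. The 17 virtual-patient
parameter sets (10 subjects, some with separate daytime/night-time rows)
ship with the package (`ivp_patients()`).

## The virtual patient

The identifiable virtual patient (IVP) model is a four-state ODE system:
blood glucose $G$ (mg/dL), insulin effectiveness $I_{EFF}$ (1/min), plasma
insulin $I_P$ and subcutaneous insulin $I_{SC}$ (both $\mu$U/mL):

$$\dot G = -(GEZI + I_{EFF})\,G + EGP + RA(t)$$
$$\dot I_{EFF} = -p_2 I_{EFF} + p_2 S_I I_P$$
$$\dot I_P = -( I_P - I_{SC})/\tau_2$$
$$\dot I_{SC} = -I_{SC}/\tau_1 + \frac{u(t)}{\tau_1 C_I}$$

`EGP` is endogenous glucose production (mg/dL/min), `GEZI` the
insulin-independent glucose clearance (1/min), $S_I$ insulin sensitivity,
$C_I$ insulin clearance (mL/min), and $\tau_1, \tau_2, p_2$ the insulin
transport/action kinetics. Meal carbohydrates $d_k$ grams appear in the
glucose space through a gamma kernel per meal,

$$RA(t) = \sum_k \frac{1000\,d_k}{V_G \tau_D^2}\,(t-\zeta_k)\,
  e^{-(t-\zeta_k)/\tau_D},$$

which integrates to $1000 d_k / V_G$ — the whole meal eventually appears.

Choices the model description leaves open, and what this package does:

* **Insulin units.** The pump interface speaks U/h; the equations consume
  $\mu$U/min (`insulin_Uh_to_uUmin()`, factor $10^6/60$), which makes
  $u/(\tau_1 C_I)$ dimensionally $\mu$U/mL/min.
* **Meal absorption constant.** $\tau_D$ has no identified per-patient
  value; the package uses a global default of 40 min (a typical
  mixed-meal absorption time scale), configurable per meal.
* **Integrator.** Fixed-step classical RK4 at $dt = 1$ min (5 sub-steps per
  control interval). The system is non-stiff at these rates; halving $dt$
  changes a 24-h trajectory by well under 0.1 mg/dL (tested), and a fixed
  step keeps trajectories bit-reproducible. Negative concentrations are
  clamped to zero after each sub-step as a numerical safety net; with
  physiological inputs the clamp never activates.
* **Initial conditions.** $G(0) = 120$ mg/dL, insulin compartments at the
  steady state of a configurable basal rate (default 0). The simulated
  insulin chain under constant infusion matches its matrix-exponential
  closed form to below $10^{-6}$ relative error (tested).

## The CGM layer

CGM sensors read interstitial, not blood, glucose, with a lag and
coloured noise. The testbed models the lag as one extra compartment,
$\dot{IG} = (G - IG)/\tau_{IG}$, integrated jointly with the patient by the
same RK4 scheme, and the noise as a second-order autoregressive process on
the 5-min sample grid,

$$v(t) = \alpha_1 v(t-T_s) + \alpha_2 v(t-2T_s) + w(t), \qquad
  w \sim N(0, \sigma^2),$$

with the reading $CGM(t) = \max(IG(t) + v(t), 0)$. Sensor drift is
deliberately excluded (it would bias long training runs), and calibration
imprecision is folded into $\sigma$ rather than modelled as a separate bias.

The noise constants are not part of the identified patient cohort; the
package defaults are $\tau_{IG} = 10$ min, $\alpha_1 = 1.23$,
$\alpha_2 = -0.3995$, $\sigma = 1$ mg/dL — a slowly-decorrelating AR(2)
comfortably inside its stationary region (stationarity is enforced at
construction). All properties of the sensor layer are parametric in these
values; `ar2_stationary_moments()` gives the closed-form stationary
variance and lag-1 autocorrelation used to validate the simulated process.

## The meal generator

Each simulated day draws up to six meals: three main meals appearing with
probability 0.95 and three snacks with probability 0.3 (3.75 expected meals
per day). Meal times are truncated-normal within slot windows (breakfast
around 07:00, lunch around 12:00, dinner around 18:00, snacks between);
amounts are normal with body-weight-scaled means (0.7/1.1/1.25 g/kg for
the main meals, 0.15 g/kg for snacks) and 15 % coefficient of variation,
floored at zero and rounded to whole grams. Multi-day episodes concatenate
independent days offset by 1440 min.

Two normalisations of the published constants were needed: the appearance
test compares a uniform draw against probabilities on the $[0,1]$ scale
(the printed pseudo-code mixes a 0–100 draw with probabilities in
$[0,1]$), and truncated-normal sampling is done by exact rejection from the
parent normal (cheap at these wide bounds). The generator emulates the
*timing and size* statistics of realistic meal patterns; it does not model
macronutrient composition, meal announcements, or day-to-day habit
correlation — so tests passing under this generator say nothing about
announced-meal or correlated-behaviour scenarios.

## The closed loop

The environment couples patient, sensor, meals and a reward into 5-min
control steps (288 per day, 10-day training episodes by default):

* observation: $(CGM/1000$ clipped to $[0,1]$, $(a_{prev}+1)/2)$ — the
  previous reading and the previous action;
* action: $a \in [-1, 1]$ mapped affinely to an infusion rate in
  $[0, 25]$ U/h, held constant over the step (pump semantics);
* reward: one of four scores of the *noisy* CGM reading (the
  controller-facing signal; a flag switches to true glucose for ablations):
  the smooth bump supported on (90, 180) with peak $e^{-1}$ at 135 mg/dL,
  the piecewise $-1/{+1}/0$ hypo/in-range/hyper score, a cosine shaped
  score on (0, 300), and the Ricker ("Mexican hat") wavelet centred at
  140 mg/dL. The formulas are implemented exactly as published; note their
  peaks sit at 135–141 mg/dL, not 120 (the surrounding text's nominal
  target) — the formulas, being the operational definition, win.
* termination: optional CGM bounds (default (50, 400) mg/dL when enabled);
  the final configuration disables termination and always simulates the
  whole horizon, which matched the better-performing published setting.
  The first step's "previous action" is $-1$ (no insulin yet).

## The PPO controller

The agent is a clipped-surrogate PPO actor-critic with separate towers
(no parameter sharing): Linear+ELU blocks, seven for the policy and five
for the value net, 2048 units per block at full scale, with a last block of
64 units and a terminal linear layer to a scalar. The action head is a
squashed Gaussian: the network emits a pre-squash mean, exploration
samples $z \sim N(\mu, \sigma)$ with a learned state-independent
$\log\sigma$ (initialised at 0), and the executed action is $\tanh(z)$ —
strictly inside $(-1, 1)$, so the policy output is always a valid insulin
fraction of the pump range. Evaluation deploys the *mean executed action*
$E[\tanh(z)]$ (Gauss–Hermite quadrature): the deterministic controller
that delivers the average dose the stochastic policy delivered in
training. While the exploration scale is still large this differs
materially from the median action $\tanh(\mu)$, and it is the faithful
deterministic equivalent of what was actually evaluated by the reward
during training. Training follows the published
hyperparameters (learning rate $3\times10^{-4}$, 288-step rollouts,
minibatch 64, $\gamma = 0.99$, GAE $\lambda = 0.95$, clip 0.2, entropy
coefficient 0, value coefficient 0.5, gradient-norm clip 0.5), with Adam
and 10 epochs per update (the customary defaults of the library lineage the
published agent built on; neither is stated). The best checkpoint is the
one maximising the trailing mean episode reward over the last 100 episodes.
Time-limit truncations bootstrap through the value function (the episode
ends by the clock, not in an absorbing state).

The squashed head deserves emphasis. An unbounded Gaussian whose samples
are merely clipped by the actuator — a common default — is pathological
here: every pre-clip sample below $-1$ produces the same zero insulin
dose, so the boundary censors the action distribution asymmetrically and
nothing stops the mean from drifting arbitrarily far outside the action
range (we observed means beyond $-5$ within $2\times10^5$ steps);
exploration noise then does the dosing while the deterministic evaluation
policy degenerates to "no insulin". Squashing the *sample* through $\tanh$
removes both problems: there is no censoring atom (every sample maps to a
distinct dose) and the executed action cannot leave $(-1,1)$ — matching
the contract that the policy output lies between $-1$ and $1$. The
$\tanh$ Jacobian of the density is parameter-free and cancels in the PPO
probability ratio, so the clipped surrogate operates on the pre-squash
Gaussian unchanged. Two numerical safeguards accompany it: the log
probability ratio is clamped at $\pm 20$ before exponentiation (far
off-policy samples otherwise overflow), and the learned log standard
deviation is kept in $[-5, 2]$.

The analytic surrogate gradient is verified against central finite
differences on toy batches to $10^{-4}$ relative error (tested), and the
whole update loop is validated on a synthetic one-step control task where
the policy mean must converge to a known optimum.

### Desk-scale training

The published budget is $5\times10^7$ environment steps per patient —
weeks of CPU per parameter set. The package's own desk-scale configuration,
used by the test suite and the acceptance script, is a faithful small-scale
replica: the same topology at width 64, one mid-weight patient (row 10,
77 kg), the piecewise reward, and a $2\times10^5$-step budget. Two
adjustments make the published recipe meaningful at this scale. First,
training episodes are one day long, matching the one-day test horizon:
with the full recipe's 10-day episodes a $2\times10^5$-step budget yields
only ~70 episodes, so the trailing-100-episode checkpoint window
degenerates into a cumulative mean that rises monotonically and always
elects the final policy — even a collapsed one; with ~700 one-day episodes
the checkpoint rule works as designed (and matched train/test duration is
also what the underlying preliminary experiments found to work best).
Second, the squashed action head described above is essential here;
without it the boundary-censoring pathology consumes small budgets
entirely.
Full-budget replication ($5\times10^7$ steps per patient, width 2048) is
out of desk scope by design; the desk-scale run demonstrates that the
controller learns — it beats the zero-insulin and random baselines on
held-out seeded days — not that it reproduces full-budget control quality.

## Metrics

Per evaluated day: occupancy of the five glucose zones ($<50$, $[50,70)$,
$[70,180]$ — the time-in-range target, $(180,250]$, $>250$ mg/dL; 70 and
180 count as in range), RMSE from 90 and from 150 mg/dL, and the CVGA point
(per-day minimum and maximum glucose, clipped to the $[50,110] \times
[90,400]$ axes) classified on the standard 3×3 grid (A best; Upper/Lower
B/C/D; E worst), with boundary membership closed on the A-adjacent side.
The published table names the zones but not the cell edges; the edges used
(110/90/70/50 on the reversed minimum axis, 90/180/300/400 on the maximum
axis) are the standard ones from the CVGA literature. Day summaries are
computed from the CGM signal by default (it is the controller-facing
signal; a flag switches to true glucose), cohort curves from true glucose.
Aggregation reports mean, SD, min, quartiles (linear interpolation, R's
default type 7; the quantile method is not stated in the source material)
and max per metric column.

The test protocol evaluates 13 one-day scenarios per patient — 10
generator-sampled days plus three predefined ones: no meals, 12 g every
hour (288 g/day), and a generated day with an extra 5 g bolus at 12 h —
over all 17 parameter sets: 221 test days. The two published descriptions
of the third scenario differ slightly; the "generated day + 5 g at 12 h"
reading is used. Random test schedules are redrawn per patient from a
patient-indexed seed (whether the published protocol shared them across
patients is not stated).

## Reproducibility and problem sizes

Every stochastic component draws from R's global RNG, so a single
`set.seed()` (or the `seed` arguments threaded through reset, training and
evaluation) reproduces a run bit-identically. The test suite validates the
simulator against closed forms (matrix-exponential insulin chain, AR(2)
stationary moments, gamma-kernel mass conservation), the generator against
its sampling statistics at $10^4$ days, the metrics against hand-computed
fixtures, and the PPO gradient against finite differences; the training
smoke tests use the width-64 desk-scale configuration described above.
`scripts/acceptance.R` reruns the full pipeline (train one desk-scale
controller, evaluate the 221-day protocol against baselines) from a single
seed.

## Known limitations

* The IVP model has no exercise, stress, circadian insulin-sensitivity or
  intra-patient variability terms; day/night differences enter only as
  separate parameter rows.
* The sensor model excludes drift, dropouts and calibration events.
* The meal generator draws days independently; real behaviour is
  correlated across days.
* Desk-scale training demonstrates learning dynamics, not the published
  full-budget control quality; closing that gap requires the
  $5\times10^7$-step budget per patient.
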