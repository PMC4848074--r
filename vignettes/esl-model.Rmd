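---
title: "Modelling joint patient and staff satisfaction in a single-server care process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling joint patient and staff satisfaction in a single-server care process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(eslqueue)
```

## The model

`eslqueue` couples three components:

1. **A patient satisfaction curve** in the waiting-time ratio
   $\Delta_p = (\text{expected} - \text{actual wait}) / \text{expected}$:
   $$S_p(\Delta_p) = a \tanh\big(b(\Delta_p - x_0)\big) + c,$$
   the expectancy-disconfirmation shape — satisfaction rises steeply around
   the expectation point and saturates for much-shorter-than-expected
   waits.

2. **A staff satisfaction curve** in the service-time ratio
   $\Delta_s = (\text{actual} - \text{ideal service}) / \text{ideal}$:
   $$U(\Delta_s) = a_1 \tanh(b_1 \Delta_s)
     + a_2 \Delta_s \tanh(b_2 \Delta_s) + c,$$
   with defaults $(0.25, 1.72, 0.76, -4.43, 0.95)$. The first term is a
   gentle odd reward for not being rushed; the second, with $a_2 \ge 0$ and
   $b_2 < 0$, is an even, non-positive, bell-shaped penalty for departing
   from the ideal in either direction; $c$ is the level at the ideal. The
   double tanh was chosen over a single tanh precisely because staff
   dissatisfaction rises both when they are rushed and when cases drag.

3. **The M/G/1 queueing link.** With Poisson arrivals at rate $\lambda$ and
   a general service-time distribution with mean $E[S]$ and squared
   coefficient of variation (SCV), the steady-state mean delay in queue is
   the Pollaczek–Khinchine formula
   $$W_q = \frac{\lambda E[S^2]}{2(1-\rho)}, \qquad
     E[S^2] = E[S]^2(1 + \text{SCV}), \quad \rho = \lambda E[S] < 1.$$
   Only the first two service-time moments matter, so arbitrary
   distributions enter through the SCV alone.

An **operating point** is one actual mean service time together with the
wait it induces, the two ratios, the two satisfaction levels, and their
weighted sum, the total satisfaction level (TSL). Swept across service
times at fixed expectation and ideal, the TSL traces the total
satisfaction curve (TSC); its maximum is the effective satisfaction level
(ESL), attained at the effective operating point (EOP). The ESL is defined
*per scenario* (fixed expected wait); `scenario_compare()` juxtaposes
scenarios without collapsing them into a single cross-scenario optimum,
because "which expectation should we set" is a policy question the
per-scenario maximum deliberately leaves open.

### Assumptions

Single server, single queue, FCFS discipline, exponential interarrival
times, service times i.i.d. from one distribution; satisfaction is driven
by time alone (communication, dignity, environment and other known drivers
are out of scope); every patient shares one expected wait, every staff
member one ideal service time. The satisfaction scale is nominally
$[0, 1]$ but **no level is ever clipped in computation**: the staff curve
is genuinely negative for extreme ratios, and truncating it would move the
TSC optimum. Display layers may clip.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| arrival rate $\lambda$ | 0.25 /h | with exponential service this makes the wait exactly 2 h when actual service = ideal = 2 h, so the default scenario is the harmonious case where a 2 h expectation can be met exactly |
| ideal service time | 2 h | the fixed ideal used throughout the expectation comparisons |
| expected wait | 2 h (compare 0.5, 2, 3) | the quantity a waiting-time target manipulates |
| weights | 0.5 / 0.5 | equal weighting of the two parties; any split summing to 1 is accepted |
| patient curve $(a, b, x_0, c)$ | (0.5, 2.5, −0.44, 0.5) | constructed, not transcribed from any survey: the source model's fitted values are not public. Chosen so $S_p(0) \approx 0.90$, $S_p \to$ just below 1 as $\Delta_p \to 1$ (the curve deliberately misses $(1,1)$: beating the expectation is rewarded slightly), and $S_p \approx 0$ by $\Delta_p = -1$ |
| staff curve | (0.25, 1.72, 0.76, −4.43, 0.95) | the published survey-fitted coefficients |
| sweep | 0.2 h to 0.95/λ, 400 points | covers utilizations up to 95% while staying comfortably stable |
| "close to maximum" threshold | 0.85 | operationalizes joint satisfiability in the expectation comparisons; configurable in the tests that use it |

Times are hours everywhere except the survey CSV, whose native unit is
minutes (converted at ingestion). Waiting time means **delay in queue,
excluding service** by default — "waiting" as time before being seen;
`wait_includes_service = TRUE` switches $\Delta_p$ to the full sojourn
time for target definitions that include service.

## The synthetic survey generator

`generate_synthetic_survey()` emulates the interview design that produced
the staff curve: 68 staff (doctors and nurses in two emergency
departments), a per-stage service-time norm for triage, first assessment
and treatment, and Likert ratings probed at 0 and ±5, ±15, ±20 minutes
from each norm. Norms are truncated-normal (triage 10 ± 3, first
assessment 20 ± 5, treatment 40 ± 10 minutes — plausible stage durations;
the source reports the design but not the norm distribution), rounded to
0.01 min so CSV round-trips are exact. Ratings are the true curve value at
$\Delta_s = \text{offset}/\text{norm}$ plus Gaussian noise
(default sd 0.05), clamped to $[0,1]$ and quantized to the nearest of the
five Likert levels $\{0, 0.25, 0.5, 0.75, 1\}$; the linear coding is a
convention, configurable for sensitivity analysis. Probes whose actual
time would be negative are dropped and counted in provenance. The offset-0
probe is a generator extension beyond the ±-design: it pins the fitted
intercept.

What the generator does *not* emulate: response styles (central tendency,
acquiescence), role or department effects, correlation between a
respondent's ratings, and the empirical category frequencies of the
original survey (unpublished). Passing recovery tests therefore shows the
fitting machinery is sound under idealized Likert measurement, not that
real interview data would be as kind.

### Floor censoring and the fitting range

The probe design creates ratios up to $\Delta_s = +2$ (a 10-minute triage
norm probed at +20 min). There the true curve is negative, but a Likert
instrument cannot score below "very dissatisfied" (level 0): the recorded
levels are **floor-censored**. Feeding those points to an uncensored
least-squares fit is a misspecification that moves the global SSE optimum
far from the generating coefficients — the fit bends its odd term into a
near-linear compensator (this is visible, not subtle: on such data the
best-fitting SSE is well below the SSE at the true parameters). The
pipeline therefore fits on $|\Delta_s| \le 1$, the bell range over which
the staff curve was originally fitted, exposed as `ratio_limit` in
`survey_to_points()` and `--ratio-limit` in the CLI. A censored-likelihood
(tobit-style) fit would use the extreme probes properly; it is out of
scope here.

With that range, a 100-seed calibration run gives a root-mean-square error
on the recovered $b_1$ of about 0.16 at noise sd 0.05 (0.15 at 0.02, 0.20
at 0.10), with single-seed errors up to ≈ 0.5. The recovery test bounds
the 20-seed RMSE at 0.35, roughly twice the calibrated value. One caveat:
between noise sd 0.02 and 0.05 the quantization half-step (0.125)
dominates both noise levels, so the error ordering between those two is
weak; the ordering against sd 0.10 is robust.

## Numerical choices

- **Fitting**: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
  analytic residual Jacobian (tanh derivatives are closed-form). Bounds
  $a_1 \in [-2,2]$, $b_1 \in (0,20]$, $a_2 \in [0,5]$, $b_2 \in [-20,0)$,
  $c \in [-1,2]$; the open endpoints at 0 are realised with a $10^{-6}$
  margin. The SSE surface is multi-modal in the slopes, so 9 starts on
  $b_1 \in \{0.5, 2, 8\} \times b_2 \in \{-0.5, -2, -8\}$ (with
  $a_1 = 0.3$, $a_2 = 0.5$, $c = \bar{y}$) are run and the best kept; ties
  within $10^{-10}$ break to the smallest parameter norm. Because
  $a\tanh(bx) \equiv (-a)\tanh(-bx)$, coefficients are reported in the
  canonical sign representative $b_1 > 0$, $a_2 \ge 0$, $b_2 < 0$.
- **ESL refinement**: grid argmax on the sweep, then Brent/golden-section
  search (`stats::optimize`, tol $10^{-6}$ h) between the argmax's grid
  neighbours; the refined value is never below the grid maximum. An
  all-flat TSC is flagged degenerate and returns its first point.
- **Staff peak**: same bracket-then-refine strategy on $[-2, 2]$; a
  maximum on the boundary means the parameters are not bell-shaped and is
  an error, not a silent answer.
- **Simulator**: the Lindley recurrence
  $W_{n+1} = \max(0, W_n + S_n - A_{n+1})$ in its vectorized
  reflected-random-walk form — exact for a single FCFS server and far
  cheaper than an event calendar; the per-customer event log (arrival,
  service start, departure) is reconstructed from the waits on request.
  Warm-up is customer-count truncation (default 10% of the run);
  replications use substream seeds derived arithmetically from the master
  seed, so adding replications never perturbs earlier ones. Lognormal and
  gamma service are parameterized from (mean, SCV) in closed form.
- **Degenerate inputs**: zero expected wait or ideal service are domain
  errors (the ratios are undefined); utilization $\ge 1$ raises an
  instability error naming the largest stable service time; constant
  fitted levels report an `NA` R² rather than a fabricated 1.

## Problem sizes

The shipped tests run the simulator at up to $2\times 10^5$ customers
$\times$ 5 replications per cell (nine load/variability cells for the
analytic cross-check) and the recovery study at 20 seeds per noise level
with 68-member surveys; the whole suite completes in well under a minute.
These sizes were chosen because the Monte-Carlo confidence intervals they
give are already an order of magnitude tighter than the effects being
checked.

## Known limitations

Single server only — no M/G/k, no networks of stations, no priorities or
reneging, no time-varying arrivals. Satisfaction is time-only and
homogeneous across patients and staff. The patient curve's parameters are
constructed defaults, not an empirical fit, so analyses that hinge on its
exact shape (rather than its monotone saturating character) should treat
them as a sensitivity knob. The resource-planning questions the ESL
naturally raises — staffing levels to operate at the ESL, admissible
demand — are not answered here.
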