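# eslqueue

Queueing-based modelling of the trade-off between **patient satisfaction
with waiting time** and **staff satisfaction with service time** in a
single-server care process, and the **Effective Satisfaction Level (ESL)**
— the operating point that best serves both parties at once.

## The problem

Waiting-time targets treat the patient side of care in isolation. But in a
queue, waiting time and service time are tied together: by Little's law and
the M/G/1 steady-state relations, the only way to shorten queues without
more capacity is for staff to spend less time with each patient. Staff have
their own sense of the *ideal* time a consultation needs, and their
satisfaction falls when they are rushed — or when cases drag past the
ideal. `eslqueue` makes that coupling explicit and asks: at which actual
service time is the *combined* satisfaction of patients and staff highest?

## The models

Two dimensionless ratios anchor everything:

- waiting-time ratio `Δp = (expected wait − actual wait) / expected wait`
  (`≤ 1`; positive means shorter-than-expected waits),
- service-time ratio `Δs = (actual service − ideal service) / ideal service`
  (`≥ −1`; negative means staff are rushed).

Patient satisfaction follows a saturating tanh curve of `Δp` (expectancy
disconfirmation: meeting the expected wait scores ≈ 0.90; beating it scores
slightly higher). Staff satisfaction follows a double hyperbolic tangent of
`Δs`, fitted from a 68-member A&E interview survey:

```
U(Δs) = 0.25 tanh(1.72 Δs) + 0.76 Δs tanh(−4.43 Δs) + 0.95
```

a bell-shaped curve peaking just past the ideal service time. The queueing
link is the M/G/1 Pollaczek–Khinchine mean wait `Wq = λE[S²] / (2(1 − ρ))`:
each candidate actual service time induces a mean wait, hence a `Δp` and a
`Δs`, hence both satisfaction levels and their weighted sum, the **Total
Satisfaction Level (TSL)**. Swept over service times this traces the Total
Satisfaction Curve; its maximum is the **ESL** and the maximizing operating
point the **EOP**.

The package also contains a discrete-event M/G/1 simulator (an independent
check on the closed forms), a synthetic Likert survey generator emulating
the interview design, and the multi-start nonlinear least-squares procedure
that recovers the double-tanh coefficients from survey data.

## Worked example

```r
library(eslqueue)

# 1. Recover the staff curve from a synthetic 68-member survey
survey <- generate_synthetic_survey(seed = 2026)
fit <- fit_double_tanh(survey_to_points(survey, ratio_limit = 1))
fit
#> Double-tanh staff satisfaction fit (1062 points, converged)
#> Staff satisfaction curve  U(Ds) = a1*tanh(b1*Ds) + a2*Ds*tanh(b2*Ds) + c
#>   a1 = 0.2653  b1 = 1.583  a2 = 0.8056  b2 = -5.974  c = 0.9788
#>   SSE 7.524   R^2 0.9100   starts tried 9
```

The generating coefficients (0.25, 1.72, 0.76, −4.43, 0.95) are recovered
to within the scatter a 5-point Likert instrument permits.

```r
# 2. Sweep the Total Satisfaction Curve for the default scenario:
#    0.25 patients/h, exponential service, ideal service 2 h, expected wait 2 h
tsc <- sweep_tsc(scenario())
tsc
#> Total satisfaction curve: 400 operating points
#>   ESL 0.9343 at actual service 1.9132 h (wait 1.7540 h, delta_p 0.1230)
autoplot(tsc)

# 3. Compare patient expectations of 0.5, 2 and 3 hours
glance(scenario_compare(scenario()))
#> # A tibble: 3 × 5
#>   expected_wait_h   esl eop_service_h eop_wait_h delta_p_at_eop
#>             <dbl> <dbl>         <dbl>      <dbl>          <dbl>
#> 1             0.5 0.707          1.13      0.449          0.102
#> 2             2   0.934          1.91      1.75           0.123
#> 3             3   0.966          2.05      2.15           0.284
```

When patients expect only a 30-minute wait no operating point satisfies
both parties (ESL 0.71, reached by rushing staff to 1.13 h consultations);
when the expectation is 2 h the optimum sits at a 1.91 h consultation —
essentially the staff ideal — with both parties near their maxima.

```r
# 4. How far is a service rushing through 1 h consultations from its ESL?
distance_from_esl(scenario(), actual_service = 1)
#> # A tibble: 1 × 2
#>   delta_tsl delta_service
#>       <dbl>         <dbl>
#> 1     0.233         0.913
```

Total satisfaction is 0.23 below the achievable maximum; staff would need
to slow down by 0.91 h per patient to reach the EOP.

A command-line wrapper over the same functions is installed at
`system.file("cli", "eslqueue.R", package = "eslqueue")` with subcommands
`mg1`, `simulate`, `gen-survey`, `fit-staff`, `sweep` and
`scenario-compare`.

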