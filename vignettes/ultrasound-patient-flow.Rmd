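---
title: "Simulating ultrasound patient flow: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ultrasound patient flow: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultraflow)
```

## The system being modeled

`ultraflow` simulates the ultrasound wing of a hospital radiology
department. Patients of three classes — outpatients, inpatients, and
emergency patients — register at a counter, are assigned to one of six
examination rooms, wait in that room's FIFO queue, undergo a setup phase
(from entering the room to the first uploaded image) followed by the
scanning phase, and depart. Waiting time is measured from registration to
room entry; no front-desk delay is modeled, so registration time equals
arrival time.

Three features make the system more than a bank of parallel queues:

1. **Sex constraints.** Prostate and scrotal scans (male patients only)
   must be performed by a male technologist; DVT scans by a technologist of
   the patient's sex. Rooms 6, 8, 10 are staffed by male technologists and
   5, 7, 9 by female technologists, a fixed 1:1 mapping.
2. **Priority rooms.** Rooms 5 and 6 are the spacious ones; an inpatient
   (emergency patient) without a sex-constrained exam is routed straight to
   room 5 (room 6) whenever nobody is *waiting* there — a busy room with an
   empty queue still receives the patient. We read "waiting" literally as
   queue length excluding the patient in service.
3. **Balance counters.** Other assignments minimize a per-room workload
   counter. The four policies (`points`, `minutes`, `random`,
   `weighted_points`) differ only in that counter; the branch structure of
   the decision tree is identical, and under `random` the argmin step
   becomes a uniform draw while the priority branches still short-circuit.

Room assignment happens once, at registration; patients never switch
queues. A consequence worth stating: each room is then an independent FIFO
single server, so a replication can be computed in one chronological pass
over arrivals — the event calendar of a general DES collapses to a Lindley
recursion per room. The test suite exploits this by checking the engine
against an independently coded Lindley recursion on single-room instances.

### The balance criterion of the `minutes` policy

The cumulative-examination-time policy balances the *realized* service
duration (setup + scan) of the patients a room has been assigned. The
realized duration is drawn at patient creation — exactly as an Arena-style
model attaches the examination time attribute when the entity is created —
so the dispatcher may legitimately use it. Slot minutes would not work as a
criterion: a slot is always 20 minutes times the slot points, so a
slot-minute counter would order rooms identically to the points counter and
the two policies could never differ, contradicting the sharply different
workload spreads the policies are known to produce. This is the one place
where we deliberately interpret "cumulative examination time" as realized
time, and it is what makes `minutes` the best-balancing (and
coarsest-to-audit) policy, with `weighted_points` a fairness-motivated
compromise between it and `points`.

Counters are incremented **at assignment**, not completion — the dispatcher
must see load it has already committed — and accumulate continuously over
the whole replication (no daily reset; the compressed clock has no real day
boundaries).

## Clock and calendar

Time is continuous and compressed. One effective day is
`480 × 93.2% = 447.36` minutes: the department's 8-hour weekday schedule
scaled by the share of examination time spent on the body parts in scope.
A replication measures `5 × 447.36 = 2236.8` minutes after a 5600-minute
warm-up (replication length 7836.8 minutes). There is no explicit lunch
break or overnight gap; day boundaries exist only for reporting. The
warm-up length can be re-derived with `warmup_scan()`, which plots running
utilization per room over a 7200-minute horizon; the curve is flat well
before 5600 minutes.

Warm-up clearing: patients arriving before the cut are excluded from counts
and waiting-time averages, but the residual service they occupy counts
toward busy time — utilization is busy time over the measured window
`[5600, 7836.8]`. Exams in progress at the horizon run to completion and
are counted as examined; their busy time counts only up to the horizon.

## Random variates and streams

Distribution specifications are declarative (`uf_dist`), covering
triangular, offset Beta (`offset + scale·Beta(a1, a2)`), offset Weibull
(`offset + Weibull(shape, scale)`, Arena's `(scale, shape)` parameter
order, mean `offset + scale·Γ(1 + 1/shape)`), exponential, deterministic,
continuous piecewise-linear empirical CDFs, and finite mixtures. Empirical
laws are continuous (Arena CONT style) rather than discrete resampling,
since they stand in for continuous inter-arrival and service data.
`dist_mean()` is closed-form for every kind (trapezoid mean for empirical
CDFs); `ks_check()` provides a one-sample Kolmogorov–Smirnov self-check
against any spec, with the exact mixture CDF and the asymptotic critical
value `sqrt(-log(α/2)/2)/√n` (adequate for the n ≥ 20 precondition).

Every stochastic process — each class's arrival stream, the exam-type draw,
the sex draw, the DVT slot draw, service times, setup times, the random
policy — has its own substream derived by hashing `(seed, stream_id)`.
Policies therefore consume identical arrivals and service demands for a
shared seed (common random numbers), which sharpens policy comparisons.
Replication seeds within an experiment are drawn from a dedicated substream
of the master seed rather than taken as consecutive integers; arithmetic
seed progressions interact measurably with generator initialization, while
drawn seeds behave like independent replications.

## The synthetic case-hospital profile

`default_profile()` is a documented stand-in for the studied department,
not a copy of it: the hospital's raw datasets are unpublished. What is
pinned to reported values:

* class shares 72.46 / 19.98 / 7.57% (six-month case mix);
* arrival rates calibrated so a 5-day window expects 355.3 outpatients,
  93.0 inpatients, 37.9 emergency patients (the validation volumes) —
  rates are absolute, so shorter test calendars keep the same traffic
  intensity;
* DVT slots: 20 minutes with probability 0.7, else 40; DVT outpatient
  male:female ratio 3:4; liver always 40 minutes; everything else 20;
* the setup phase TRIA(1, 5, 9), mean 5 minutes;
* the prostate scanning-time law, the one published fit:
  `0.485(3 + 7·Beta(1.9, 1.16)) + 0.424(10 + Weib(3.46, 1.23)) +
  0.091(20 + Weib(6.99, 1.29))`;
* the shoulder mean scanning time 16.35 minutes (the published
  weighted-points example, giving 0.8 + 0.3 = 1.1 points).

What is invented, once, and why:

* **Inter-arrival laws** are exponential stands-ins calibrated to the
  weekly volumes. The department's own description of its outpatient stream
  ("4.7 patients per 20 minutes on average") implies a ~48% higher rate
  than its validated weekly volume; we calibrate to the volume, which is
  what the validation procedure checks. Users with empirical inter-arrival
  data can substitute `dist_empirical()` specs.
* **Service-time stand-ins** for the unpublished body parts: offset
  Weibulls, a triangular, and an empirical CDF with means of 15.0–16.35
  minutes for 20-minute-slot exams and 32 minutes for liver — inside
  realistic bands (15–25 and 30–45 minutes) for exams scheduled into those
  slots. The exam mix (abdomen 38%, other 27%, liver 12%, shoulder 10%,
  DVT 7%, prostate 4%, scrotum 2%) puts abdomen at the reported ~38% of
  outpatient volume and keeps the constrained exams a realistic minority.
* **Inpatient/emergency body-part mixes** reuse the outpatient mix
  (not separately published); both are configurable.
* Batch arrivals are simultaneous and registered in generation order; ties
  across classes at identical timestamps are processed in class order
  (outpatient, inpatient, emergency), deterministically.

Under these stand-ins the profile runs hotter than the studied department
(mean room utilization in the low 80s rather than ~69%): the published
utilizations imply shorter true mean service times than the slot-based
bands allow, and we kept the bands. Consequences: absolute waiting times
and utilizations are *not* comparable to the reported tables, and the
package makes no such claim. What does transfer — and what the acceptance
tests check — are the arithmetic reproductions (shares, calendar,
replication sizing, CV, weighted points, workload-SD arithmetic), the
calibrated arrival volumes, and the *orderings*: the workload spread across
rooms satisfies `minutes < weighted_points < points ≪ random` at 95%
confidence over 110 paired replications, the same qualitative ranking as
the reported 0.06 < 0.54 < 1.40 < 13.69 percentage points, and throughput
is monotone in the appointment interval.

## Replication statistics and the optimizer

`run_experiment()` aggregates measures across replications with Student-t
half-widths; the sample SD uses the n−1 denominator, pinned by exact
reproduction of the reported across-room workload statistics (69.21 / 1.40
and 0.06). `required_replications(n0, h0, h)` is the quadratic rule rounded
up (`ceiling`); from the pilot (30 replications, half-width 6.1, mean
351.7) a 1% CV target needs 91 > 89 replications, and experiments default
to the over-provisioned 110. Percentages and waiting times are reported to
two decimals.

The appointment search is an exhaustive integer grid (intervals 1–30
minutes, small batch range) rather than a metaheuristic: the space is tiny
and reproducibility beats fidelity to a proprietary black box. Feasibility
requires every room's mean utilization strictly above 70% and mean total
examined strictly above 485 patients; the 485 threshold scales linearly
with the measured horizon so reduced-scale runs remain meaningful. An upper
utilization bound of 75% is supported but off by default — the brief states
both a 70–75% band and a "more than 70%" constraint, and we take the
explicitly stated binding constraint as the default. With batch size 1 the
calibrated profile saturates the throughput constraint only at short
intervals, so feasible intervals are small and the objective decreases
toward the feasibility boundary — the same "largest feasible interval wins"
structure as in the study, whose own best solution (18-minute intervals)
relies on batched arrivals of about three patients, as its Scenario-3
design makes explicit.

## Numerical choices and degenerate inputs

* Weighted points round each addend **half-up** to one decimal
  (`0.25 → 0.3`); base R's banker's rounding would give 0.2 and could not
  reproduce the published 1.1-point example. A small epsilon guards against
  binary representation artifacts before flooring.
* Ties in the argmin over rooms break toward the lowest room id —
  deterministic and testable; the original dispatch rule is silent.
* Scheduled arrival epochs are generated as exact integer multiples of the
  interval, strictly below the horizon (`seq()`'s fuzz would occasionally
  admit the horizon itself).
* Mixture weights must sum to 1 within 1e-9; empirical breakpoints must be
  strictly increasing and end at probability 1; triangular requires
  `min ≤ mode ≤ max`. Violations raise errors naming the field.
* A female patient with a male-only exam type is rejected as a
  contradiction, as is a patient with no eligible room in the layout.
* Zero-length horizons, empty arrival streams, single-room layouts, and
  degenerate (sd = 0) confidence intervals are all defined and tested
  rather than special-cased away.

## Problem sizes used by the test suite

Unit tests run the case-hospital profile on a reduced calendar (one
measured day after a 500-minute warm-up) and a deliberately lighter-loaded
variant where saturation would mask policy differences; distribution checks
use 10^5 draws; the calibration, M/M/1 oracle (λ = 1/30, μ = 1/20,
Wq = 40 minutes), and policy-ordering checks run 110–200 replications of
the full calendar. These sizes were chosen so the statistical assertions
have the power they claim while the whole suite stays comfortably fast.

## Known limitations

* No no-shows, unpunctuality, or Saturday policies; breast ultrasound and
  heterogeneous equipment are out of scope, as in the study the model
  follows.
* Technologist proficiency differences are not modeled; the
  `weighted_points` policy exists precisely because the department considers
  them real.
* The synthetic profile reproduces structure and calibration targets, not
  the department's absolute performance numbers (see above).
* The K-S check uses the asymptotic critical value and ignores parameter
  estimation effects; it is a self-check for configured laws, not a
  substitute for a fitting workflow.
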