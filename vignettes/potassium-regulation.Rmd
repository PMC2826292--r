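---
title: "Computerized potassium regulation: model, simulator and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computerized potassium regulation: model, simulator and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripk)
```

# The advisory algorithm

`gripk` implements the GRIP-II computerized potassium replacement protocol:
a deterministic rule set that turns one potassium measurement plus a small
set of renal covariates into a syringe-pump rate recommendation and a
next-measurement interval. The decision sequence is

1. estimate creatinine clearance with Cockcroft-Gault
   ((140 − age)·weight / (72·S~cr~ in mg/dL), ×0.85 for women; creatinine
   entered in µmol/L is divided by 88.4);
2. form the potassium **clearance fraction**
   f = min(1, eGFR/100, diuresis/60), + 0.5 on hemofiltration — the most
   impaired of the two linear renal signals wins, a deliberately
   conservative aggregation;
3. classify renal impairment (eGFR < 30 mL/min or diuresis < 30 mL/h,
   strict inequalities) and set the target range, 3.8–4.5 mmol/L, lowered
   by 0.2 mmol/L at both ends when impaired;
4. classify the measured potassium against the target range (bounds
   inclusive: a value exactly at a bound is in range) and dose:
   * **hypokalemia** — sliding scale, linear through the anchors
     (2.0 mmol/L → 20 mmol/h) and (3.5 mmol/L → 6 mmol/h), clamped at
     20 mmol/h below K = 2.0 and extended linearly between 3.5 mmol/L and
     the lower target bound;
   * **normokalemia** — exponential smoothing of the recent mean rate
     toward 4·f (next section);
   * **hyperkalemia** — rate 0; the protocol gives no other hyperkalemia
     treatment advice;
5. alerts: marked abnormal potassium (< 2.8 / > 6.0 mmol/L, or < 2.6 /
   > 5.8 under renal failure — the impairment criterion doubles as the
   renal-failure criterion, since no separate definition exists) and
   advised rates over 12 mmol/h both request physician notification;
6. next measurement in 1 h with a marked-abnormal alert, 2 h out of range,
   4 h in range — calibrated so a stable patient is measured about six
   times a day. The interval table is an artifact of this implementation
   (the original system's exact schedule is not published) and is fully
   configurable.

All constants live in `advisor_config()`; every rule above is exercised
individually in the unit tests and jointly through `advise()`.

## The within-range rule and the smoothing weight

For an in-range potassium the protocol advises the mean infusion rate of
the last 8 hours (or since admission, whichever is shorter, with log gaps
counting as zero) *and* makes the pump converge to 4·f mmol/h. The two
statements are combined as exponential smoothing

\[ r_{new} = (1 - w)\,\bar r_{8h} + w \cdot 4f , \]

which advises (approximately) the recent mean while making 4·f the exact,
globally attracting fixed point for any weight w ∈ (0, 1].

Two numerical choices matter here.

* **Rounding is applied once, by `advise()`, to the final recommendation**
  (nearest 0.5 mmol/h — the solution is 1 mmol/mL, so rates map 1:1 to
  pump mL/h). `within_range_rate()` itself returns the unrounded smoothed
  value. If the smoothing output were rounded before being fed back, the
  iteration would acquire spurious fixed points on the 0.5 grid around 4·f
  and the advertised limits (4 mmol/h at f = 1, 1 mmol/h at f = 0.25)
  would be unreachable from most starting rates.
* **The default weight is w = 0.5.** In the physical closed loop the pump
  runs at the *rounded* rate, so the advised-rate map is effectively
  r ↦ round₀.₅((1 − w)r + w·4f). For w ≤ 0.25 this map has additional fixed
  points at ±0.5 mmol/h around 4·f (e.g. 4.5 → 4.375 → rounds back to 4.5),
  so the pump could stall half a unit away from its stated limit forever.
  With w = 0.5 the pull per step (≥ 0.25 mmol/h within half a unit of the
  limit) beats the rounding radius and 4·f is the unique fixed point for
  the protocol's printed clearances. The closed-loop test asserts exactly
  this: a noise-free in-range patient's pump settles on 4·f and stays.

## Degenerate inputs

Missing creatinine falls back to a diuresis-only clearance and impairment
assessment; missing diuresis to eGFR-only; with both missing the advisor
assumes normal renal function and warns. Potassium is validated, never
silently clipped. Infusion-log intervals must be non-overlapping and inside
`[admission, now]`.

# The virtual patient

The protocol's original clinical evaluation rested on thousands of real
ICU admissions, which are not available; closed-loop behaviour is
therefore studied on a synthetic cohort. Plasma potassium follows a single-compartment model

\[ V \frac{dC}{dt} = R + B + H\,(C_{set} - C) - CL_0\, f\, C , \]

with infusion R (mmol/h), endogenous/enteral input B, transcellular
buffering H toward a set point C~set~ (the insulin/catecholamine-driven
shift pool, linearized), and renal elimination proportional to C through
the same clearance fraction f the advisor estimates. This is the simplest
model that (i) drifts hypokalemic without potassium intake, (ii)
accumulates potassium in renal failure, and (iii) corrects under infusion.
Integration is Euler–Maruyama with additive process noise
(default SD 0.15 mmol/L·h^−1/2^); measurements add analyzer noise
(SD 0.05 mmol/L) and round to the 0.1 mmol/L reporting resolution of a
point-of-care blood-gas analyzer.

**Calibration.** Defaults V = 15 L, CL₀ = 2.286 L/h, H = 1 L/h,
C~set~ = 4.2 mmol/L, B = 7.3 mmol/h solve two anchor conditions at f = 1:
steady state 4.2 mmol/L under a 2.3 mmol/h infusion (the typical
administered rate in protocolized care) and 3.5 mmol/L untreated (so
essentially every patient needs potassium, consistent with replacement
being near-universal in the ICU). The closed-form steady state
C\* = (R + B + H·C~set~)/(H + CL₀·f) is the oracle for the integration
tests (agreement within 10⁻³ mmol/L after ten time constants).

**Step size.** The default is dt = 0.005 h. The model's time constant is
V/(H + CL₀f) ≈ 4.6 h at f = 1, and with explicit Euler the chosen step
keeps the halving perturbation of a noise-free trajectory below
10⁻³ mmol/L even for the steepest transient the protocol can command (a
sustained 20 mmol/h dose). Step-size convergence is checked on open-loop
(fixed-infusion) trajectories: the closed loop is not a meaningful
convergence probe because the 0.1 mmol/L measurement rounding makes it
discontinuous — an arbitrarily small trajectory shift can flip a measured
value and change the advised rate by half a unit.

**Cohort.** `make_cohort()` samples admission potassium ~ N(4.0, 0.4)
truncated to [2.0, 6.5] mmol/L (admission medians of about 4.0 are typical
of mixed surgical ICUs), about 11% of patients with acute kidney injury
(high creatinine, 6-hour diuresis 40–170 mL, ~45% of them — ~5% of the
cohort — on renal replacement therapy, matching the study population's AKI
and RRT rates), and mild lognormal-free variation of V, B and C~set~.
Each patient's kinetic f is derived from their own covariates via
`clearance_fraction()`, so the advisor's renal assessment and the
physiology agree by construction. AKI patients get a reduced endogenous
input (B ≈ 4.5 mmol/h), emulating dietary potassium restriction in kidney
injury. One RNG stream per patient is derived from the master seed, so
runs are reproducible patient-by-patient and the two study arms can be
simulated on the *same* cohort with paired noise.

**Physician emulator.** The baseline arm mimics pre-protocol practice as
described for the study unit: the potassium order is revised once a day at
the morning review (coarse 2 mmol/h dose resolution; stop above
5.0 mmol/L; dose below 3.8 mmol/L; in-range values leave the pump alone),
with fixed 4-hourly measurements, and between reviews only a distinctly
abnormal value (< 3.0 or > 5.5 mmol/L) triggers a consult applied after a
1-hour delay. These parameters are plausible reconstructions, not
validated ones — the source describes the workflow qualitatively — and all
are arguments of `physician_controller()`.

## What the simulator does and does not show

The controller-comparison property (protocol arm strictly lower
hypokalemia *and* hyperkalemia time-in-range prevalence than the physician
arm on the same seeded cohort) reproduces the *direction* of the published
before/after result, and that is all it can show. Absolute prevalences in
the synthetic cohort are higher than the real ones — in particular the
synthetic AKI subgroup equilibrates at 5–6 mmol/L when not on RRT, a
severity a real unit would treat with dialysis, which no potassium-pump
controller can correct. Measurement-level *incidence* can even favour the
physician arm, because the protocol samples out-of-range patients two to
four times more often and thereby over-represents excursions in the pooled
measurement counts; the time-based prevalence is the fair metric and the
one asserted. Real-data effects the simulator does not emulate at all:
acid-base and insulin shifts, enteral absorption dynamics, measurement
artifacts (pseudohyperkalemia), discharge/censoring, and nurse compliance
below 100%.

# Evaluation methods

Each patient's potassium curve is the linear interpolation of their
measurements. **Prevalence** of hypo-/hyperkalemia is the duration spent
below 3.5 / above 5.0 mmol/L (marked hyperkalemia: above 6.0) divided by
the ICU stay; threshold crossings are solved exactly on every linear
segment, and the analytic result is tested against 1-second brute-force
resampling (agreement within 0.01 percentage points). When explicit
admission/discharge times are absent, the span from first to last
measurement stands in for the stay; single-measurement patients are
excluded from aggregates and counted. **Incidence** is the fraction of
individual measurements out of range among all measurements taken after
the first 8 h of admission, pooled over the cohort (pooled counting, not
per-patient averaging, matches the published count arithmetic). Strict
inequalities throughout: a value exactly at 3.5 or 5.0 is in range.

**Odds ratios** use the proportion-odds formula
OR = [p₁/(1−p₁)]/[p₂/(1−p₂)] — the point estimate is independent of group
size — with Woolf (log-normal) 95% intervals from cell counts
reconstructed as round(p·n); proportions of 0 or 1 fall back to a 0.5
continuity correction with a warning. Recomputing from the published
proportions and measurement counts (2.4% → 1.7% hypokalemia, 7.4% → 4.8%
hyperkalemia on 15 857 vs 37 717 measurements) reproduces the published
incidence ORs of 1.4 and 1.6 at one decimal. `compare_arms()` assembles
incidence, the three prevalences, ORs with CIs, measurements per
patient-day, 5/25/50/75/95 percentile bands over the first ICU day
(type-7 quantiles), a chi-square test on out-of-range counts (no Yates
correction by default; the counts are large) and a Mann-Whitney U test on
per-patient prevalence distributions, choosing mean ± SD versus
median (IQR) presentation by the kurtosis of those distributions.

# Problem sizes and reproducibility

The shipped tests run the full closed-loop comparison at 100 patients ×
5 days per arm (the package's standard demonstration size; one master
seed pins cohort, noise and both arms), the prevalence oracle on 100
random curves, and the kinetic checks over ten time constants. Every
stochastic test and the acceptance script take their randomness from a
single integer seed. Known limitations are listed above; the open design
questions — whether the hypokalemia sliding scale should itself be scaled
by the clearance fraction (implemented unscaled, relying on the lowered
target and alerts), and whether within-range advice should cap at the
12 mmol/h alert threshold (no cap; the alert fires instead) — follow the
protocol text as printed rather than guessing intent.
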