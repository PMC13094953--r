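---
title: "Validating continuous ward monitoring against nurse spot-checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating continuous ward monitoring against nurse spot-checks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Postoperative patients on general wards are conventionally assessed 2–3
times a day. A chest-patch sensor that reports pulse rate (PR), mean blood
pressure (MBP), respiratory rate (RR), oxygen saturation (SpO2) and skin
temperature every 5 minutes promises much earlier detection of
deterioration — if its readings can be trusted. Assessing that trust
requires a chain of decisions that are easy to get subtly wrong:
non-physiological spikes must be removed without discarding genuine
deterioration; massive transmission loss must be accounted for rather than
silently ignored; device and nurse readings must be aligned in time before
they are compared; continuous agreement must respect that each patient
contributes many correlated pairs; and the clinically relevant question —
do the two sources flag the *same patients* as abnormal? — needs paired
binary statistics, not correlation coefficients. `wardmon` implements this
chain as composable, individually tested stages.

```{r}
library(wardmon)
report <- run_pipeline(pipeline_config(
  synth = synth_config(n_patients = 12, duration_hours = c(24, 48), seed = 42)
))
render_report(report)
```

## Artifact rules

Three numerical criteria, applied per patient and parameter in
`apply_qc()`:

* **Range** (`flag_range`): values strictly outside per-parameter limits
  (defaults PR [5, 250] bpm, SBP [20, 300] mmHg; the remaining limits are
  broad package defaults — MBP [10, 250], RR [0, 80], SpO2 [0, 100],
  TEMP [30, 45] — overridable and echoed in every report). Strict
  inequalities mean boundary values pass.
* **Deviation** (`flag_deviation`): a value changing by more than 50%
  from the prior reading is a candidate artifact. The follow-up clause is
  ambiguous in the field's usual phrasing ("unless followed by a ±25%
  recovery value"), so both readings are implemented behind
  `qc_rules(deviation_semantics =)`. The default, **confirmation**,
  treats a candidate as genuine when the next reading stays within ±25%
  of *the candidate*: sustained changes (real deterioration) are kept,
  spike-and-return patterns are removed. The literal **recovery** reading
  (genuine only if the next value returns to within ±25% of the prior)
  is available but not default, because it discards genuine sustained
  deterioration — and, since flagged values cannot serve as the prior,
  it keeps flagging the new level indefinitely.
* **SpO2 step** (`flag_spo2_step`): a change of ≥ 8 *absolute* percentage
  points between consecutive readings. Saturation is already a
  percentage; a relative 8% would be ~7.7 points at SpO2 96 — nearly the
  same number but non-standard. The follow-up clause for this rule is
  also expressed in step points: a drop is genuine when the next reading
  stays within 8 points of it, an artifact when the trace leaps back.
  (A relative ±25% clause would be vacuous here: 25% of a saturation
  value spans more than the whole plausible SpO2 range.)

Further conventions: a candidate at the end of a series can never be
confirmed and is flagged (conservative — the agreement analyses then never
see it); flagged values are excluded from acting as the "prior reading",
so one spike cannot cascade into a run of flags; range-flagged values are
removed before the serial rules run, so a 300-bpm reading never serves as
anyone's prior; the deviation rule is applied across gaps of any length
(the prior reading may be hours old — with a mean-reverting signal this is
harmless, and the alternative of resetting after gaps would let the rule
miss every spike that follows a gap); the deviation rule is applied to
temperature too, where a 50% change inside the physiological range is
impossible — the rule is simply inert there, and temperature artifacts
arise from the range rule.

A value may be flagged by two rules (deviation and SpO2 step); it is
removed once and counted in each rule's tally.

## Completeness

`completeness()` compares obtained records against the expected 5-minute
slot grid of each patient's monitoring episode (admission to sensor
removal; `floor(duration/step) + 1` slots). Records are assigned to the
nearest slot, so both grid-aligned and free-running ~5-minute cadences are
supported. Missingness is reported at the slot level (whole records lost)
and per parameter among obtained records, because the two mechanisms —
transmission loss versus a parameter the device declined to report —
have different clinical interpretations.

## Pairing

`match_pairs()` pairs each nurse reading, per parameter, with the device
record closest in time among those carrying that parameter, provided
|Δt| ≤ 5 minutes (configurable). Nearest-in-time is the least-biased
deterministic choice when the source protocol only states "within 5
minutes"; a first-in-window variant is available
(`pairing_config(selection = "first")`). Distance ties break toward the
earlier record. A device record may serve two back-to-back nurse checks
when both fall inside the window; this is allowed (repeated-measures
agreement tolerates it) and visible in the pair table. Every unmatched
(observation, parameter) is logged with a reason — no device data in the
window, parameter absent, or value removed by QC.

Nurse temperatures must carry the +0.5 °C auricular-to-core correction
before pairing; `adjust_auricular_temperature()` applies it exactly once
and errors on re-application, so a table can never be corrected twice.

## Repeated-measures Bland–Altman

With differences `d = device − nurse` grouped by patient, the bias is the
mean of all differences (a subject-means variant is available by
configuration) and the SD entering the limits of agreement combines the
within- and between-subject variance components of a one-way ANOVA with
the unbalanced-design correction:

$$ s_w^2 = MSW, \qquad s_b^2 = \max\!\left(0, \frac{MSB - MSW}{n_0}\right),
\qquad n_0 = \frac{N - \sum_i m_i^2 / N}{k - 1}, $$

with $m_i$ pairs for subject $i$, $N = \sum m_i$, $k$ subjects, and
LoA $= \text{bias} \pm 1.96\sqrt{s_w^2 + s_b^2}$. The 1.96 multiplier is
conventional and configurable. When every subject contributes exactly one
pair the decomposition is undefined and the function degenerates — by
design, and labelled in its output — to the classic single-measurement
formula. No confidence intervals are put on the limits; that is a
documented extension point rather than a default, since the validation
literature this serves reports none.

## Error-grid classification

The Clarke grid was designed for glucose; its zone boundaries for other
vital signs are a matter of clinical judgment and published studies rarely
print them. `wardmon` therefore makes the geometry *declarative*:
`clarke_zone_config()` builds zones A–E from an A-band (±10% relative or
an absolute half-width, whichever is larger), a clinically normal band,
and critical boundaries. E is "opposite critical extremes", D a
"dangerous miss" (reference critical, measurement normal), C an
"overcorrection risk" (reference normal, measurement critical), and B the
remaining benign disagreement. The shipped per-parameter defaults are
explicitly provisional; every report embeds the geometry used, and they do
not claim to reproduce any particular published zone percentages.

Two structural guarantees are enforced rather than assumed:
`validate_zone_config()` probes a 10⁴-point lattice to verify the zones
partition the domain (gaps and interior overlaps are errors with a witness
point) and that the identity line lies wholly in A; and classification
assigns boundary points to the more benign zone (A > B > C > D > E) by
evaluating closed regions in benign-first order. For a one-sided parameter
(SpO2 has no critical *high*), zone E is empty and the remaining zones
still partition.

## Abnormality concordance

`detect_abnormal()` marks a patient positive when at least
`min_consecutive` consecutive obtained values cross a threshold;
the default is 1 (any single exceedance), because the source protocols
state no persistence criterion — the parameter exists for sensitivity
analyses. Threshold strictness follows the printed symbols exactly:
`MBP <60` is strict, `PR ≤40` and `PR ≥100` inclusive. The 17 default
thresholds cover hemodynamic, respiratory, oxygenation and temperature
abnormalities.

For each threshold, patients are cross-classified into a 2×2 table
(patients lacking the parameter in either source are excluded and
counted). Cohen's kappa uses the standard 2×2 formula with the
Fleiss–Cohen–Everitt asymptotic standard error; the interval is labelled
honestly as a 95% CI. McNemar's test follows the two-regime rule: with
fewer than 10 discordant patients, the exact two-sided binomial p-value
$\min\{1, 2\,P(X \le \min(b,c))\}$, $X \sim \mathrm{Bin}(b+c, 1/2)$
(p = 1 when there are no discordants); otherwise the continuity-corrected
$\chi^2 = (|b-c|-1)^2/(b+c)$ on 1 df. The corrected statistic is used as
stated even when $b = c$, where it yields p ≈ 0.83 rather than 1 — the
rule is applied consistently rather than special-cased. Whether a nurse
"positive" should use any reading or only the worst of the day is
likewise unspecified in the protocols this mirrors; any-reading is used,
symmetric with the device rule.

Report formatting follows the field's conventions: percentages at 0.1,
kappa at 2 decimals, p-values at 3 decimals with `<0.001` below 0.0005.

## The synthetic ward generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with ground truth for every mechanism so the pipeline's recovery
can be tested:

* **Episodes**: durations uniform on 12–118 h (median ~65 h), admissions
  within a 6-hour window, a 5-minute slot grid.
* **Physiology**: per-patient baselines (cohort centers MBP 89 mmHg,
  PR 77 bpm, RR 16 /min, SpO2 96%, TEMP 37.8 °C) plus a stationary AR(1)
  fluctuation with coefficient 0.9 at the 5-minute lag. The
  between/within spreads (e.g. MBP 8/7 mmHg) were chosen once so cohort
  medians and interquartile ranges resemble ward telemetry distributions.
* **Abnormality episodes**: optional per-patient excursions (hypotension
  to 54 mmHg, hypertension, tachycardia, tachypnea, desaturation to 89%,
  fever), ramped in with a raised-cosine profile. Smooth ramps matter:
  the latent physiology itself must never violate the artifact rules,
  which is exactly the assumption the QC criteria encode.
* **Missingness**: whole-record loss as alternating obtained/lost bursts
  with geometric lengths (mean lost burst 6 slots; the obtained mean is
  set so the long-run loss fraction equals the configured 0.438). Burst
  structure — rather than independent Bernoulli slots — is what stresses
  the "prior reading" logic of the QC rules; the geometric choice is a
  modelling convenience, since no gap-length distribution is published.
  On top of this, per-parameter dropout among obtained records is
  SpO2-dominated (default 16.1% for SpO2, ~2% MBP, ~1.6% RR).
* **Artifacts**: isolated spikes injected at obtained records, each
  constructed to violate its rule — deviation spikes at 1.7× the prior
  with the follow-up left near baseline, range violations (e.g. PR 300),
  SpO2 drops of 12 points that rebound. Positions are kept ≥ 3 records
  apart so priors and follow-ups stay natural; per-record rates default
  to the low per-parameter rates such studies report (0.04–0.31%).
* **Nurse observations**: 2–3 visits/day drawn in morning / midday /
  evening windows (07–09, 12–14, 18–20 h), sampled from the latent truth
  with measurement noise, a +3 breaths/min nurse RR offset and a 0.4 °C
  device-over-nurse temperature offset. These two biases are free
  parameters chosen so the Bland–Altman output reproduces the
  *directions* reported for such devices (device RR below nurse counts,
  device temperature above adjusted auricular readings); they are not
  claimed as anyone's measured biases.

One random stream per patient is derived from `(seed, patient index)`, so
cohorts are bit-identical under a fixed seed and stable under parallel
generation.

What the generator does **not** emulate: motion-artifact clustering,
calibration drift of the cuff reference, circadian rhythms,
non-stationary postoperative trends, device-internal signal rejection, or
any waveform-level physics. Passing recovery tests on this generator
therefore demonstrates that the pipeline's logic is correct under its
stated assumptions — not that the artifact rules have any particular
sensitivity on real ward data.

## Numerical choices and test scale

All timestamps are timezone-naive (stored as UTC) at second resolution;
interval arithmetic is in seconds. Absent values are represented as `NA`,
never sentinel numbers, because missingness accounting is itself a
headline output. Device values are reported at the device's scale
(integers, temperature at 0.1 °C), which makes CSV round-trips exact.

The test suite checks the artifact rules against a naive nested-loop
reference on 1,000 random short series, the exact McNemar p against
brute-force binomial-tail enumeration for every table with ≤ 12
discordants, the variance decomposition against `aov()`, and generator
convergence (slot loss, SpO2 dropout, injected-artifact sensitivity,
false-flag rate) on seeded cohorts of 30–40 patients at 48–72 h — sizes
chosen to give three-SE Monte-Carlo resolution while keeping the default
suite fast.

## Known limitations

* Error-grid defaults are provisional clinical judgment; real analyses
  should supply study-specific geometry (and the report will embed it).
* The kappa CI is asymptotic and unreliable for near-empty margins; rows
  where one source never flags a patient are better read from the raw
  counts.
* No time-to-detection or alert-latency analysis, and no early-warning
  score computation: the pipeline quantifies agreement, not clinical
  benefit.
* The pairing stage does not interpolate device values to nurse
  timestamps; only observed records are compared.
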