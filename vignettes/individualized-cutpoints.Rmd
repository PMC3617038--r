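---
title: "Individualized accelerometer cutpoints: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized accelerometer cutpoints: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hip-worn accelerometers summarize movement as *activity counts* per epoch
(counts·min⁻¹ at 60-s epochs). Fixed count thresholds — the absolute
Freedson scheme, moderate 1952–5724 and vigorous ≥ 5725 counts·min⁻¹ —
turn a count stream into time spent at light, moderate and vigorous
intensity, but intensity is only meaningful *relative to capacity*: 40–60%
of heart-rate reserve (HRR) is moderate work for anyone, whereas a fixed
count value is hard work for an unfit wearer and light work for a fit one.
A wearer whose maximal capacity is low may be physiologically unable to
ever reach 5725 counts·min⁻¹, and a very fit wearer can cross it at well
below 60% HRR. `relcal` calibrates the count scale to the individual.

## The calibration model

For each subject, with resting heart rate $HR_{rest}$ and measured maximal
heart rate $HR_{max}$,

$$\%HRR = 100 \cdot \frac{HR - HR_{rest}}{HR_{max} - HR_{rest}},$$

and a staged submaximal treadmill test supplies paired observations of
steady-state %HRR and counts·min⁻¹. The pipeline
(`calibrate_subject()`) is:

1. **Stage selection** (`select_calibration_stages()`): stages with fewer
   than 2 recorded minutes are unusable (the test terminates at 85% of
   $HR_{max}$, typically clipping the final stage) and are dropped; the
   last 3 remaining stages, in protocol order, enter the regression.
   Fewer than 3 usable stages is a refusal, not an extrapolation. The rule
   never skips an interior completed stage; if a middle stage must be
   excluded (device fault, protocol deviation), filter it out before
   constructing the session.
2. **Stage summaries** (`stage_summary()`): the arithmetic mean of the
   last 2 recorded minutes of HR and counts, taken as the stage's steady
   state; stage %HRR outside [0, 100] is flagged, never clipped.
3. **Line fit** (`fit_cutpoint_model()`): ordinary least squares,
   $y = m x + b$ with $y$ = counts·min⁻¹ and $x$ = %HRR.
4. **Cutpoints** (`derive_cutpoints()`): the line evaluated at the target
   intensities, 40% HRR (moderate) and 60% HRR (vigorous) by default.

**Orientation.** The regression can be posed in either direction. The
default, `counts_on_hrr`, treats counts as the response, because the
quantity of use is a *count* threshold at a fixed %HRR and OLS prediction
should be in the direction of use. The inverse pose, `hrr_on_counts`
(counts as regressor, threshold recovered by solving the fitted line), is
available via `orientation =`. With $r^2 = 1$ the two agree exactly; with
$r^2 < 1$ they differ by regression-to-the-mean, which the test suite
asserts in both directions.

**Targets as parameters.** 40/60% HRR are defaults, not constants — fit
wearers cross absolute vigorous counts near 30–40% HRR, and studying such
shifts requires moving the target (`moderate_pct`, `vigorous_pct`).

**Failure handling.** A zero-variance regressor (all stage %HRR equal) is
a singular fit and an error. A negative fitted slope is physiologically
implausible and is flagged on the model with a warning; a derived
non-positive cutpoint is a hard calibration failure. Minimum points per
fit is 3, matching the 3-stage selection.

## Classification and group comparison

`classify_epoch()` applies left-closed bands: light below the moderate
cutpoint, moderate in `[moderate_cut, vigorous_cut)`, vigorous at or
above. The inclusive lower edge follows the printed integer band
1952–5724 of the absolute scheme and is applied identically to
individualized schemes. Epochs other than 60 s are accepted; counts are
rescaled by `60/epoch_length` before classification (cutpoints are
per-minute quantities) and each epoch contributes `epoch_length/60`
minutes, so category minutes always sum exactly to wear time.

Cohort tools stratify by MET capacity (`vo2max / 3.5`): low < 10 MET,
moderate 10–13 MET, high > 13 MET. The interval labels make 10 and 13
both "moderate", so the band is implemented closed, `[10, 13]`. Group
means use the $n-1$ sample SD. `compare_groups()` runs the classic
equal-variance one-way ANOVA, $F = (SSB/(k-1))/(SSW/(N-k))$; because no
standard post-hoc procedure is implied by the design, the follow-up is
pairwise Welch $t$-tests with Bonferroni adjustment over the group pairs —
conservative, assumption-light and reproducible without quantile tables.
`cutpoint_deviation()` reports signed individualized-minus-absolute
differences, and `correlate_cutpoints()` the squared Pearson correlation
of cutpoints with VO2max, age or BMI (BMI derived as
`weight / (height/100)^2` rather than stored).

## What the simulator emulates

`simulate_cohort()` generates the study conditions the method is designed
for: three fitness groups of 9/31/33 subjects with VO2max distributed
N(31.6, 2.2), N(40.1, 2.7) and N(51.2, 3.7) ml·kg⁻¹·min⁻¹ (truncated by
redraw to each group's MET band), resting HR N(62, 8) and maximal HR
N(188, 9) bpm with a reserve of at least 60 bpm enforced, walking the
5-stage protocol with minute-level recording and 85%-HRmax termination.

The physiological bridge is the standard exercise-prescription
approximation **%HRR ≡ %VO2R**: oxygen demand at speed $v$ m·min⁻¹ is
taken from walking economy ($0.1\,v + 3.5$ ml·kg⁻¹·min⁻¹) below 8.0 kph
and running economy ($0.2\,v + 3.5$) at or above it; percent oxygen-uptake
reserve $(VO_2 - 3.5)/(VO_{2max} - 3.5)$, clipped to [0, 1.05], then fixes
expected HR between rest and max. Minute HR adds Gaussian noise
(SD 3 bpm). This is a modeling assumption of the generator, not a claim
about any particular dataset.

**Counts track metabolic demand.** Minute counts are
`intercept + slope · v_eq + noise` (SD 150 counts·min⁻¹, floored at 0),
where `v_eq` is the *walking-equivalent speed* carrying the same net
oxygen demand. At walking speeds `v_eq` equals the treadmill speed, so
the default slope (1000 ± 100 counts·min⁻¹ per kph between subjects) and
intercept (−2500 counts·min⁻¹) read naturally — 6.4 kph gives
−2500 + 1000·6.4 = 3900 expected counts. At the walk→run transition
`v_eq`, like oxygen demand, jumps upward, mirroring the abrupt rise in
trunk acceleration when gait changes. This choice is load-bearing: it
makes every subject's generating counts-vs-%HRR relation *exactly linear*
(slope proportional to the VO2 reserve), so

- closed-form true cutpoints exist (`true_cutpoints()`) for
  parameter-recovery testing,
- noise-free calibration is an exact identity end-to-end, and
- expected cutpoints are strictly increasing in VO2max — the mechanism of
  interest — even though counts are deliberately *fitness-independent* at
  any fixed speed (two subjects at 6.4 kph produce the same expected
  counts; only their %HRR differs). Had counts instead been tied to raw
  treadmill speed across the economy switch, the generating relation
  would be discontinuous in %HRR, and because fitness groups terminate at
  different stages (and hence mix walking/running points differently) the
  fitted group cutpoints would be distorted by the break rather than by
  fitness.

**Degenerate inputs the generator can produce.** The floor at 0 counts
truncates the slowest stage when a subject's count slope draw is unusually
low (below ≈780 counts·min⁻¹ per kph with the default intercept); such a
stage is off the generating line, so exact-identity checks fix the
between-subject slope SD at 0. A subject whose HR crosses the termination
threshold before completing 3 usable stages cannot be calibrated;
`calibrate_cohort()` drops such subjects with a message (essentially never
at the default parameters).

**What the simulator does not emulate:** free-living activity (only
steady-state treadmill stages), within-stage HR kinetics (minutes are
i.i.d. around steady state — no on-transient or cardiovascular drift),
nonwear, device differences, or day-to-day biological variation. Passing
tests therefore validate the *pipeline arithmetic and its statistical
behavior* under the stated model, not the field validity of the
physiological assumptions, which requires real paired VO2/accelerometer
data.

## Reproducibility and problem sizes

All simulation randomness flows through R's RNG; `simulate_cohort()`
seeds it from `config$seed`, so identical configurations give identical
cohorts, and the CLI's `--seed` yields byte-identical output tables. The
validation suite uses: 9 noise-free subjects for the exact-identity check
(tolerance 10⁻⁹ relative); 25+ randomized small fixtures per statistic
against independent brute-force oracles (grid-search least squares,
explicit sums-of-squares $F$, two-pass SD, covariance-formula $r^2$); 200
subjects in 25/85/90 group proportions for parameter recovery (observed
|bias| ≲ 0.7%, RMSE ≈ 4–6% at default noise, against bounds of 2% and
10%); 100 reseeded 9/31/33 cohorts for the group-ordering and ANOVA
replication; and 1000 random epoch series for the conservation and
dominance invariants. These sizes give stable Monte-Carlo margins while
keeping the full suite under a minute on one core.

## Known limitations

- Measured $HR_{max}$ and VO2max are required inputs; the package
  deliberately provides no age-based estimation of either.
- Calibration extrapolates the fitted line when a target %HRR lies
  outside the range spanned by the selected stages (routine for low-fit
  subjects at 60% HRR); the linearity assumption is untested in that
  range for a given subject.
- Only %HRR calibration is implemented; calibration against oxygen-uptake
  reserve directly (%VO2R from expired-gas measurement) is out of scope.
- No bout or nonwear logic: every epoch is classified.
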