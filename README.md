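# relcal — individualized accelerometer cutpoints from %HRR calibration

Accelerometer activity counts are usually classified into physical-activity
intensities with fixed ("absolute") thresholds — most commonly the Freedson
cutpoints, moderate 1952–5724 counts·min⁻¹ and vigorous ≥ 5725 counts·min⁻¹.
Those thresholds presume roughly average (≈10 MET) fitness: for an unfit
wearer they overstate the counts needed to reach a truly moderate effort,
and for a fit wearer they understate them. **relcal** implements the
alternative: calibrate each wearer individually against their own
heart-rate reserve (HRR = HRmax − HRrest) and derive per-subject cutpoints.

The method, for researchers and exercise-physiology labs with a treadmill,
a heart-rate monitor and a hip-worn accelerometer:

1. The subject walks/runs a staged submaximal protocol (5-min stages at
   3.2, 4.8, 6.4, 8.0, 9.6 kph) while minute HR and minute activity counts
   are recorded; the test stops once HR reaches 85% of measured HRmax.
2. The last 3 stages achieved are selected; the last 2 minutes of each are
   averaged, and stage HR is converted to percent heart-rate reserve,
   %HRR = 100·(HR − HRrest)/(HRmax − HRrest).
3. An ordinary least-squares line *y = m·x + b* (y = counts·min⁻¹,
   x = %HRR) is fitted per subject, and evaluated at 40% and 60% HRR to
   give that subject's individualized moderate and vigorous cutpoints.

On top of the calibration core the package provides epoch classification
and time-in-intensity accounting under any cutpoint scheme, fitness-group
comparisons (MET-capacity tertiles, one-way ANOVA, deviations from the
absolute cutpoints, cutpoint–covariate r²), CSV readers/writers for epoch
and HR logs with clock alignment, a synthetic cohort simulator with
fitness-dependent heart-rate response, and a `relcal` command-line tool.

## Worked example

Calibrate one simulated subject (VO2max 44 ml·kg⁻¹·min⁻¹, resting HR 62,
HRmax 188) and compare their individualized cutpoints with the absolute
scheme:

```r
library(relcal)
profile <- subject_profile("S001", age = 26, sex = "F", height = 168,
                           weight = 62, resting_hr = 62, max_hr = 188,
                           vo2max = 44)
set.seed(42)
session <- simulate_session(profile, simulation_config())
session
#> <calibration_session> subject S001: 5 stage(s)
#>   speeds (kph): 3.2, 4.8, 6.4, 8, 9.6; minutes: 5, 5, 5, 5, 1
#>   terminated early (reached 85% of maximal HR)

result <- calibrate_subject(session)
result$summaries
#>   speed n_minutes   mean_hr mean_counts  hrr_pct hrr_in_range
#> 1   4.8         5  84.88438    2752.027 18.16220         TRUE
#> 2   6.4         5  91.58045    4846.079 23.47655         TRUE
#> 3   8.0         5 143.74079   15527.918 64.87364         TRUE
result
#> <calibration_result> subject S001 (1 stage(s) dropped)
#> <cutpoint_model> [counts_on_hrr] slope 267.6, intercept -1793 (n = 3)
#>   r-squared 0.9976, residual SD 477.7
#> <cutpoint_pair> 8911.8 counts/min @ 40% HRR; 14264.2 counts/min @ 60% HRR

cutpoint_deviation(result$cutpoints)
#> moderate vigorous
#> 6959.844 8539.174
```

The test was stopped in stage 5 (the single terminating minute is dropped),
so stages 2–4 enter the regression. This subject is fit (12.6 MET): their
individualized moderate threshold, 8912 counts·min⁻¹, lies 6960 counts·min⁻¹
*above* the absolute 1952 — counts that the absolute scheme already calls
moderate are, for them, light effort:

```r
scheme <- as_cutpoint_scheme(result)
set.seed(43)
day <- epoch_series("S001", rpois(60, 4000))    # an hour around 4000 cpm
compare_schemes(day, scheme, freedson_scheme())$minute_diff
#>    light moderate vigorous
#>       60      -60        0
```

All 60 minutes the absolute scheme records as moderate are light relative
to this subject's capacity. (Simulated counts are on an invented but
plausible scale; the ordering of schemes, not the absolute magnitude, is
the point.)

The same pipeline is scriptable from a shell via the bundled CLI
(`system.file("cli", "relcal", package = "relcal")`): subcommands
`simulate`, `calibrate`, `classify` and `cohort`; see `?relcal_main`.

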