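# Shared in-code fixtures.

demo_profile <- function(id = "P1", resting_hr = 60, max_hr = 180,
                         vo2max = 45, age = 26, sex = "F", height = 168,
                         weight = 62) {
  subject_profile(id, age = age, sex = sex, height = height,
                  weight = weight, resting_hr = resting_hr,
                  max_hr = max_hr, vo2max = vo2max)
}

# A session whose stage steady states sit exactly on
# counts = slope * hrr + intercept, with constant minute values so the
# last-2-minute averages reproduce the targets exactly.
make_line_session <- function(profile = demo_profile(),
                              hrr_targets = c(30, 45, 60),
                              slope = 80, intercept = 300, minutes = 5) {
  speeds <- c(3.2, 4.8, 6.4, 8.0, 9.6)[seq_along(hrr_targets)]
  stages <- lapply(seq_along(hrr_targets), function(i) {
    hr <- profile$resting_hr +
      hrr_targets[i] / 100 * (profile$max_hr - profile$resting_hr)
    calibration_stage(speeds[i], rep(hr, minutes),
                      rep(intercept + slope * hrr_targets[i], minutes))
  })
  calibration_session(profile, stages)
}

# Stage-summary data frame straight from hrr/counts vectors.
summaries_df <- function(hrr, counts) {
  data.frame(speed = seq_along(hrr), n_minutes = 5, mean_hr = NA_real_,
             mean_counts = counts, hrr_pct = hrr, hrr_in_range = TRUE)
}

random_epoch_series <- function(n = 120, max_cpm = 9000, id = "R1") {
  epoch_series(id, round(runif(n, 0, max_cpm)))
}
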