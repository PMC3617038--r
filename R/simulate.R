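#' Treadmill protocol specification
#'
#' The staged submaximal protocol the simulator walks a subject through:
#' 5-minute stages at increasing speeds (3.2, 4.8, 6.4, 8.0, 9.6 kph by
#' default, no rest between stages), terminated the first minute heart
#' rate reaches 85% of the subject's maximal HR. Speeds at or above
#' `run_threshold_kph` use running rather than walking oxygen-cost
#' economy.
#'
#' @param speeds Strictly increasing stage speeds, kph.
#' @param stage_minutes Minutes per stage.
#' @param termination_fraction Fraction of maximal HR that terminates the
#'   test (0 < x < 1).
#' @param run_threshold_kph Speed at/above which running economy applies.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(speeds = c(3.2, 4.8, 6.4, 8.0, 9.6),
                          stage_minutes = 5,
                          termination_fraction = 0.85,
                          run_threshold_kph = 8.0) {
  if (any(diff(speeds) <= 0))
    stop("protocol speeds must be strictly increasing", call. = FALSE)
  if (termination_fraction <= 0 || termination_fraction >= 1)
    stop("termination_fraction must be in (0, 1)", call. = FALSE)
  structure(list(speeds = speeds, stage_minutes = stage_minutes,
                 termination_fraction = termination_fraction,
                 run_threshold_kph = run_threshold_kph),
            class = "protocol_spec")
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic cohort generator. Group sizes and VO2max
#' distributions reproduce the study conditions of the reference cohort
#' (9 / 31 / 33 subjects with group VO2max 31.6 +/- 2.2, 40.1 +/- 2.7 and
#' 51.2 +/- 3.7 ml/kg/min); heart-rate anchors default to 62 +/- 8
#' (resting) and 188 +/- 9 (maximal) bpm. The counts model is
#' fitness-independent by design so that any cutpoint difference between
#' fitness groups arises purely from the heart-rate side.
#'
#' @param n_low,n_moderate,n_high Subjects per fitness group.
#' @param seed Integer RNG seed; identical configs give identical cohorts.
#' @param protocol A [protocol_spec()].
#' @param hr_noise_sd Minute-level HR noise SD, bpm.
#' @param counts_noise_sd Minute-level count noise SD, counts/min.
#' @param counts_speed_slope_mean,counts_speed_slope_sd Between-subject
#'   distribution of the counts-per-kph slope (at walking speeds).
#' @param counts_intercept Counts/min intercept of the counts model
#'   (generated counts are floored at 0).
#' @param vo2max_mean,vo2max_sd Length-3 named vectors (low, moderate,
#'   high), ml/kg/min.
#' @param resting_hr_mean,resting_hr_sd,max_hr_mean,max_hr_sd HR anchors,
#'   bpm.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_low = 9, n_moderate = 31, n_high = 33,
                              seed = 1L,
                              protocol = protocol_spec(),
                              hr_noise_sd = 3,
                              counts_noise_sd = 150,
                              counts_speed_slope_mean = 1000,
                              counts_speed_slope_sd = 100,
                              counts_intercept = -2500,
                              vo2max_mean = c(low = 31.6, moderate = 40.1,
                                              high = 51.2),
                              vo2max_sd = c(low = 2.2, moderate = 2.7,
                                            high = 3.7),
                              resting_hr_mean = 62, resting_hr_sd = 8,
                              max_hr_mean = 188, max_hr_sd = 9) {
  stopifnot(inherits(protocol, "protocol_spec"),
            hr_noise_sd >= 0, counts_noise_sd >= 0,
            counts_speed_slope_sd >= 0, resting_hr_sd >= 0, max_hr_sd >= 0,
            all(vo2max_sd >= 0))
  structure(
    list(n = c(low = n_low, moderate = n_moderate, high = n_high),
         seed = as.integer(seed), protocol = protocol,
         hr_noise_sd = hr_noise_sd, counts_noise_sd = counts_noise_sd,
         counts_speed_slope_mean = counts_speed_slope_mean,
         counts_speed_slope_sd = counts_speed_slope_sd,
         counts_intercept = counts_intercept,
         vo2max_mean = vo2max_mean, vo2max_sd = vo2max_sd,
         resting_hr_mean = resting_hr_mean, resting_hr_sd = resting_hr_sd,
         max_hr_mean = max_hr_mean, max_hr_sd = max_hr_sd),
    class = "simulation_config")
}

# Oxygen cost of locomotion (ml/kg/min): walking economy 0.1 * v + 3.5
# below the run threshold, running economy 0.2 * v + 3.5 at/above it
# (v in m/min).
demand_vo2 <- function(speed_kph, protocol) {
  v <- speed_kph * 1000 / 60
  if (speed_kph < protocol$run_threshold_kph) 0.1 * v + 3.5 else 0.2 * v + 3.5
}

# Walking-equivalent speed (kph) carrying the same net oxygen demand:
# the counts model is linear in this, so counts track metabolic demand
# and jump at the walk-to-run transition just as VO2 does.
walking_equivalent_kph <- function(speed_kph, protocol) {
  (demand_vo2(speed_kph, protocol) - 3.5) / (0.1 * 1000 / 60)
}

#' Simulate one subject profile
#'
#' Draws VO2max from the group's normal distribution truncated (by redraw)
#' to the group's MET bounds, and resting/maximal HR with a reserve of at
#' least 60 bpm enforced by redraw. Age, sex, height and weight are drawn
#' from plausible young-adult distributions. Uses the current RNG state;
#' seed it (or use [simulate_cohort()]) for reproducibility.
#'
#' @param group `"low"`, `"moderate"` or `"high"`.
#' @param config A [simulation_config()].
#' @param subject_id Identifier for the profile.
#' @return A [subject_profile()].
#' @export
simulate_profile <- function(group = c("low", "moderate", "high"),
                             config = simulation_config(),
                             subject_id = "S001") {
  group <- match.arg(group)
  draw_until <- function(gen, ok, what) {
    for (i in 1:100) {
      x <- gen()
      if (ok(x)) return(x)
    }
    stop(sprintf("simulation error: could not draw a valid %s in 100 tries",
                 what), call. = FALSE)
  }
  in_group <- function(met) switch(group,
    low = met < 10, moderate = met >= 10 && met <= 13, high = met > 13)
  vo2 <- draw_until(
    function() stats::rnorm(1, config$vo2max_mean[[group]],
                            config$vo2max_sd[[group]]),
    function(x) x > 3.5 && in_group(x / 3.5), "vo2max")
  hrs <- draw_until(
    function() c(stats::rnorm(1, config$resting_hr_mean, config$resting_hr_sd),
                 stats::rnorm(1, config$max_hr_mean, config$max_hr_sd)),
    function(x) x[2] - x[1] >= 60 && x[1] > 30, "heart-rate pair")
  age <- min(39, max(18, round(stats::rnorm(1, 26, 5))))
  sex <- sample(c("M", "F"), 1)
  height <- stats::rnorm(1, if (sex == "M") 178 else 165, 7)
  bmi <- stats::rnorm(1, 24.5, 3.5)
  subject_profile(subject_id, age = age, sex = sex, height = height,
                  weight = bmi * (height / 100)^2,
                  resting_hr = round(hrs[1]), max_hr = round(hrs[2]),
                  vo2max = vo2)
}

#' Steady-state heart-rate and count response at one speed
#'
#' The generator's physiological bridge: oxygen demand comes from standard
#' walking/running economy; %HRR is set equal to the percent oxygen-uptake
#' reserve `(VO2 - 3.5) / (vo2max - 3.5)` (the usual exercise-prescription
#' approximation), clipped to `[0, 1.05]`; heart rate is
#' `rest + %HRR * (max - rest)` plus Gaussian noise. Counts are linear in
#' metabolic demand — `intercept + slope * walking-equivalent speed` —
#' plus Gaussian noise, floored at 0, and independent of fitness, so the
#' same speed always yields the same expected counts regardless of VO2max.
#'
#' @param profile A [subject_profile()] with `vo2max > 3.5`.
#' @param speed Treadmill speed, kph (> 0).
#' @param config A [simulation_config()] (noise SDs, counts model).
#' @param counts_slope Subject's counts-per-kph slope; defaults to the
#'   configured mean.
#' @return Named numeric `c(hr = ..., counts = ...)`, one noisy minute.
#' @export
steady_state_response <- function(profile, speed,
                                  config = simulation_config(),
                                  counts_slope =
                                    config$counts_speed_slope_mean) {
  stopifnot(inherits(profile, "subject_profile"), speed > 0)
  if (profile$vo2max <= 3.5)
    stop("invalid profile: vo2max must exceed 3.5 ml/kg/min", call. = FALSE)
  vo2 <- demand_vo2(speed, config$protocol)
  p <- (vo2 - 3.5) / (profile$vo2max - 3.5)
  p <- min(max(p, 0), 1.05)
  hr <- profile$resting_hr + p * (profile$max_hr - profile$resting_hr) +
    stats::rnorm(1, 0, config$hr_noise_sd)
  veq <- walking_equivalent_kph(speed, config$protocol)
  counts <- max(0, config$counts_intercept + counts_slope * veq +
                  stats::rnorm(1, 0, config$counts_noise_sd))
  c(hr = hr, counts = counts)
}

#' Simulate a subject's calibration session
#'
#' Walks the subject minute-by-minute through the protocol stages via
#' [steady_state_response()]. The session is truncated at the first
#' recorded minute whose heart rate reaches
#' `termination_fraction * max_hr`; that minute is recorded and the
#' session flagged `terminated_early`. Uses the current RNG state.
#'
#' @param profile A [subject_profile()].
#' @param config A [simulation_config()].
#' @param counts_slope Subject counts-per-kph slope; if `NULL`, drawn from
#'   the configured between-subject distribution.
#' @return A [calibration_session()]; the slope used is attached as
#'   attribute `"counts_slope"`.
#' @export
simulate_session <- function(profile, config = simulation_config(),
                             counts_slope = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  if (is.null(counts_slope))
    counts_slope <- stats::rnorm(1, config$counts_speed_slope_mean,
                                 config$counts_speed_slope_sd)
  threshold <- config$protocol$termination_fraction * profile$max_hr
  stages <- list()
  terminated <- FALSE
  for (speed in config$protocol$speeds) {
    hr <- counts <- numeric(0)
    for (m in seq_len(config$protocol$stage_minutes)) {
      r <- steady_state_response(profile, speed, config, counts_slope)
      hr <- c(hr, r[["hr"]]); counts <- c(counts, r[["counts"]])
      if (r[["hr"]] >= threshold) { terminated <- TRUE; break }
    }
    if (length(hr) > 0)
      stages <- c(stages, list(calibration_stage(
        speed, hr, counts, planned_duration = config$protocol$stage_minutes)))
    if (terminated) break
  }
  session <- calibration_session(
    profile, stages, terminated_early = terminated,
    termination_reason = if (terminated)
      sprintf("reached %g%% of maximal HR",
              100 * config$protocol$termination_fraction) else NA_character_)
  attr(session, "counts_slope") <- counts_slope
  session
}

#' True generating cutpoints of a simulated subject
#'
#' Because simulated counts are linear in metabolic demand and %HRR equals
#' the percent oxygen-uptake reserve, each subject's generating
#' counts-vs-%HRR relation is exactly linear:
#' `counts(p) = intercept + slope * (p/100) * (vo2max - 3.5) / 1.6667`.
#' This closed form is the ground truth that calibration on noisy sessions
#' is measured against.
#'
#' @param profile A [subject_profile()].
#' @param counts_slope The subject's counts-per-kph slope (attribute
#'   `"counts_slope"` of a simulated session).
#' @param config A [simulation_config()].
#' @param moderate_pct,vigorous_pct Target %HRR values.
#' @return Named numeric `c(moderate = ..., vigorous = ...)`, counts/min.
#' @export
true_cutpoints <- function(profile, counts_slope,
                           config = simulation_config(),
                           moderate_pct = 40, vigorous_pct = 60) {
  kph_per_pct <- (profile$vo2max - 3.5) / 100 / (0.1 * 1000 / 60)
  at <- function(pct) config$counts_intercept +
    counts_slope * kph_per_pct * pct
  c(moderate = at(moderate_pct), vigorous = at(vigorous_pct))
}

#' Simulate a full cohort
#'
#' Seeds the RNG from `config$seed`, then draws the configured number of
#' subjects per fitness group, a counts slope per subject, and a
#' calibration session per subject. Fully deterministic given the config.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_cohort`: a list of records, each
#'   with `profile`, `group`, `counts_slope`, `session` and
#'   `true_cutpoints` (at 40/60% HRR).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  set.seed(config$seed)
  records <- list()
  i <- 0L
  for (group in c("low", "moderate", "high")) {
    for (k in seq_len(config$n[[group]])) {
      i <- i + 1L
      profile <- simulate_profile(group, config,
                                  subject_id = sprintf("S%03d", i))
      slope <- stats::rnorm(1, config$counts_speed_slope_mean,
                            config$counts_speed_slope_sd)
      session <- simulate_session(profile, config, counts_slope = slope)
      records[[i]] <- list(profile = profile, group = group,
                           counts_slope = slope, session = session,
                           true_cutpoints = true_cutpoints(profile, slope,
                                                           config))
    }
  }
  structure(records, class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("<simulated_cohort> %d subjects (%s)\n", length(x),
              paste(sprintf("%s n=%d", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Calibrate every subject of a simulated cohort
#'
#' Runs [calibrate_subject()] on each simulated session and assembles the
#' per-subject cohort table. Subjects whose session cannot be calibrated
#' (fewer than 3 usable stages) are dropped with a message.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param orientation Regression orientation, see [fit_cutpoint_model()].
#' @return Data frame with one row per calibrated subject: `subject_id`,
#'   `group`, `vo2max`, `age`, `sex`, `height_cm`, `weight_kg`, `slope`,
#'   `intercept`, `r_squared`, `moderate_cut`, `vigorous_cut`,
#'   `true_moderate`, `true_vigorous`.
#' @export
calibrate_cohort <- function(cohort, orientation = "counts_on_hrr") {
  stopifnot(inherits(cohort, "simulated_cohort"))
  rows <- lapply(cohort, function(rec) {
    res <- tryCatch(calibrate_subject(rec$session, orientation = orientation),
                    error = function(e) {
                      message(conditionMessage(e)); NULL
                    })
    if (is.null(res)) return(NULL)
    p <- rec$profile
    data.frame(subject_id = p$subject_id, group = rec$group,
               vo2max = p$vo2max, age = p$age, sex = p$sex,
               height_cm = p$height, weight_kg = p$weight,
               slope = res$model$slope, intercept = res$model$intercept,
               r_squared = res$model$r_squared,
               moderate_cut = res$cutpoints$moderate_cut,
               vigorous_cut = res$cutpoints$vigorous_cut,
               true_moderate = rec$true_cutpoints[["moderate"]],
               true_vigorous = rec$true_cutpoints[["vigorous"]])
  })
  do.call(rbind, rows)
}

#' Convert a simulated session to writable series
#'
#' Flattens a session's stage minutes into one [epoch_series()] (60 s
#' epochs) and a minute-level HR data frame sharing the same clock, the
#' same dialects the file readers consume.
#'
#' @param session A [calibration_session()].
#' @param start_time POSIXct start of the first minute.
#' @return List with `counts` (an [epoch_series()]) and `hr` (data frame
#'   `timestamp`, `hr`).
#' @export
session_series <- function(session,
                           start_time = as.POSIXct("2000-01-01 08:00:00",
                                                   tz = "UTC")) {
  stopifnot(inherits(session, "calibration_session"))
  hr <- unlist(lapply(session$stages, `[[`, "minute_hr"))
  counts <- unlist(lapply(session$stages, `[[`, "minute_counts"))
  ts <- start_time + (seq_along(hr) - 1L) * 60
  list(counts = epoch_series(session$subject$subject_id, counts,
                             start_time = start_time, epoch_length = 60),
       hr = data.frame(timestamp = ts, hr = hr))
}
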