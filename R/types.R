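#' Subject physiological profile
#'
#' Bundles the per-subject physiological inputs needed to express exercise
#' heart rate as a percentage of heart-rate reserve (HRR = `max_hr -
#' resting_hr`) and to stratify subjects by cardiorespiratory fitness.
#'
#' @param subject_id Character identifier.
#' @param age Age in years (>= 18).
#' @param sex `"M"` or `"F"`.
#' @param height Standing height in cm.
#' @param weight Body mass in kg.
#' @param resting_hr Resting heart rate, beats/min.
#' @param max_hr Measured maximal heart rate, beats/min; must exceed
#'   `resting_hr`.
#' @param vo2max Maximal oxygen uptake, ml/kg/min (> 0). Measured during a
#'   maximal exercise test; it is an input here, never estimated.
#'
#' @return An object of class `subject_profile`.
#' @export
#' @examples
#' subject_profile("S001", age = 26, sex = "F", height = 168, weight = 62,
#'                 resting_hr = 62, max_hr = 188, vo2max = 44)
subject_profile <- function(subject_id, age, sex, height, weight,
                            resting_hr, max_hr, vo2max) {
  sex <- match.arg(as.character(sex), c("M", "F"))
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.finite(age) || age < 18)
    stop("invalid profile: age must be >= 18 years", call. = FALSE)
  if (!is.finite(height) || height <= 0 || !is.finite(weight) || weight <= 0)
    stop("invalid profile: height and weight must be positive", call. = FALSE)
  if (!is.finite(vo2max) || vo2max <= 0)
    stop("invalid profile: vo2max must be > 0", call. = FALSE)
  if (!is.finite(max_hr) || !is.finite(resting_hr) || max_hr <= resting_hr)
    stop("invalid profile: max_hr must exceed resting_hr", call. = FALSE)
  structure(
    list(subject_id = subject_id, age = as.numeric(age), sex = sex,
         height = as.numeric(height), weight = as.numeric(weight),
         resting_hr = as.numeric(resting_hr), max_hr = as.numeric(max_hr),
         vo2max = as.numeric(vo2max)),
    class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s: %s, %g y, %g cm, %g kg\n",
              x$subject_id, x$sex, x$age, x$height, x$weight))
  cat(sprintf("  resting HR %g, max HR %g bpm; VO2max %g ml/kg/min (%.1f MET)\n",
              x$resting_hr, x$max_hr, x$vo2max, x$vo2max / 3.5))
  invisible(x)
}

#' Body-mass index from a profile
#'
#' @param profile A [subject_profile()].
#' @return BMI in kg/m^2, computed as `weight / (height/100)^2`.
#' @export
profile_bmi <- function(profile) {
  profile$weight / (profile$height / 100)^2
}

#' One treadmill stage of a submaximal calibration test
#'
#' A constant-speed stage with minute-level heart-rate and activity-count
#' recordings. Stages are nominally 5 min; a terminated stage may carry
#' fewer recorded minutes.
#'
#' @param speed Treadmill speed in kph.
#' @param minute_hr Numeric vector of minute heart rates (beats/min).
#' @param minute_counts Numeric vector of minute activity counts
#'   (counts/min), same length as `minute_hr`, all >= 0.
#' @param planned_duration Planned stage length in minutes (default 5).
#'
#' @return An object of class `calibration_stage`.
#' @export
calibration_stage <- function(speed, minute_hr, minute_counts,
                              planned_duration = 5) {
  if (!is.finite(speed) || speed <= 0)
    stop("stage speed must be positive", call. = FALSE)
  if (length(minute_hr) != length(minute_counts))
    stop("minute_hr and minute_counts must have equal length", call. = FALSE)
  if (any(!is.finite(minute_hr)) || any(!is.finite(minute_counts)))
    stop("minute series must be finite", call. = FALSE)
  if (any(minute_counts < 0))
    stop("minute_counts must be non-negative", call. = FALSE)
  structure(
    list(speed = as.numeric(speed),
         planned_duration = as.numeric(planned_duration),
         minute_hr = as.numeric(minute_hr),
         minute_counts = as.numeric(minute_counts)),
    class = "calibration_stage")
}

#' A subject's submaximal calibration session
#'
#' Ordered treadmill stages (strictly increasing speed) recorded for one
#' subject, optionally flagged as terminated early (the protocol stops once
#' heart rate reaches a set fraction of maximal HR).
#'
#' @param subject A [subject_profile()].
#' @param stages List of [calibration_stage()] objects, speeds strictly
#'   increasing.
#' @param terminated_early Logical flag.
#' @param termination_reason Free-text reason (optional).
#'
#' @return An object of class `calibration_session`.
#' @export
calibration_session <- function(subject, stages, terminated_early = FALSE,
                                termination_reason = NA_character_) {
  stopifnot(inherits(subject, "subject_profile"), is.list(stages))
  if (length(stages) < 1L)
    stop("a session needs at least one stage", call. = FALSE)
  ok <- vapply(stages, inherits, logical(1), "calibration_stage")
  if (!all(ok)) stop("stages must be calibration_stage objects", call. = FALSE)
  speeds <- vapply(stages, `[[`, numeric(1), "speed")
  if (any(diff(speeds) <= 0))
    stop("stage speeds must be strictly increasing", call. = FALSE)
  structure(
    list(subject = subject, stages = stages,
         terminated_early = isTRUE(terminated_early),
         termination_reason = termination_reason),
    class = "calibration_session")
}

#' @export
print.calibration_session <- function(x, ...) {
  speeds <- vapply(x$stages, `[[`, numeric(1), "speed")
  mins <- vapply(x$stages, function(s) length(s$minute_hr), integer(1))
  cat(sprintf("<calibration_session> subject %s: %d stage(s)\n",
              x$subject$subject_id, length(x$stages)))
  cat(sprintf("  speeds (kph): %s; minutes: %s\n",
              paste(speeds, collapse = ", "), paste(mins, collapse = ", ")))
  if (x$terminated_early)
    cat(sprintf("  terminated early (%s)\n", x$termination_reason))
  invisible(x)
}

#' Cutpoint scheme for intensity classification
#'
#' A pair of counts/min thresholds separating light, moderate and vigorous
#' intensity. The band is left-closed: counts in
#' `[moderate_cut, vigorous_cut)` are moderate, `>= vigorous_cut` vigorous.
#'
#' @param name Scheme label.
#' @param moderate_cut Lower edge of the moderate band, counts/min.
#' @param vigorous_cut Lower edge of the vigorous band, counts/min; must
#'   exceed `moderate_cut`.
#' @param provenance One of `"absolute_freedson"`, `"individualized"`,
#'   `"custom"`.
#'
#' @return An object of class `cutpoint_scheme`.
#' @seealso [freedson_scheme()] for the standard absolute scheme.
#' @export
cutpoint_scheme <- function(name, moderate_cut, vigorous_cut,
                            provenance = c("custom", "absolute_freedson",
                                           "individualized")) {
  provenance <- match.arg(provenance)
  if (!is.finite(moderate_cut) || !is.finite(vigorous_cut) ||
      moderate_cut <= 0 || vigorous_cut <= moderate_cut)
    stop("need 0 < moderate_cut < vigorous_cut", call. = FALSE)
  structure(
    list(name = name, moderate_cut = as.numeric(moderate_cut),
         vigorous_cut = as.numeric(vigorous_cut), provenance = provenance),
    class = "cutpoint_scheme")
}

#' Absolute Freedson cutpoint scheme
#'
#' The widely used absolute intensity thresholds: moderate 1952--5724
#' counts/min, vigorous >= 5725 counts/min. These were derived assuming an
#' average fitness near 10 MET and take no account of the wearer's actual
#' capacity — the comparison point for individualized cutpoints.
#'
#' @return A [cutpoint_scheme()].
#' @export
freedson_scheme <- function() {
  cutpoint_scheme("freedson_absolute", 1952, 5725,
                  provenance = "absolute_freedson")
}

#' @export
print.cutpoint_scheme <- function(x, ...) {
  cat(sprintf("<cutpoint_scheme> %s (%s): moderate >= %g, vigorous >= %g counts/min\n",
              x$name, x$provenance, x$moderate_cut, x$vigorous_cut))
  invisible(x)
}

#' Minute-epoch activity-count series
#'
#' @param subject_id Character identifier.
#' @param counts Non-negative counts per epoch.
#' @param start_time POSIXct start of the first epoch (default origin).
#' @param epoch_length Epoch length in seconds; 60 for faithful use of
#'   per-minute cutpoints. Other lengths are accepted and rescaled to
#'   counts/min at classification time.
#'
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(subject_id, counts,
                         start_time = as.POSIXct("2000-01-01 00:00:00",
                                                 tz = "UTC"),
                         epoch_length = 60) {
  if (length(counts) < 1L) stop("empty epoch series", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("epoch counts must be finite and non-negative", call. = FALSE)
  if (!is.finite(epoch_length) || epoch_length <= 0)
    stop("epoch_length must be positive", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), start_time = start_time,
         epoch_length = as.numeric(epoch_length), counts = as.numeric(counts)),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s: %d epochs of %g s from %s\n",
              x$subject_id, length(x$counts), x$epoch_length,
              format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' Epoch timestamps of a series
#'
#' @param series An [epoch_series()].
#' @return POSIXct vector, one left-closed epoch start per count.
#' @export
epoch_timestamps <- function(series) {
  series$start_time + (seq_along(series$counts) - 1L) * series$epoch_length
}
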