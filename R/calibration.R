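#' Percent heart-rate reserve
#'
#' Expresses a heart rate as a percentage of the heart-rate reserve:
#' `100 * (hr - hr_rest) / (hr_max - hr_rest)`. Resting HR maps to 0% and
#' maximal HR to 100%. Values below 0 or above 100 are returned as-is —
#' validity is the caller's decision.
#'
#' @param hr Heart rate(s), beats/min. Vectorized.
#' @param hr_rest Resting heart rate, beats/min.
#' @param hr_max Maximal heart rate, beats/min; must exceed `hr_rest`.
#' @return %HRR value(s).
#' @export
#' @examples
#' hrr_percent(120, 60, 180)  # 50
hrr_percent <- function(hr, hr_rest, hr_max) {
  if (!is.finite(hr_max) || !is.finite(hr_rest) || hr_max <= hr_rest)
    stop("invalid profile: hr_max must exceed hr_rest", call. = FALSE)
  100 * (hr - hr_rest) / (hr_max - hr_rest)
}

#' Summarize one calibration stage
#'
#' Averages the last 2 recorded minutes of a stage to obtain steady-state
#' heart rate and activity counts, then converts the HR to %HRR using the
#' subject's resting and maximal HR. A stage with fewer than 2 recorded
#' minutes is unusable.
#'
#' @param stage A [calibration_stage()].
#' @param profile A [subject_profile()].
#' @return One-row data frame with columns `speed`, `n_minutes`, `mean_hr`,
#'   `mean_counts`, `hrr_pct`, `hrr_in_range`. `hrr_in_range` flags (does
#'   not clip) %HRR values outside `[0, 100]`.
#' @export
stage_summary <- function(stage, profile) {
  stopifnot(inherits(stage, "calibration_stage"),
            inherits(profile, "subject_profile"))
  n <- length(stage$minute_hr)
  if (n < 2L)
    stop(sprintf("stage unusable: %d recorded minute(s) at %g kph, need >= 2",
                 n, stage$speed), call. = FALSE)
  last2 <- (n - 1L):n
  mean_hr <- mean(stage$minute_hr[last2])
  mean_counts <- mean(stage$minute_counts[last2])
  hrr <- hrr_percent(mean_hr, profile$resting_hr, profile$max_hr)
  data.frame(speed = stage$speed, n_minutes = n, mean_hr = mean_hr,
             mean_counts = mean_counts, hrr_pct = hrr,
             hrr_in_range = hrr >= 0 & hrr <= 100)
}

#' Select the calibration stages for regression
#'
#' Applies the last-3-stages rule: stages with fewer than 2 recorded
#' minutes (typically a stage cut short by the 85%-HRmax termination) are
#' dropped, then the final 3 remaining stages, in protocol order, are
#' selected for the per-subject regression.
#'
#' @param session A [calibration_session()].
#' @return List of 3 [calibration_stage()] objects. The number of dropped
#'   stages is attached as attribute `"n_dropped"`.
#' @export
select_calibration_stages <- function(session) {
  stopifnot(inherits(session, "calibration_session"))
  usable <- Filter(function(s) length(s$minute_hr) >= 2L, session$stages)
  if (length(usable) < 3L)
    stop(sprintf(
      "insufficient calibration data for subject %s: %d usable stage(s), need >= 3",
      session$subject$subject_id, length(usable)), call. = FALSE)
  out <- usable[(length(usable) - 2L):length(usable)]
  attr(out, "n_dropped") <- length(session$stages) - length(usable)
  out
}

#' Fit the per-subject cutpoint regression
#'
#' Ordinary least-squares line through the stage summaries. In the default
#' `counts_on_hrr` orientation mean counts is regressed on %HRR, so the
#' fitted line predicts the activity counts expected at a target relative
#' intensity (y = m x + b with y = counts, x = %HRR). The alternative
#' `hrr_on_counts` orientation regresses %HRR on counts; with r-squared < 1 the
#' two orientations give different cutpoints (regression to the mean).
#'
#' A negative slope is physiologically implausible (counts should rise with
#' relative intensity); it raises a warning and is flagged on the model.
#'
#' @param summaries Data frame of stage summaries ([stage_summary()] rows)
#'   with columns `hrr_pct` and `mean_counts`; at least 3 rows.
#' @param orientation `"counts_on_hrr"` (default) or `"hrr_on_counts"`.
#' @return An object of class `cutpoint_model` with elements `slope`,
#'   `intercept`, `orientation`, `r_squared`, `residual_sd`, `n_points`,
#'   `slope_warning`.
#' @export
fit_cutpoint_model <- function(summaries,
                               orientation = c("counts_on_hrr",
                                               "hrr_on_counts")) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(summaries),
            all(c("hrr_pct", "mean_counts") %in% names(summaries)))
  if (nrow(summaries) < 3L)
    stop("need at least 3 stage summaries to fit", call. = FALSE)
  if (orientation == "counts_on_hrr") {
    x <- summaries$hrr_pct; y <- summaries$mean_counts
  } else {
    x <- summaries$mean_counts; y <- summaries$hrr_pct
  }
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop("singular fit: regressor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # noise-free fits are legitimate here; silence summary.lm's perfect-fit note
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope <- unname(stats::coef(fit)[2L])
  slope_warning <- slope < 0
  if (slope_warning)
    warning("calibration failure flagged: negative slope", call. = FALSE)
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
         orientation = orientation, r_squared = sm$r.squared,
         residual_sd = sm$sigma, n_points = nrow(summaries),
         slope_warning = slope_warning),
    class = "cutpoint_model")
}

#' @export
print.cutpoint_model <- function(x, ...) {
  cat(sprintf("<cutpoint_model> [%s] slope %.4g, intercept %.4g (n = %d)\n",
              x$orientation, x$slope, x$intercept, x$n_points))
  cat(sprintf("  r-squared %.4f, residual SD %.4g%s\n", x$r_squared,
              x$residual_sd,
              if (isTRUE(x$slope_warning)) " [FLAG: negative slope]" else ""))
  invisible(x)
}

#' Derive individualized cutpoints from a fitted model
#'
#' Evaluates the calibration line at the target relative intensities
#' (40% and 60% HRR by default). For `counts_on_hrr` models the cutpoint is
#' `slope * pct + intercept`; for `hrr_on_counts` the line is inverted
#' algebraically, `(pct - intercept) / slope`.
#'
#' @param model A [fit_cutpoint_model()] result.
#' @param moderate_pct %HRR defining the moderate threshold (default 40).
#' @param vigorous_pct %HRR defining the vigorous threshold (default 60);
#'   must exceed `moderate_pct`.
#' @return An object of class `cutpoint_pair` with `moderate_cut`,
#'   `vigorous_cut` (counts/min) and the target percentages.
#' @export
derive_cutpoints <- function(model, moderate_pct = 40, vigorous_pct = 60) {
  stopifnot(inherits(model, "cutpoint_model"))
  if (!(moderate_pct < vigorous_pct))
    stop("moderate_pct must be below vigorous_pct", call. = FALSE)
  at <- function(pct) {
    if (model$orientation == "counts_on_hrr") {
      model$slope * pct + model$intercept
    } else {
      if (model$slope == 0)
        stop("division error: hrr_on_counts model has zero slope",
             call. = FALSE)
      (pct - model$intercept) / model$slope
    }
  }
  mod <- at(moderate_pct); vig <- at(vigorous_pct)
  if (!is.finite(mod) || !is.finite(vig) || mod <= 0 || vig <= 0)
    stop(sprintf(
      "calibration failure: non-positive cutpoint (%.4g at %g%%, %.4g at %g%%)",
      mod, moderate_pct, vig, vigorous_pct), call. = FALSE)
  structure(
    list(moderate_cut = mod, vigorous_cut = vig,
         moderate_pct = moderate_pct, vigorous_pct = vigorous_pct),
    class = "cutpoint_pair")
}

#' @export
print.cutpoint_pair <- function(x, ...) {
  cat(sprintf("<cutpoint_pair> %g counts/min @ %g%% HRR; %g counts/min @ %g%% HRR\n",
              round(x$moderate_cut, 1), x$moderate_pct,
              round(x$vigorous_cut, 1), x$vigorous_pct))
  invisible(x)
}

#' Calibrate a subject end-to-end
#'
#' Deterministic pipeline: select the last 3 usable stages, summarize each
#' (last-2-minute averages, %HRR), fit the OLS calibration line, evaluate
#' it at the target intensities. Errors from each step are propagated with
#' the subject id attached.
#'
#' @inheritParams fit_cutpoint_model
#' @inheritParams derive_cutpoints
#' @param session A [calibration_session()].
#' @return An object of class `calibration_result`: a list with
#'   `subject_id`, `summaries` (data frame), `model`, `cutpoints`,
#'   `n_stages_dropped`.
#' @export
calibrate_subject <- function(session,
                              orientation = c("counts_on_hrr",
                                              "hrr_on_counts"),
                              moderate_pct = 40, vigorous_pct = 60) {
  stopifnot(inherits(session, "calibration_session"))
  orientation <- match.arg(orientation)
  id <- session$subject$subject_id
  stages <- select_calibration_stages(session)
  summaries <- do.call(rbind, lapply(stages, stage_summary,
                                     profile = session$subject))
  model <- tryCatch(fit_cutpoint_model(summaries, orientation),
                    error = function(e) stop(sprintf("subject %s: %s", id,
                                                     conditionMessage(e)),
                                             call. = FALSE))
  cuts <- tryCatch(derive_cutpoints(model, moderate_pct, vigorous_pct),
                   error = function(e) stop(sprintf("subject %s: %s", id,
                                                    conditionMessage(e)),
                                            call. = FALSE))
  structure(
    list(subject_id = id, summaries = summaries, model = model,
         cutpoints = cuts, n_stages_dropped = attr(stages, "n_dropped")),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> subject %s (%d stage(s) dropped)\n",
              x$subject_id, x$n_stages_dropped))
  print(x$model); print(x$cutpoints)
  invisible(x)
}

#' Turn a calibration result into a cutpoint scheme
#'
#' @param result A [calibrate_subject()] result.
#' @return A [cutpoint_scheme()] with provenance `"individualized"`.
#' @export
as_cutpoint_scheme <- function(result) {
  stopifnot(inherits(result, "calibration_result"))
  cutpoint_scheme(paste0("individualized_", result$subject_id),
                  result$cutpoints$moderate_cut,
                  result$cutpoints$vigorous_cut,
                  provenance = "individualized")
}
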