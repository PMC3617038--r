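#' Classify counts/min values into intensity categories
#'
#' Left-closed bands: `light` below `moderate_cut`, `moderate` in
#' `[moderate_cut, vigorous_cut)`, `vigorous` at or above `vigorous_cut`.
#' Matches the printed Freedson moderate band 1952--5724 counts/min
#' (inclusive at 1952, vigorous from 5725); the same rule is applied to
#' individualized schemes.
#'
#' @param counts Non-negative counts/min value(s). Vectorized.
#' @param scheme A [cutpoint_scheme()].
#' @return Factor with levels `light`, `moderate`, `vigorous`.
#' @export
#' @examples
#' classify_epoch(c(0, 1952, 5724, 5725), freedson_scheme())
classify_epoch <- function(counts, scheme) {
  stopifnot(inherits(scheme, "cutpoint_scheme"))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  lab <- ifelse(counts >= scheme$vigorous_cut, "vigorous",
                ifelse(counts >= scheme$moderate_cut, "moderate", "light"))
  factor(lab, levels = c("light", "moderate", "vigorous"))
}

#' Time spent in each intensity category
#'
#' Classifies every epoch of a series under a scheme and totals minutes per
#' category. Counts are interpreted as counts/min: epochs shorter or longer
#' than 60 s are rescaled by `60 / epoch_length` before classification and
#' each epoch contributes `epoch_length / 60` minutes, so the category
#' totals always sum exactly to total wear time.
#'
#' @param series An [epoch_series()].
#' @param scheme A [cutpoint_scheme()].
#' @return An object of class `intensity_profile`: list with `scheme_name`,
#'   `minutes_light`, `minutes_moderate`, `minutes_vigorous`,
#'   `total_minutes`.
#' @export
time_in_intensity <- function(series, scheme) {
  stopifnot(inherits(series, "epoch_series"))
  if (length(series$counts) == 0L)
    stop("empty epoch series", call. = FALSE)
  cpm <- series$counts * 60 / series$epoch_length
  cls <- classify_epoch(cpm, scheme)
  per_epoch_min <- series$epoch_length / 60
  n <- table(cls)
  structure(
    list(scheme_name = scheme$name,
         minutes_light = unname(n[["light"]]) * per_epoch_min,
         minutes_moderate = unname(n[["moderate"]]) * per_epoch_min,
         minutes_vigorous = unname(n[["vigorous"]]) * per_epoch_min,
         total_minutes = length(cls) * per_epoch_min),
    class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "<intensity_profile> [%s] light %g, moderate %g, vigorous %g of %g min\n",
    x$scheme_name, x$minutes_light, x$minutes_moderate, x$minutes_vigorous,
    x$total_minutes))
  invisible(x)
}

#' Compare two cutpoint schemes on the same series
#'
#' Classifies one epoch series under two schemes and reports, per category,
#' the minute difference (scheme `a` minus scheme `b`) plus the number of
#' epochs the two schemes classify differently. This is how the
#' absolute-vs-individualized discrepancy in recorded moderate/vigorous
#' time is quantified.
#'
#' @param series An [epoch_series()].
#' @param a,b [cutpoint_scheme()] objects.
#' @return List with `profile_a`, `profile_b`, `minute_diff` (named numeric,
#'   a - b per category) and `discordant_epochs`.
#' @export
compare_schemes <- function(series, a, b) {
  pa <- time_in_intensity(series, a)
  pb <- time_in_intensity(series, b)
  cpm <- series$counts * 60 / series$epoch_length
  discord <- sum(classify_epoch(cpm, a) != classify_epoch(cpm, b))
  list(profile_a = pa, profile_b = pb,
       minute_diff = c(light = pa$minutes_light - pb$minutes_light,
                       moderate = pa$minutes_moderate - pb$minutes_moderate,
                       vigorous = pa$minutes_vigorous - pb$minutes_vigorous),
       discordant_epochs = discord)
}

#' Intensity profile as a one-row data frame
#'
#' @param profile An [time_in_intensity()] result.
#' @param subject_id Optional subject id column value.
#' @return One-row data frame (`subject_id`, `scheme`, `light_min`,
#'   `moderate_min`, `vigorous_min`).
#' @export
intensity_profile_df <- function(profile, subject_id = NA_character_) {
  stopifnot(inherits(profile, "intensity_profile"))
  data.frame(subject_id = subject_id, scheme = profile$scheme_name,
             light_min = profile$minutes_light,
             moderate_min = profile$minutes_moderate,
             vigorous_min = profile$minutes_vigorous)
}
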