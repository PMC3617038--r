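#' Assign cardiorespiratory fitness groups
#'
#' Converts VO2max to MET capacity (`vo2max / 3.5`, 1 MET = 3.5 ml
#' O2/kg/min) and assigns low (< 10 MET), moderate (10--13 MET, closed
#' interval) or high (> 13 MET) fitness. The three-group split mirrors the
#' very poor / poor-to-fair / good-and-above bands for young adults.
#'
#' @param vo2max VO2max value(s) in ml/kg/min, all > 0. Vectorized.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
#' @examples
#' assign_fitness_group(c(31.6, 35, 51.2))
assign_fitness_group <- function(vo2max) {
  if (any(!is.finite(vo2max)) || any(vo2max <= 0))
    stop("invalid profile: vo2max must be > 0", call. = FALSE)
  met <- vo2max / 3.5
  lab <- ifelse(met < 10, "low", ifelse(met <= 13, "moderate", "high"))
  factor(lab, levels = c("low", "moderate", "high"))
}

#' MET bounds of the fitness groups
#'
#' @return Data frame with `group`, `met_min`, `met_max` (open/closed per
#'   [assign_fitness_group()]).
#' @export
fitness_group_bounds <- function() {
  data.frame(group = factor(c("low", "moderate", "high"),
                            levels = c("low", "moderate", "high")),
             met_min = c(-Inf, 10, 13), met_max = c(10, 13, Inf))
}

#' Per-group cutpoint statistics
#'
#' Sample mean and SD (n - 1 denominator) of the individualized moderate
#' and vigorous cutpoints within each fitness group. Groups with no
#' members appear with `n = 0` and `NA` statistics; single-member groups
#' have a mean but `NA` SD.
#'
#' @param cohort Data frame with columns `vo2max`, `moderate_cut`,
#'   `vigorous_cut` (one row per subject), or a column `group` already
#'   holding fitness labels.
#' @return Data frame with one row per group x intensity: `group`,
#'   `intensity`, `n`, `mean`, `sd`.
#' @export
group_cutpoint_stats <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("moderate_cut", "vigorous_cut") %in% names(cohort)))
  grp <- if ("group" %in% names(cohort)) {
    factor(cohort$group, levels = c("low", "moderate", "high"))
  } else {
    assign_fitness_group(cohort$vo2max)
  }
  out <- expand.grid(group = levels(grp),
                     intensity = c("moderate", "vigorous"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  col <- c(moderate = "moderate_cut", vigorous = "vigorous_cut")
  stats <- lapply(seq_len(nrow(out)), function(i) {
    v <- cohort[grp == out$group[i], col[[out$intensity[i]]]]
    c(n = length(v),
      mean = if (length(v) >= 1) mean(v) else NA_real_,
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  })
  cbind(out, do.call(rbind, stats))
}

#' One-way ANOVA comparison of a cutpoint across groups
#'
#' Classic equal-variance one-way ANOVA
#' (F = (SSB / (k - 1)) / (SSW / (N - k))) across fitness groups, followed
#' by pairwise Welch two-sample t-tests with Bonferroni adjustment over the
#' group pairs. Groups with fewer than 2 members are excluded; at least two
#' usable groups are required. Significance is conventionally read at
#' p < 0.05.
#'
#' @param values Numeric vector (e.g. moderate cutpoints).
#' @param groups Factor or vector of group labels, same length.
#' @return An object of class `group_comparison`: list with `stats`
#'   (per-group n/mean/sd data frame), `F_statistic`, `df`, `anova_p`,
#'   `pairwise` (data frame: `group1`, `group2`, `mean_diff`, `p_adj`).
#' @export
compare_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  keep <- names(which(table(groups) >= 2))
  if (length(keep) < 2L)
    stop("comparison error: need >= 2 groups with >= 2 members each",
         call. = FALSE)
  sel <- groups %in% keep
  values <- values[sel]; groups <- droplevels(groups[sel])
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  per <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd)))
  pairs <- utils::combn(levels(groups), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- values[groups == pairs[1, j]]
    g2 <- values[groups == pairs[2, j]]
    tt <- stats::t.test(g1, g2)  # Welch
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               mean_diff = mean(g1) - mean(g2), p_raw = tt$p.value)
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "bonferroni")
  structure(
    list(stats = per,
         F_statistic = unname(fit$statistic),
         df = unname(fit$parameter),
         anova_p = fit$p.value,
         pairwise = pw[, c("group1", "group2", "mean_diff", "p_adj")]),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%g, %g) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$F_statistic, x$anova_p))
  print(x$stats, row.names = FALSE)
  cat("pairwise (Welch, Bonferroni-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Deviation of individualized cutpoints from an absolute scheme
#'
#' Signed difference, individualized minus absolute, at each intensity:
#' positive values mean the absolute scheme's threshold is reached at a
#' lower relative intensity than the individualized one.
#'
#' @param pair A [derive_cutpoints()] result (or any list with
#'   `moderate_cut`/`vigorous_cut`).
#' @param absolute A [cutpoint_scheme()], typically [freedson_scheme()].
#' @return Named numeric `c(moderate = ..., vigorous = ...)` in counts/min.
#' @export
#' @examples
#' pair <- structure(list(moderate_cut = 5037, vigorous_cut = 7367,
#'                        moderate_pct = 40, vigorous_pct = 60),
#'                   class = "cutpoint_pair")
#' cutpoint_deviation(pair, freedson_scheme())  # +3085, +1642
cutpoint_deviation <- function(pair, absolute = freedson_scheme()) {
  stopifnot(inherits(absolute, "cutpoint_scheme"))
  c(moderate = pair$moderate_cut - absolute$moderate_cut,
    vigorous = pair$vigorous_cut - absolute$vigorous_cut)
}

#' Correlate individualized cutpoints with a subject covariate
#'
#' Squared Pearson correlation between a covariate (VO2max, age or BMI)
#' and the individualized cutpoint values at one intensity — the ancillary
#' check of how much of the between-subject cutpoint variability fitness
#' explains compared with age or body size.
#'
#' @param cohort Data frame with per-subject columns `moderate_cut`,
#'   `vigorous_cut` and the covariate: `vo2max`, `age`, or (for BMI)
#'   `height_cm` and `weight_kg`.
#' @param covariate `"vo2max"`, `"age"` or `"bmi"`.
#' @param intensity `"moderate"` or `"vigorous"`.
#' @param intensity_pct %HRR label carried on the result (defaults 40/60
#'   matching the intensity).
#' @return An object of class `covariate_association`: list with
#'   `covariate`, `intensity_pct`, `r_squared`, `n`.
#' @export
correlate_cutpoints <- function(cohort,
                                covariate = c("vo2max", "age", "bmi"),
                                intensity = c("moderate", "vigorous"),
                                intensity_pct = NULL) {
  covariate <- match.arg(covariate)
  intensity <- match.arg(intensity)
  stopifnot(is.data.frame(cohort))
  x <- switch(covariate,
              vo2max = cohort$vo2max,
              age = cohort$age,
              bmi = cohort$weight_kg / (cohort$height_cm / 100)^2)
  y <- cohort[[c(moderate = "moderate_cut",
                 vigorous = "vigorous_cut")[[intensity]]]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need >= 3 subjects with covariate present", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  if (is.null(intensity_pct))
    intensity_pct <- c(moderate = 40, vigorous = 60)[[intensity]]
  structure(
    list(covariate = covariate, intensity_pct = intensity_pct,
         r_squared = stats::cor(x, y)^2, n = length(x)),
    class = "covariate_association")
}

#' @export
print.covariate_association <- function(x, ...) {
  cat(sprintf(
    "<covariate_association> %s vs cutpoint @ %g%% HRR: r-squared = %.4f (n = %d)\n",
    x$covariate, x$intensity_pct, x$r_squared, x$n))
  invisible(x)
}

#' Pooled per-group calibration lines
#'
#' Pools stage summaries within each fitness group and fits one OLS line of
#' mean counts on %HRR per group — the plottable group regression-line
#' table.
#'
#' @param summaries Data frame with columns `group`, `hrr_pct`,
#'   `mean_counts` (stacked stage summaries labelled by fitness group).
#' @return Data frame: `group`, `n_points`, `slope`, `intercept`,
#'   `r_squared`.
#' @export
group_regression_table <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("group", "hrr_pct", "mean_counts") %in% names(summaries)))
  grp <- factor(summaries$group, levels = c("low", "moderate", "high"))
  rows <- lapply(levels(grp), function(g) {
    d <- summaries[grp == g & !is.na(grp), , drop = FALSE]
    if (nrow(d) < 3L)
      return(data.frame(group = g, n_points = nrow(d), slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_))
    m <- fit_cutpoint_model(d, orientation = "counts_on_hrr")
    data.frame(group = g, n_points = m$n_points, slope = m$slope,
               intercept = m$intercept, r_squared = m$r_squared)
  })
  do.call(rbind, rows)
}
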