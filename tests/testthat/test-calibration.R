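test_that("hrr_percent anchors rest at 0%, max at 100%, midpoint at 50%", {
  expect_equal(hrr_percent(60, 60, 180), 0)
  expect_equal(hrr_percent(180, 60, 180), 100)
  expect_equal(hrr_percent(120, 60, 180), 50)
  # vectorized, unclipped outside [0, 100]
  expect_equal(hrr_percent(c(48, 192), 60, 180), c(-10, 110))
  expect_error(hrr_percent(100, 180, 60), "hr_max must exceed hr_rest")
})

test_that("stage_summary averages the last two recorded minutes", {
  p <- demo_profile(resting_hr = 60, max_hr = 180)
  s <- calibration_stage(6.4, c(110, 118, 122, 124, 126),
                         c(3000, 3100, 3200, 3300, 3400))
  out <- stage_summary(s, p)
  expect_equal(out$mean_hr, 125)
  expect_equal(out$mean_counts, 3350)
  expect_equal(out$hrr_pct, hrr_percent(125, 60, 180))
  expect_true(out$hrr_in_range)

  const <- calibration_stage(3.2, rep(120, 5), rep(1500, 5))
  expect_equal(stage_summary(const, p)$mean_hr, 120)

  truncated <- calibration_stage(8.0, c(110, 118), c(3000, 3100))
  expect_equal(stage_summary(truncated, p)$mean_hr, 114)

  one_min <- calibration_stage(9.6, 170, 8000)
  expect_error(stage_summary(one_min, p), "stage unusable")
})

test_that("stage_summary flags but does not clip out-of-range %HRR", {
  p <- demo_profile(resting_hr = 60, max_hr = 180)
  hot <- calibration_stage(9.6, rep(186, 3), rep(9000, 3))
  out <- stage_summary(hot, p)
  expect_false(out$hrr_in_range)
  expect_gt(out$hrr_pct, 100)
})

test_that("last-3-stage selection drops short stages first", {
  p <- demo_profile()
  mk <- function(speed, minutes) {
    calibration_stage(speed, rep(120, minutes), rep(3000, minutes))
  }
  # five full stages -> the three fastest
  full <- calibration_session(p, lapply(c(3.2, 4.8, 6.4, 8, 9.6), mk,
                                        minutes = 5))
  sel <- select_calibration_stages(full)
  expect_equal(vapply(sel, `[[`, numeric(1), "speed"), c(6.4, 8, 9.6))
  expect_equal(attr(sel, "n_dropped"), 0L)

  # terminated during stage 4 with 3 recorded minutes -> stages 2-4
  s4 <- calibration_session(p, c(lapply(c(3.2, 4.8, 6.4), mk, minutes = 5),
                                 list(mk(8, 3))), terminated_early = TRUE)
  expect_equal(vapply(select_calibration_stages(s4), `[[`, numeric(1),
                      "speed"), c(4.8, 6.4, 8))

  # a 1-minute terminal stage is unusable and dropped before selection
  s1 <- calibration_session(p, c(lapply(c(3.2, 4.8, 6.4), mk, minutes = 5),
                                 list(mk(8, 1))), terminated_early = TRUE)
  sel1 <- select_calibration_stages(s1)
  expect_equal(vapply(sel1, `[[`, numeric(1), "speed"), c(3.2, 4.8, 6.4))
  expect_equal(attr(sel1, "n_dropped"), 1L)

  # exactly three usable stages -> those three
  s3 <- calibration_session(p, lapply(c(3.2, 4.8, 6.4), mk, minutes = 5))
  expect_equal(vapply(select_calibration_stages(s3), `[[`, numeric(1),
                      "speed"), c(3.2, 4.8, 6.4))

  # two stages -> refusal
  s2 <- calibration_session(p, lapply(c(3.2, 4.8), mk, minutes = 5))
  expect_error(select_calibration_stages(s2), "insufficient calibration")
})

test_that("fit_cutpoint_model recovers a noise-free line exactly", {
  sm <- summaries_df(c(30, 45, 60), 80 * c(30, 45, 60) + 300)
  m <- fit_cutpoint_model(sm)
  expect_equal(m$slope, 80, tolerance = 1e-12)
  expect_equal(m$intercept, 300, tolerance = 1e-10)
  expect_equal(m$r_squared, 1)
  expect_equal(m$n_points, 3L)
  expect_false(m$slope_warning)
})

test_that("fit_cutpoint_model matches the grid-search OLS oracle", {
  hrr <- c(30, 45, 60)
  counts <- c(2500, 3700, 5200)
  m <- fit_cutpoint_model(summaries_df(hrr, counts))
  o <- oracle_ols(hrr, counts)
  expect_equal(m$slope, o[["slope"]], tolerance = 1e-3)
  expect_equal(m$intercept, o[["intercept"]], tolerance = 1e-3)

  set.seed(401)
  for (rep in 1:25) {
    n <- sample(3:5, 1)
    x <- sort(runif(n, 10, 90))
    y <- 2000 + 60 * x + rnorm(n, 0, 400)
    m <- suppressWarnings(fit_cutpoint_model(summaries_df(x, y)))
    o <- oracle_ols(x, y)
    expect_equal(m$slope, o[["slope"]], tolerance = 1e-3)
    expect_equal(m$intercept, o[["intercept"]],
                 tolerance = max(1e-3, abs(o[["intercept"]]) * 1e-3))
  }
})

test_that("degenerate and implausible fits are refused or flagged", {
  expect_error(fit_cutpoint_model(summaries_df(c(40, 40, 40),
                                               c(1000, 2000, 3000))),
               "singular fit")
  expect_error(fit_cutpoint_model(summaries_df(c(30, 45), c(100, 200))),
               "at least 3")
  expect_warning(
    m <- fit_cutpoint_model(summaries_df(c(30, 45, 60),
                                         c(5200, 3700, 2500))),
    "negative slope")
  expect_true(m$slope_warning)
})

test_that("derive_cutpoints evaluates and inverts the line", {
  m <- fit_cutpoint_model(summaries_df(c(30, 45, 60),
                                       80 * c(30, 45, 60) + 300))
  cp <- derive_cutpoints(m)
  expect_equal(cp$moderate_cut, 3500, tolerance = 1e-9)
  expect_equal(cp$vigorous_cut, 5100, tolerance = 1e-9)

  # algebraic inverse of the same line, hrr_on_counts orientation
  inv <- structure(list(slope = 0.0125, intercept = -3.75,
                        orientation = "hrr_on_counts", r_squared = 1,
                        residual_sd = 0, n_points = 3L,
                        slope_warning = FALSE),
                   class = "cutpoint_model")
  cpi <- derive_cutpoints(inv)
  expect_equal(cpi$moderate_cut, 3500)
  expect_equal(cpi$vigorous_cut, 5100)

  # noisy fit: cutpoints equal oracle line evaluated at 40/60
  hrr <- c(30, 45, 60)
  counts <- c(2500, 3700, 5200)
  cp2 <- derive_cutpoints(fit_cutpoint_model(summaries_df(hrr, counts)))
  o <- oracle_ols(hrr, counts)
  expect_equal(cp2$moderate_cut, o[["intercept"]] + 40 * o[["slope"]],
               tolerance = 1e-3)
  expect_equal(cp2$vigorous_cut, o[["intercept"]] + 60 * o[["slope"]],
               tolerance = 1e-3)
})

test_that("derive_cutpoints validates targets and rejects bad geometry", {
  m <- fit_cutpoint_model(summaries_df(c(30, 45, 60),
                                       80 * c(30, 45, 60) + 300))
  expect_error(derive_cutpoints(m, moderate_pct = 60, vigorous_pct = 40),
               "moderate_pct must be below")
  # steep negative intercept pushes the moderate cutpoint below zero
  low <- structure(list(slope = 10, intercept = -1000,
                        orientation = "counts_on_hrr", r_squared = 1,
                        residual_sd = 0, n_points = 3L,
                        slope_warning = FALSE),
                   class = "cutpoint_model")
  expect_error(derive_cutpoints(low), "non-positive cutpoint")
  flat <- structure(list(slope = 0, intercept = 20,
                         orientation = "hrr_on_counts", r_squared = 0,
                         residual_sd = 1, n_points = 3L,
                         slope_warning = FALSE),
                    class = "cutpoint_model")
  expect_error(derive_cutpoints(flat), "division error")
})

test_that("cutpoint spacing is 20 x slope and increasing in pct", {
  set.seed(402)
  for (rep in 1:10) {
    x <- sort(runif(4, 10, 90))
    y <- 1000 + runif(1, 30, 120) * x + rnorm(4, 0, 200)
    m <- fit_cutpoint_model(summaries_df(x, y))
    cp <- derive_cutpoints(m)
    expect_equal(cp$vigorous_cut - cp$moderate_cut, 20 * m$slope,
                 tolerance = 1e-9)
    cp2 <- derive_cutpoints(m, moderate_pct = 45, vigorous_pct = 55)
    expect_gt(cp2$vigorous_cut, cp2$moderate_cut)
  }
})

test_that("orientations agree exactly when r2 = 1 and differ when r2 < 1", {
  p <- demo_profile()
  perfect <- make_line_session(p)
  a <- calibrate_subject(perfect, orientation = "counts_on_hrr")
  b <- calibrate_subject(perfect, orientation = "hrr_on_counts")
  expect_equal(a$model$r_squared, 1)
  expect_equal(a$cutpoints$moderate_cut, b$cutpoints$moderate_cut,
               tolerance = 1e-9)
  expect_equal(a$cutpoints$vigorous_cut, b$cutpoints$vigorous_cut,
               tolerance = 1e-9)

  # perturb one stage -> r2 < 1 -> regression-to-mean splits the two
  noisy <- make_line_session(p, hrr_targets = c(30, 45, 60))
  noisy$stages[[2]]$minute_counts <- noisy$stages[[2]]$minute_counts + 400
  a2 <- calibrate_subject(noisy, orientation = "counts_on_hrr")
  b2 <- calibrate_subject(noisy, orientation = "hrr_on_counts")
  expect_lt(a2$model$r_squared, 1)
  expect_false(isTRUE(all.equal(a2$cutpoints$moderate_cut,
                                b2$cutpoints$moderate_cut)))
})

test_that("calibrate_subject recovers the generating line end-to-end", {
  p <- demo_profile()
  res <- calibrate_subject(make_line_session(p, slope = 80,
                                             intercept = 300))
  expect_equal(res$cutpoints$moderate_cut, 80 * 40 + 300,
               tolerance = 1e-9)
  expect_equal(res$cutpoints$vigorous_cut, 80 * 60 + 300,
               tolerance = 1e-9)
  expect_equal(res$n_stages_dropped, 0L)

  # a 5-stage session terminated during stage 5 uses stages 2-4
  five <- make_line_session(p, hrr_targets = c(20, 30, 40, 50, 60))
  five$stages[[5]]$minute_hr <- five$stages[[5]]$minute_hr[1]
  five$stages[[5]]$minute_counts <- five$stages[[5]]$minute_counts[1]
  res5 <- calibrate_subject(five)
  expect_equal(res5$summaries$speed, c(4.8, 6.4, 8.0))
  expect_equal(res5$n_stages_dropped, 1L)

  two <- make_line_session(p, hrr_targets = c(30, 45))
  expect_error(calibrate_subject(two), "insufficient calibration")
})

test_that("custom target percentages propagate through the pipeline", {
  res <- calibrate_subject(make_line_session(slope = 80, intercept = 300),
                           moderate_pct = 30, vigorous_pct = 50)
  expect_equal(res$cutpoints$moderate_cut, 80 * 30 + 300, tolerance = 1e-9)
  expect_equal(res$cutpoints$vigorous_cut, 80 * 50 + 300, tolerance = 1e-9)
  expect_equal(res$cutpoints$moderate_pct, 30)
})
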