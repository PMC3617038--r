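# Independent brute-force oracles. These deliberately avoid lm(), var(),
# sd(), cor() and oneway.test() so they can cross-check the implementation.

# Least squares by grid search over the slope (closed-form intercept given
# a slope candidate), refined until the slope grid step is negligible.
oracle_ols <- function(x, y) {
  sse <- function(b) {
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2)
  }
  span <- (max(y) - min(y)) / max(max(x) - min(x), 1e-9)
  lo <- -3 * abs(span) - 1
  hi <- 3 * abs(span) + 1
  best <- NA_real_
  for (round in 1:6) {
    grid <- seq(lo, hi, length.out = 401)
    errs <- vapply(grid, sse, numeric(1))
    best <- grid[which.min(errs)]
    step <- grid[2] - grid[1]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  c(slope = best, intercept = mean(y) - best * mean(x))
}

# One-way ANOVA F from explicit between/within sums of squares.
oracle_anova_F <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  gm <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Two-pass sample standard deviation (n - 1 denominator).
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Squared Pearson correlation straight from the covariance formula.
oracle_r2 <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my))^2 / (sum((x - mx)^2) * sum((y - my)^2))
}

# Per-epoch loop-and-count classification tally.
oracle_tally <- function(cpm, scheme) {
  n <- c(light = 0, moderate = 0, vigorous = 0)
  for (v in cpm) {
    if (v >= scheme$vigorous_cut) n[["vigorous"]] <- n[["vigorous"]] + 1
    else if (v >= scheme$moderate_cut) n[["moderate"]] <- n[["moderate"]] + 1
    else n[["light"]] <- n[["light"]] + 1
  }
  n
}

# Mean of a normal truncated to (lo, hi): the generator draws group VO2max
# by redraw inside the group's MET bounds, so this is its true expectation.
oracle_truncnorm_mean <- function(mu, sd, lo = -Inf, hi = Inf) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
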