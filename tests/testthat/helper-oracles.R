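# Independent brute-force oracles used across the suite. These re-derive
# the classical statistics from their defining formulas, deliberately not
# sharing any code path with the package implementations.

oracle_anova_f <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  grand <- mean(y)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  ms_b <- ss_between / (k - 1)
  ms_w <- ss_within / (n - k)
  ms_b / ms_w
}

oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive scan for the always-positive-above threshold
oracle_apa_threshold <- function(index, response) {
  cand <- sort(unique(index), decreasing = TRUE)
  best <- NA_real_
  for (v in cand) {
    if (all(response[index >= v] > 0)) best <- v else break
  }
  best
}

# piecewise two-segment dataset generator: continuous broken line with
# breakpoint psi, plus gaussian noise
make_piecewise <- function(n, psi, intercept = 5, slope_left = -400,
                           slope_right = 0, x_range = c(0.005, 0.1),
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sort(runif(n, x_range[1], x_range[2]))
  y0 <- intercept + slope_right * (x - psi)
  y0[x <= psi] <- intercept + slope_left * (x[x <= psi] - psi)
  y <- y0 + rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}

# minimal long-format incubation frame for metric tests
make_incubation_rows <- function(treatment, replicate, variable, time_d,
                                 value, station_id = "T1",
                                 season = "summer") {
  data.frame(station_id = station_id, season = season,
             treatment = treatment, replicate = replicate,
             time_d = time_d, variable = variable, value = value,
             censored = FALSE, stringsAsFactors = FALSE)
}
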