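test_that("delta_r matches hand arithmetic and is antisymmetric", {
  expect_equal(delta_r(c(1, 2, 3), c(1, 2, 3), 5), 0)
  # averages 2.0 vs 1.0 over 5 days
  expect_equal(delta_r(2, 1, 5), log10(2) / 5)
  expect_equal(round(delta_r(2, 1, 5), 6), 0.060206)
  expect_equal(delta_r(1, 2, 5), -delta_r(2, 1, 5))
  set.seed(1)
  for (i in 1:10) {
    a <- runif(5, 0.1, 5); b <- runif(5, 0.1, 5); t <- runif(1, 1, 6)
    expect_equal(delta_r(a, b, t), -delta_r(b, a, t))
  }
  expect_error(delta_r(c(1, 0), c(1, 2), 5), "positive")
  expect_error(delta_r(1, 1, 0), "positive number of days")
  expect_error(delta_r(numeric(0), 1, 5), "empty")
})

test_that("nutrient utilization is initial minus final, sign preserved", {
  expect_equal(nutrient_utilization(0.10, 0.05), 0.05)
  expect_equal(nutrient_utilization(0.05, 0.05), 0)
  # net accumulation stays negative
  expect_equal(nutrient_utilization(0.05, 0.07), -0.02)
  expect_error(nutrient_utilization(-0.1, 0.05), "finite")
})

test_that("potential maximum DOP utilization follows the N-implied demand", {
  expect_equal(dop_star(16, 1, 16), 0)
  expect_equal(dop_star(4.8, 0.01, 16), 0.29)
  expect_equal(dop_star(4.8, 0.01, 48), 0.09)
  expect_error(dop_star(1, 1, 0), "positive")
  expect_error(dop_star(1, 1, -16), "positive")
  # exact identity on random inputs: dop_star(a, b, 16) + b = a/16
  set.seed(7)
  a <- runif(100, 0, 10); b <- runif(100, -1, 1)
  expect_equal(dop_star(a, b, 16) + b, a / 16)
})

test_that("excess-nutrient indices satisfy n_star = -ratio * p_star", {
  r <- p_star_n_star(1.6, 0.1)
  expect_equal(r$p_star, 0); expect_equal(r$n_star, 0)
  r <- p_star_n_star(9.83, 0.065)
  expect_equal(round(r$p_star, 3), -0.549)
  expect_equal(round(r$n_star, 2), 8.79)
  r <- p_star_n_star(0, 0.1)
  expect_equal(r$p_star, 0.1); expect_equal(r$n_star, -1.6)
  set.seed(3)
  din <- runif(200, 0, 20); dip <- runif(200, 0, 0.5)
  pn <- p_star_n_star(din, dip)
  expect_equal(pn$n_star, -16 * pn$p_star)
})

test_that("DOP error margin propagates and is scale invariant", {
  expect_equal(dop_error_margin(0, 0, 0.20, 0.06), 0)
  expect_equal(round(dop_error_margin(0.001, 0.001, 0.20, 0.06), 4),
               1.0102)
  expect_error(dop_error_margin(0.01, 0.01, 0.06, 0.06), "exceed")
  set.seed(11)
  for (i in 1:20) {
    s1 <- runif(1, 0, 0.01); s2 <- runif(1, 0, 0.01)
    m1 <- runif(1, 0.1, 0.3); m2 <- runif(1, 0.0, 0.09)
    k <- runif(1, 0.1, 10)
    expect_equal(dop_error_margin(k * s1, k * s2, k * m1, k * m2),
                 dop_error_margin(s1, s2, m1, m2), tolerance = 1e-12)
  }
})

test_that("DOP detection limit is the sum of the assay limits", {
  expect_identical(dop_detection_limit(0.005, 0.02), 0.025)
  expect_identical(dop_detection_limit(0, 0), 0)
  expect_identical(dop_detection_limit(0.01, 0.02), 0.03)
})

test_that("ratio-style metrics compute the stated quantities", {
  expect_equal(relative_apa_change(2, 1), 1.0)
  expect_error(relative_apa_change(2, 0), "positive")
  expect_equal(log_chl_dip(1.0, 0.1), 1.0)
  expect_equal(log_chl_dip(10, 0.1), 2.0)
  expect_error(log_chl_dip(1, 0), "dip")
  expect_equal(delta_np0(127, 127), 0)
  expect_equal(apa_per_chl(10, 2), 5)
  expect_error(apa_per_chl(10, 0), "positive")
})

test_that("difference-derived DOP clamps negatives and flags them", {
  r <- derive_dop(c(0.2, 0.05), c(0.06, 0.06))
  expect_equal(r$dop, c(0.14, 0))
  expect_equal(r$clamped, c(FALSE, TRUE))
})

test_that("series summaries are sparse-aware means and endpoints", {
  d <- rbind(
    make_incubation_rows("control", 1, "chl", 0:5, rep(2, 6)),
    make_incubation_rows("control", 1, "din", 0:5, 6:1),
    make_incubation_rows("control", 1, "apa", c(0, 2, 5), c(1, 2, 3)))
  s <- summarize_series(d)
  expect_equal(s$chl_avg, 2)
  expect_equal(s$din_0, 6); expect_equal(s$din_t, 1)
  # APA present at 3 of 6 time points: mean over the 3 present values
  expect_equal(s$apa_avg, 2)
  expect_equal(s$t_span_d, 5)
  # missing variable is NA, never zero
  expect_true(is.na(s$dip_0))
  # 3-point mean
  d2 <- make_incubation_rows("control", 1, "chl", 0:2, c(1, 2, 3))
  expect_equal(summarize_series(d2)$chl_avg, 2)
  # excluding t = 0 changes the average accordingly
  cfg <- run_config(include_t0 = FALSE)
  expect_equal(summarize_series(d2, cfg)$chl_avg, 2.5)
})

test_that("censoring policies act on flagged values only", {
  d <- make_incubation_rows("control", 1, "dip", 0:3,
                            c(0.10, 0.05, 0.005, 0.005))
  d$censored <- c(FALSE, FALSE, TRUE, TRUE)
  d <- rbind(d, make_incubation_rows("control", 1, "chl", 0:3,
                                     c(1, 1, 1, 1)))
  at <- summarize_series(d, run_config(censoring_policy = "at_limit"))
  half <- summarize_series(d, run_config(censoring_policy = "half_limit"))
  expect_equal(at$dip_t, 0.005)
  expect_equal(half$dip_t, 0.0025)
})

test_that("metric table keeps its exact internal identities", {
  cfg <- sim_config(noise_cv = 0.1, seed = 5)
  sim <- simulate_incubation(cfg, default_treatments())
  m <- metric_table(sim)
  expect_equal(m$dop_star_16, m$delta_din / 16 - m$delta_dip)
  expect_equal(m$n_star, -16 * m$p_star)
  expect_equal(m$dop_star_48, m$delta_din / 48 - m$delta_dip)
  # control rows have delta_r 0 and no treatment-only metrics
  ctrl <- m[m$treatment == "control", ]
  expect_true(all(ctrl$delta_r == 0))
  expect_true(all(is.na(ctrl$rel_apa_change)))
  expect_true(all(is.na(ctrl$delta_np0)))
})

test_that("Redfield-coupled drawdown without hydrolysis closes the budget", {
  # gentle drawdown so DIP stays clear of its detection limit, which
  # would otherwise bias the measured delta-DIP by the censoring floor
  cfg <- sim_config(noise_cv = 0, hydrolysis_rate = 0, dop_exudation = 0,
                    apa_constitutive = 0, mu_max = 0.2, duration_days = 3,
                    initial_state = list(din = 1, dip = 0.1, dop = 0.14,
                                         chl = 1))
  sim <- simulate_incubation(cfg, list(control = treatment_spec("control"),
                                       N = treatment_spec("N", din = 2)))
  m <- metric_table(sim)
  # all P uptake came from DIP at exactly 16:1, so dop_star must vanish
  expect_lt(max(abs(m$dop_star_16)), 1e-9)
})
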