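ctrl_only <- function() list(control = treatment_spec("control"))

test_that("a dead, noise-free bottle stays exactly constant", {
  cfg <- sim_config(mu_max = 0, hydrolysis_rate = 0, noise_cv = 0,
                    apa_sampling = "all")
  sim <- simulate_incubation(cfg, ctrl_only())
  for (v in c("chl", "din", "dip", "dop", "apa")) {
    vals <- sim$value[sim$variable == v]
    expect_equal(vals, rep(vals[1], length(vals)))
  }
})

test_that("APA stays constitutive wherever DIP is above the threshold", {
  cfg <- sim_config(initial_state = list(din = 1, dip = 0.10, dop = 0.14,
                                         chl = 1),
                    noise_cv = 0, apa_sampling = "all")
  sim <- simulate_incubation(cfg, ctrl_only())
  one <- sim[sim$replicate == 1, ]
  dip <- one$value[one$variable == "dip"]
  apa <- one$value[one$variable == "apa"]
  above <- dip > cfg$dip_threshold_psi
  expect_true(all(apa[above] == cfg$apa_constitutive))
})

test_that("noise-free runs conserve total P and N to 1e-6", {
  cfg <- sim_config(noise_cv = 0)
  sim <- simulate_incubation(cfg, default_treatments())
  err <- conservation_error(sim)
  expect_lt(err[["p_rel_error"]], 1e-6)
  expect_lt(err[["n_rel_error"]], 1e-6)
  # independent of the step size
  cfg2 <- sim_config(noise_cv = 0, dt = 0.025)
  err2 <- conservation_error(simulate_incubation(cfg2, ctrl_only()))
  expect_lt(err2[["p_rel_error"]], 1e-6)
})

test_that("trajectories agree with an independent continuous-time oracle", {
  skip_if_not_installed("deSolve")
  cfg <- sim_config(noise_cv = 0, dt = 2.5e-4, apa_sampling = "all")
  treatments <- list(control = treatment_spec("control"),
                     river_high = default_treatments()$river_high)
  sim <- simulate_incubation(cfg, treatments)
  st <- attr(sim, "state")
  rhs <- function(t, y, p) {
    chl <- p$chl_per_p * y[4]
    apa <- p$apa_constitutive + p$apa_inducible_per_chl * chl *
      max(0, 1 - y[2] / p$dip_threshold_psi)
    hyd <- min(p$hydrolysis_rate * apa * 24 / 1000,
               y[3] / 1e-3)  # finite drain cap, inactive unless empty
    mu <- p$mu_max * min(y[1] / (p$k_n + y[1]), y[2] / (p$k_p + y[2]))
    up <- mu * y[4]
    list(c(-p$redfield_np * up, hyd - up, -hyd + p$dop_exudation * up,
           (1 - p$dop_exudation) * up))
  }
  for (tr in names(treatments)) {
    inc <- treatments[[tr]]$increments
    y0 <- c(cfg$initial_state$din + inc[["din"]],
            cfg$initial_state$dip + inc[["dip"]],
            cfg$initial_state$dop,
            cfg$initial_state$chl / cfg$chl_per_p)
    times <- seq(0, cfg$duration_days, by = 0.5)
    ode <- deSolve::lsoda(y0, times, rhs, cfg, rtol = 1e-9, atol = 1e-12)
    s <- st[st$treatment == tr, ]
    ours <- s[match(times, round(s$time_d, 9)),
              c("din", "dip", "dop", "b_p")]
    scale <- pmax(abs(as.matrix(ode[, 2:5])), 0.01)
    rel <- abs(as.matrix(ours) - as.matrix(ode[, 2:5])) / scale
    expect_lt(max(rel), 1e-3)
  }
  # the qualitative contrast: treatment boosts APA and final DIN:DIP
  cfg_apa <- function(s) {
    apa_response(s$dip, cfg$chl_per_p * s$b_p, cfg)
  }
  s_c <- st[st$treatment == "control", ]
  s_t <- st[st$treatment == "river_high", ]
  expect_gt(mean(cfg_apa(s_t)), mean(cfg_apa(s_c)))
  expect_gt(s_t$din[nrow(s_t)] / s_t$dip[nrow(s_t)],
            s_c$din[nrow(s_c)] / s_c$dip[nrow(s_c)])
})

test_that("chlorophyll and APA respond monotonically to the DIN dose", {
  cfg <- sim_config(noise_cv = 0)
  sim <- simulate_incubation(cfg, default_treatments())
  m <- metric_table(sim)
  doses <- c("control", "aerosol_low", "aerosol_mid", "aerosol_high")
  chl <- vapply(doses, function(tr)
    mean(m$chl_avg[m$treatment == tr]), numeric(1))
  apa <- vapply(doses, function(tr)
    mean(m$apa_avg[m$treatment == tr]), numeric(1))
  expect_true(all(diff(chl) >= 0))
  expect_true(all(diff(apa) >= 0))
})

test_that("gross DOP turnover is never below the net DOP change", {
  cfg <- sim_config(noise_cv = 0)
  sim <- simulate_incubation(cfg, default_treatments())
  st <- attr(sim, "state")
  for (tr in unique(st$treatment)) {
    s <- st[st$treatment == tr, ]
    gross <- s$gross_hydrolysis[nrow(s)]
    net <- abs(s$dop[1] - s$dop[nrow(s)])
    expect_gte(gross, net - 1e-12)
  }
  # with exudation active the margin is strict
  s <- st[st$treatment == "river_high", ]
  expect_gt(s$gross_hydrolysis[nrow(s)],
            1.2 * abs(s$dop[1] - s$dop[nrow(s)]))
})

test_that("below-detection readings are censored, nothing negative", {
  cfg <- sim_config(noise_cv = 0.4,
                    initial_state = list(din = 1, dip = 0.008,
                                         dop = 0.03, chl = 1),
                    seed = 11)
  sim <- simulate_incubation(cfg, ctrl_only())
  expect_true(all(sim$value >= 0))
  dl <- c(dip = 0.005, tdp = 0.02, dop = 0.025)
  for (v in names(dl)) {
    sv <- sim[sim$variable == v, ]
    expect_true(all(sv$value >= dl[[v]]))
    expect_true(all(sv$value[sv$censored] == dl[[v]]))
    expect_true(all(sv$value[!sv$censored] > dl[[v]] - 1e-12))
  }
  expect_gt(sum(sim$censored), 0)
  # TDP never reported below DIP
  one <- sim[sim$replicate == 2, ]
  tdp <- one$value[one$variable == "tdp"]
  dip <- one$value[one$variable == "dip"]
  expect_true(all(tdp >= dip - 0.005))
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99)
  s1 <- simulate_incubation(cfg, default_treatments())
  s2 <- simulate_incubation(cfg, default_treatments())
  expect_identical(s1$value, s2$value)
  expect_identical(s1$censored, s2$censored)
  s3 <- simulate_incubation(sim_config(seed = 100), default_treatments())
  expect_false(identical(s1$value, s3$value))
})

test_that("configuration and treatment preconditions are enforced", {
  expect_error(sim_config(dt = 0.5), "dt")
  expect_error(sim_config(mu_max = -1), "mu_max")
  expect_error(sim_config(dip_threshold_psi = 0.004), "detection limit")
  expect_error(sim_config(noise_cv = NA), "noise_cv")
  expect_error(simulate_incubation(sim_config(),
                                   list(N = treatment_spec("N", din = 2))),
               "control")
  bad_ctrl <- list(control = treatment_spec("control", din = 1))
  expect_error(simulate_incubation(sim_config(), bad_ctrl),
               "zero increments")
})

test_that("APA survey reflects the threshold response with noise", {
  cfg <- sim_config(noise_cv = 0)
  sv <- simulate_apa_survey(30, cfg, chl = 1, seed = 2)
  above <- sv$dip > cfg$dip_threshold_psi
  expect_true(all(sv$apa[above] == cfg$apa_constitutive))
  expect_true(all(sv$apa[!above] > cfg$apa_constitutive))
})
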