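#' Configuration for the microcosm incubation simulator
#'
#' Collects the biological and observational parameters of the synthetic
#' bottle model: Monod growth on the limiting nutrient, Redfield-coupled
#' N and P uptake, alkaline phosphatase (AP) induction below a DIP
#' threshold, first-order enzymatic DOP-to-DIP hydrolysis, multiplicative
#' lognormal observation noise, and detection-limit censoring.
#'
#' @param duration_days incubation length, days.
#' @param sampling_interval_h sampling interval, hours (default 24).
#' @param n_replicates bottles per treatment (default 3).
#' @param initial_state named list/vector with `din`, `dip`, `dop` (uM) and
#'   `chl` (ug L-1). Defaults are typical meso-eutrophic coastal surface
#'   water with low DIP (DIN 1.0, DIP 0.06, DOP 0.14 uM, Chl a 1.0).
#' @param mu_max maximum specific growth rate, d-1.
#' @param k_n,k_p Monod half-saturation constants for DIN and DIP, uM.
#' @param redfield_np N:P uptake stoichiometry (default 16).
#' @param apa_constitutive background APA, nM P h-1.
#' @param apa_inducible_per_chl inducible APA per unit chlorophyll,
#'   nM P h-1 per ug L-1.
#' @param dip_threshold_psi DIP threshold for AP induction, uM
#'   (default 0.02).
#' @param hydrolysis_rate fraction of the APA-equivalent P flux actually
#'   transferred DOP -> DIP per day (dimensionless, 0-1ish).
#' @param dop_exudation fraction of P uptake leaked back to the DOP pool
#'   (phytoplankton exudation / sloppy recycling). This is what makes
#'   gross DOP turnover exceed the net DOP change, as observed in
#'   coastal incubations.
#' @param chl_per_p chlorophyll yield, ug Chl a per uM biomass P.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal observation noise (0 = noise-free).
#' @param detection_limits named vector of detection limits, uM:
#'   `dip` 0.005, `tdp` 0.02, `dop` 0.025 by default.
#' @param apa_sampling `"ends"` (beginning, middle, end -- the usual assay
#'   schedule) or `"all"` time points.
#' @param dt Euler integration step, days (<= 0.1).
#' @param seed master seed; per-bottle substreams are derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration_days = 5,
                       sampling_interval_h = 24,
                       n_replicates = 3,
                       initial_state = list(din = 1.0, dip = 0.05,
                                            dop = 0.14, chl = 1.0),
                       mu_max = 0.6,
                       k_n = 0.5,
                       k_p = 0.02,
                       redfield_np = 16,
                       apa_constitutive = 1,
                       apa_inducible_per_chl = 20,
                       dip_threshold_psi = 0.02,
                       hydrolysis_rate = 0.3,
                       dop_exudation = 0.3,
                       chl_per_p = 25,
                       noise_cv = 0.1,
                       detection_limits = c(dip = 0.005, tdp = 0.02,
                                            dop = 0.025),
                       apa_sampling = c("ends", "all"),
                       dt = 0.1,
                       seed = 1L) {
  apa_sampling <- match.arg(apa_sampling)
  init <- as.list(initial_state)
  needed <- c("din", "dip", "dop", "chl")
  if (!all(needed %in% names(init)))
    stop("initial_state must name din, dip, dop, chl")
  num_ok <- function(x, nm, strict_pos = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < 0 || (strict_pos && x <= 0))
      stop("sim_config: invalid value for ", nm)
  }
  num_ok(duration_days, "duration_days", TRUE)
  num_ok(sampling_interval_h, "sampling_interval_h", TRUE)
  num_ok(mu_max, "mu_max"); num_ok(k_n, "k_n", TRUE)
  num_ok(k_p, "k_p", TRUE); num_ok(redfield_np, "redfield_np", TRUE)
  num_ok(apa_constitutive, "apa_constitutive")
  num_ok(apa_inducible_per_chl, "apa_inducible_per_chl")
  num_ok(dip_threshold_psi, "dip_threshold_psi", TRUE)
  num_ok(hydrolysis_rate, "hydrolysis_rate")
  num_ok(dop_exudation, "dop_exudation")
  if (dop_exudation >= 1) stop("sim_config: dop_exudation must be < 1")
  num_ok(chl_per_p, "chl_per_p", TRUE)
  num_ok(noise_cv, "noise_cv")
  num_ok(dt, "dt", TRUE)
  for (nm in needed) num_ok(init[[nm]], paste0("initial_state$", nm))
  if (dt > 0.1) stop("sim_config: Euler step dt must be <= 0.1 d")
  if (n_replicates < 1) stop("sim_config: n_replicates must be >= 1")
  if (!all(c("dip", "tdp", "dop") %in% names(detection_limits)))
    stop("detection_limits must name dip, tdp, dop")
  if (dip_threshold_psi <= detection_limits[["dip"]])
    stop("dip_threshold_psi must exceed the DIP detection limit")
  structure(list(
    duration_days = duration_days,
    sampling_interval_h = sampling_interval_h,
    n_replicates = as.integer(n_replicates),
    initial_state = init,
    mu_max = mu_max, k_n = k_n, k_p = k_p,
    redfield_np = redfield_np,
    apa_constitutive = apa_constitutive,
    apa_inducible_per_chl = apa_inducible_per_chl,
    dip_threshold_psi = dip_threshold_psi,
    hydrolysis_rate = hydrolysis_rate,
    dop_exudation = dop_exudation,
    chl_per_p = chl_per_p,
    noise_cv = noise_cv,
    detection_limits = detection_limits,
    apa_sampling = apa_sampling,
    dt = dt,
    seed = as.integer(seed)), class = "sim_config")
}

#' Treatment specification for a bioassay
#'
#' Either direct nutrient increments (uM, applied as a single spike at
#' t = 0) or an endmember source dosed to a target DIN increment.
#'
#' @param label treatment label; the standard design uses `control`, `N`,
#'   `P`, `NP`, `Fe`, `NFe`, `aerosol_low/mid/high`, `river_low/high`.
#' @param din,dip,si direct increments, uM (ignored when `source` given).
#' @param source optional `endmember` dosed via
#'   [dose_from_composition()].
#' @param target_din_increment target DIN increase for `source` dosing,
#'   uM.
#' @param system_volume,seawater_salinity passed to
#'   [dose_from_composition()].
#' @return an object of class `treatment_spec` with resolved `increments`
#'   and `salinity_change`.
#' @export
treatment_spec <- function(label, din = 0, dip = 0, si = 0,
                           source = NULL, target_din_increment = NULL,
                           system_volume = 20, seawater_salinity = 33) {
  if (!is.null(source)) {
    if (is.null(target_din_increment))
      stop("treatment_spec: target_din_increment required with a source")
    dose <- dose_from_composition(target_din_increment, source,
                                  system_volume, seawater_salinity)
    inc <- dose$increments
    sal <- dose$salinity_change
  } else {
    inc <- c(din = din, dip = dip, si = si)
    sal <- 0
    target_din_increment <- din
  }
  structure(list(label = label,
                 target_din_increment = target_din_increment,
                 increments = inc,
                 salinity_change = sal,
                 source_name = if (is.null(source)) NA_character_
                               else source$name),
            class = "treatment_spec")
}

#' The standard treatment set of the bioassay design
#'
#' Control; single and joint inorganic spikes (N: +2 uM nitrate, P:
#' +0.2 uM phosphate, NP: both; Fe and NFe as no-nutrient-effect
#' controls); aerosol extract at DIN targets 0.5/1/2 uM; riverine water at
#' DIN targets 0.5 and 2 uM.
#'
#' @param compositions endmember list as from [default_compositions()].
#' @param aerosol which aerosol preset to dose (default `aerosol_1`).
#' @return named list of `treatment_spec`.
#' @export
default_treatments <- function(compositions = default_compositions(),
                               aerosol = "aerosol_1") {
  aer <- compositions[[aerosol]]
  riv <- compositions$river
  list(
    control = treatment_spec("control"),
    N  = treatment_spec("N",  din = 2),
    P  = treatment_spec("P",  dip = 0.2),
    NP = treatment_spec("NP", din = 2, dip = 0.2),
    Fe  = treatment_spec("Fe"),
    NFe = treatment_spec("NFe", din = 2),
    aerosol_low  = treatment_spec("aerosol_low",  source = aer,
                                  target_din_increment = 0.5),
    aerosol_mid  = treatment_spec("aerosol_mid",  source = aer,
                                  target_din_increment = 1),
    aerosol_high = treatment_spec("aerosol_high", source = aer,
                                  target_din_increment = 2),
    river_low  = treatment_spec("river_low",  source = riv,
                                target_din_increment = 0.5),
    river_high = treatment_spec("river_high", source = riv,
                                target_din_increment = 2)
  )
}

#' Alkaline phosphatase activity response function
#'
#' APA(t) = constitutive + inducible_per_chl * chl * max(0, 1 - DIP/psi):
#' constant background plus a biomass-scaled inducible part that switches
#' on linearly as DIP falls below the threshold psi.
#'
#' @param dip DIP, uM.
#' @param chl chlorophyll a, ug L-1.
#' @param config a `sim_config`.
#' @return APA, nM P h-1.
#' @export
apa_response <- function(dip, chl, config) {
  config$apa_constitutive +
    config$apa_inducible_per_chl * chl *
      pmax(0, 1 - dip / config$dip_threshold_psi)
}

# nM P h-1 -> uM P d-1
.apa_to_um_per_day <- 24 / 1000

# deterministic core: Euler integration of one bottle, no noise
.integrate_bottle <- function(config, increments) {
  dt <- config$dt
  n_steps <- ceiling(config$duration_days / dt - 1e-9)
  times <- numeric(n_steps + 1L)
  din <- config$initial_state$din + increments[["din"]]
  dip <- config$initial_state$dip + increments[["dip"]]
  dop <- config$initial_state$dop
  b_p <- config$initial_state$chl / config$chl_per_p
  b_n <- config$redfield_np * b_p
  rnp <- config$redfield_np
  exu <- config$dop_exudation
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 7L,
                dimnames = list(NULL, c("time_d", "din", "dip", "dop",
                                        "b_p", "b_n",
                                        "gross_hydrolysis")))
  gross <- 0
  out[1L, ] <- c(0, din, dip, dop, b_p, b_n, gross)
  t_cur <- 0
  for (i in seq_len(n_steps)) {
    h <- min(dt, config$duration_days - t_cur)
    chl <- config$chl_per_p * b_p
    apa <- apa_response(dip, chl, config)
    transfer <- min(config$hydrolysis_rate * apa * .apa_to_um_per_day * h,
                    dop)
    dip_pool <- dip + transfer
    mu <- config$mu_max * min(din / (config$k_n + din),
                              dip_pool / (config$k_p + dip_pool))
    uptake <- min(mu * b_p * h, dip_pool, din / rnp)
    exuded <- exu * uptake  # P leaked back to the DOP pool
    din <- din - rnp * uptake
    dip <- dip_pool - uptake
    dop <- dop - transfer + exuded
    b_p <- b_p + uptake - exuded
    b_n <- b_n + rnp * uptake
    gross <- gross + transfer
    if (!all(is.finite(c(din, dip, dop, b_p))))
      stop("simulate_incubation: non-finite state at t = ", t_cur + h,
           " d; reduce dt (current dt = ", dt, ")")
    t_cur <- t_cur + h
    out[i + 1L, ] <- c(t_cur, din, dip, dop, b_p, b_n, gross)
  }
  out
}

.sample_rows <- function(state, sample_times) {
  idx <- vapply(sample_times,
                function(t) which.min(abs(state[, "time_d"] - t)),
                integer(1))
  state[idx, , drop = FALSE]
}

# one observation: lognormal noise, then detection-limit censoring
.observe <- function(true, cv, dl) {
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    obs <- true * exp(stats::rnorm(length(true), -sdlog^2 / 2, sdlog))
  } else obs <- true
  censored <- obs < dl
  obs[censored] <- dl
  list(value = obs, censored = censored)
}

#' Simulate a set of microcosm incubations
#'
#' Runs the deterministic bottle model (Monod growth limited by the
#' scarcer of DIN and DIP at the chosen stoichiometry; AP induction below
#' the DIP threshold; first-order DOP hydrolysis replenishing DIP) for
#' every treatment and replicate, then applies per-bottle observation
#' noise and detection-limit censoring. The noise-free model conserves
#' total phosphorus (DIP + DOP + biomass P) and total nitrogen
#' (DIN + biomass N) exactly, and because part of the P uptake is
#' exuded back to the DOP pool, gross DOP turnover can greatly exceed
#' the net DOP change -- the signature the derived metrics are designed
#' to detect.
#'
#' @param config a [sim_config()].
#' @param treatments named list of [treatment_spec()]; must include a
#'   `control`.
#' @param station_id,season labels attached to the output.
#' @return a long-format data frame of class `incubation_data` with
#'   columns `station_id, season, treatment, replicate, time_d, variable,
#'   value, censored`; variables are `chl, din, dip, tdp, dop, apa`.
#'   The noise-free state trajectories (including biomass P and cumulative
#'   gross hydrolysis) are attached as `attr(, "state")`.
#' @export
simulate_incubation <- function(config, treatments,
                                station_id = "S1", season = "summer") {
  stopifnot(inherits(config, "sim_config"))
  if (!"control" %in% names(treatments))
    stop("simulate_incubation: treatments must include a control")
  if (any(treatments$control$increments != 0))
    stop("simulate_incubation: control must have zero increments")

  interval_d <- config$sampling_interval_h / 24
  sample_times <- seq(0, config$duration_days, by = interval_d)
  if (sample_times[length(sample_times)] < config$duration_days - 1e-9)
    sample_times <- c(sample_times, config$duration_days)
  n_t <- length(sample_times)
  apa_idx <- if (config$apa_sampling == "all") seq_len(n_t) else
    unique(c(1L, ceiling(n_t / 2), n_t))

  set.seed(config$seed)
  n_bottles <- length(treatments) * config$n_replicates
  bottle_seeds <- sample.int(.Machine$integer.max, n_bottles)

  dl <- config$detection_limits
  rows <- list()
  states <- list()
  b <- 0L
  for (tr_name in names(treatments)) {
    tr <- treatments[[tr_name]]
    state <- .integrate_bottle(config, tr$increments)
    samp <- .sample_rows(state, sample_times)
    chl_true <- config$chl_per_p * samp[, "b_p"]
    apa_true <- apa_response(samp[, "dip"], chl_true, config)
    for (rep_i in seq_len(config$n_replicates)) {
      b <- b + 1L
      set.seed(bottle_seeds[b])
      cv <- config$noise_cv
      o_chl <- .observe(chl_true, cv, 0)
      o_din <- .observe(samp[, "din"], cv, 0.02)
      o_dip <- .observe(samp[, "dip"], cv, dl[["dip"]])
      o_dop <- .observe(samp[, "dop"], cv, dl[["dop"]])
      # TDP is DIP + DOP by construction so tdp >= dip always holds
      tdp_val <- o_dip$value + o_dop$value
      tdp_cen <- tdp_val < dl[["tdp"]]
      tdp_val[tdp_cen] <- dl[["tdp"]]
      o_apa <- .observe(apa_true[apa_idx], cv, 0)
      add <- function(variable, times, value, censored) {
        data.frame(station_id = station_id, season = season,
                   treatment = tr$label, replicate = rep_i,
                   time_d = times, variable = variable,
                   value = value, censored = censored,
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- rbind(
        add("chl", sample_times, o_chl$value, o_chl$censored),
        add("din", sample_times, o_din$value, o_din$censored),
        add("dip", sample_times, o_dip$value, o_dip$censored),
        add("tdp", sample_times, tdp_val, tdp_cen),
        add("dop", sample_times, o_dop$value, o_dop$censored),
        add("apa", sample_times[apa_idx], o_apa$value, o_apa$censored))
    }
    states[[tr_name]] <- data.frame(treatment = tr$label,
                                    state, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "state") <- do.call(rbind, c(states, make.row.names = FALSE))
  attr(out, "config") <- config
  class(out) <- c("incubation_data", "data.frame")
  out
}

#' Phosphorus and nitrogen conservation error of a simulated run
#'
#' On the attached noise-free state trajectories, computes the maximum
#' relative drift of total P (DIP + DOP + biomass P) and total N
#' (DIN + biomass N) over the run. Both should be at floating-point
#' level for any step size, since the discrete scheme moves mass between
#' pools without loss.
#'
#' @param sim output of [simulate_incubation()].
#' @return named numeric: `p_rel_error`, `n_rel_error`.
#' @export
conservation_error <- function(sim) {
  st <- attr(sim, "state")
  cfg <- attr(sim, "config")
  if (is.null(st) || is.null(cfg))
    stop("conservation_error: no state trajectories attached")
  p_err <- n_err <- 0
  for (tr in unique(st$treatment)) {
    s <- st[st$treatment == tr, ]
    tot_p <- s$dip + s$dop + s$b_p
    tot_n <- s$din + s$b_n
    p_err <- max(p_err, max(abs(tot_p - tot_p[1])) / tot_p[1])
    n_err <- max(n_err, max(abs(tot_n - tot_n[1])) / tot_n[1])
  }
  c(p_rel_error = p_err, n_rel_error = n_err)
}

#' Simulate an APA-versus-DIP survey for threshold estimation
#'
#' Draws `n` observations of alkaline phosphatase activity at DIP
#' concentrations spread over `dip_range`, from the simulator's APA
#' response at fixed chlorophyll, with multiplicative lognormal noise.
#' This is the field-survey analogue used to test DIP-threshold recovery
#' by segmented regression: the true breakpoint is
#' `config$dip_threshold_psi`.
#'
#' @param n number of observations.
#' @param config a [sim_config()]; `noise_cv` sets the noise level.
#' @param dip_range range of DIP values, uM.
#' @param chl chlorophyll level held fixed, ug L-1.
#' @param seed RNG seed.
#' @return data frame with columns `dip`, `apa`.
#' @export
simulate_apa_survey <- function(n, config = sim_config(),
                                dip_range = c(0.005, 0.1),
                                chl = 1, seed = 1L) {
  stopifnot(n >= 6, dip_range[1] < dip_range[2])
  set.seed(seed)
  dip <- seq(dip_range[1], dip_range[2], length.out = n)
  true <- apa_response(dip, chl, config)
  obs <- .observe(true, config$noise_cv, 0)
  data.frame(dip = dip, apa = obs$value)
}
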