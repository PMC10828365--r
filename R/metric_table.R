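.apply_censoring <- function(value, censored, policy) {
  if (policy == "half_limit") value[censored] <- value[censored] / 2
  if (policy == "drop") {
    value <- value[!censored]
  }
  value
}

#' Per-bottle summaries of an incubation series
#'
#' For every (station, season, treatment, replicate) bottle: the
#' arithmetic time averages of chlorophyll and APA over the sampled
#' points (t = 0 included by default), the initial and final nutrient
#' concentrations, and the elapsed incubation span. Censored values are
#' handled per the configured policy; a variable with no observations
#' yields `NA` (an explicit missing marker), never zero.
#'
#' @param data an `incubation_data` long data frame.
#' @param config a [run_config()] (censoring policy, t = 0 handling).
#' @return data frame with one row per bottle: `chl_avg`, `apa_avg`,
#'   `t_span_d`, and `<var>_0` / `<var>_t` for din, dip, dop, plus
#'   `chl_0`, `dop_clamped` (any TDP < DIP clamping applied upstream).
#' @export
summarize_series <- function(data, config = run_config()) {
  stopifnot(is.data.frame(data))
  keys <- unique(data[c("station_id", "season", "treatment", "replicate")])
  rownames(keys) <- NULL
  pol <- config$censoring_policy
  one <- function(k) {
    d <- data[data$station_id == k$station_id & data$season == k$season &
              data$treatment == k$treatment &
              data$replicate == k$replicate, ]
    get_var <- function(v) {
      dv <- d[d$variable == v, ]
      dv <- dv[order(dv$time_d), ]
      dv
    }
    avg_of <- function(v) {
      dv <- get_var(v)
      if (nrow(dv) == 0L) return(NA_real_)
      if (!config$include_t0) dv <- dv[dv$time_d > 0, ]
      vals <- .apply_censoring(dv$value, dv$censored, pol)
      if (length(vals) == 0L) NA_real_ else mean(vals)
    }
    ends_of <- function(v) {
      dv <- get_var(v)
      if (nrow(dv) == 0L) return(c(NA_real_, NA_real_))
      vals <- .apply_censoring(dv$value, dv$censored,
                               if (pol == "drop") "at_limit" else pol)
      c(vals[1], vals[length(vals)])
    }
    chl <- get_var("chl")
    t_span <- if (nrow(chl) > 1) diff(range(chl$time_d)) else NA_real_
    din <- ends_of("din"); dip <- ends_of("dip"); dop <- ends_of("dop")
    data.frame(k, chl_avg = avg_of("chl"), apa_avg = avg_of("apa"),
               t_span_d = t_span,
               chl_0 = ends_of("chl")[1],
               din_0 = din[1], din_t = din[2],
               dip_0 = dip[1], dip_t = dip[2],
               dop_0 = dop[1], dop_t = dop[2],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(keys)),
                               function(i) one(keys[i, ])))
  rownames(out) <- NULL
  out
}

#' Derived-metric table for a set of incubations
#'
#' Computes, per bottle, every formula-level statistic of the analysis:
#' the bioassay response Delta-R against the matched control, nutrient
#' utilizations (Delta-DIN/DIP/DOP), potential maximum DOP utilization
#' Delta-DOP* at each configured stoichiometry (16/48/80 by default),
#' excess-nutrient indices P* and N* at the start of the incubation,
#' time-averaged chlorophyll and APA, chlorophyll-normalized APA, the
#' relative APA change and initial DIN:DIP shift against the control
#' (treatment rows only), and the initial Log10(Chl a / DIP).
#'
#' Delta-R for a treatment replicate uses the replicate's own chlorophyll
#' time average against the pooled control average (replicates averaged
#' after the log ratio); set `average_first = TRUE` for the other order.
#' The duration t is the elapsed time between the first and last sampled
#' chlorophyll point.
#'
#' @param data an `incubation_data` long data frame for one or more
#'   stations.
#' @param config a [run_config()].
#' @param control label of the control treatment.
#' @param average_first average replicate chlorophyll before the log
#'   ratio (one Delta-R per treatment, recycled to its replicates).
#' @return data frame keyed by (station_id, season, treatment,
#'   replicate).
#' @export
metric_table <- function(data, config = run_config(),
                         control = "control", average_first = FALSE) {
  summ <- summarize_series(data, config)
  if (!control %in% summ$treatment)
    stop("metric_table: no '", control, "' treatment in the data")
  r0 <- config$redfield_np
  out <- list()
  for (st in unique(summ$station_id)) for (se in
       unique(summ$season[summ$station_id == st])) {
    s <- summ[summ$station_id == st & summ$season == se, ]
    ctrl <- s[s$treatment == control, ]
    ctrl_chl_avg <- mean(ctrl$chl_avg)
    ctrl_apa_avg <- mean(ctrl$apa_avg)
    ctrl_np0 <- mean(ctrl$din_0) / mean(ctrl$dip_0)
    for (tr in unique(s$treatment)) {
      g <- s[s$treatment == tr, ]
      is_ctrl <- tr == control
      t_span <- mean(g$t_span_d)
      dr <- if (is_ctrl) rep(0, nrow(g)) else if (average_first) {
        rep(delta_r(mean(g$chl_avg), ctrl_chl_avg, t_span), nrow(g))
      } else {
        vapply(g$chl_avg, function(a) delta_r(a, ctrl_chl_avg, t_span),
               numeric(1))
      }
      d_din <- nutrient_utilization(g$din_0, g$din_t)
      d_dip <- nutrient_utilization(g$dip_0, g$dip_t)
      d_dop <- nutrient_utilization(g$dop_0, g$dop_t)
      stars <- sapply(config$dop_ratio_variants,
                      function(r) dop_star(d_din, d_dip, r))
      stars <- matrix(stars, nrow = nrow(g))
      colnames(stars) <- paste0("dop_star_", config$dop_ratio_variants)
      pn <- p_star_n_star(g$din_0, g$dip_0, r0)
      rel_apa <- if (is_ctrl || !is.finite(ctrl_apa_avg) ||
                     ctrl_apa_avg <= 0) rep(NA_real_, nrow(g)) else
        relative_apa_change(g$apa_avg, ctrl_apa_avg)
      dnp0 <- if (is_ctrl) rep(NA_real_, nrow(g)) else
        delta_np0(g$din_0 / g$dip_0, ctrl_np0)
      out[[length(out) + 1L]] <- data.frame(
        g[c("station_id", "season", "treatment", "replicate")],
        delta_r = dr,
        delta_din = d_din, delta_dip = d_dip, delta_dop = d_dop,
        stars,
        p_star = pn$p_star, n_star = pn$n_star,
        chl_avg = g$chl_avg, apa_avg = g$apa_avg,
        apa_per_chl = g$apa_avg / g$chl_avg,
        rel_apa_change = rel_apa,
        delta_np0 = dnp0,
        log_chl_dip0 = log10(g$chl_0 / g$dip_0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "censoring_policy") <- config$censoring_policy
  out
}

#' Write a metric table as CSV with unit annotations
#'
#' @param metrics output of [metric_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# doputil %s metric table",
            as.character(utils::packageVersion("doputil"))),
    sprintf("# censoring_policy: %s",
            attr(metrics, "censoring_policy") %||% "at_limit"),
    "# units: delta_r 1/d; delta_* dop_star_* p_star n_star uM;",
    "#   chl_avg ug/L; apa_avg nM P/h; apa_per_chl nM P/h per ug/L;",
    "#   rel_apa_change delta_np0 log_chl_dip0 dimensionless"), con)
  utils::write.table(metrics, con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
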