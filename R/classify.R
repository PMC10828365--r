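#' Nutrient-limitation call from bioassay contrasts
#'
#' Encodes the decision table used to colour bioassay panels: a station
#' is called N-limited when the +N addition (alone, or together with the
#' joint +NP addition) produced a significant positive chlorophyll
#' response, P-limited symmetrically, N+P colimited when either only the
#' joint addition responded or both single additions responded, and
#' unlimited when nothing responded. Significant negative responses are
#' not evidence of limitation and count as non-significant here.
#'
#' @param contrasts data frame with one row per treatment contrast
#'   against the control, columns `treatment` (must cover `"N"`, `"P"`,
#'   `"NP"`), `p_value`, and `effect` (signed response, e.g. the mean
#'   Delta-R or Tukey mean difference).
#' @param alpha significance level (default 0.05).
#' @return list with `call` (one of `"N"`, `"P"`, `"NP"`, `"none"`) and
#'   the significance pattern used.
#' @export
classify_limitation <- function(contrasts, alpha = 0.05) {
  need <- c("N", "P", "NP")
  if (!all(need %in% contrasts$treatment))
    stop("classify_limitation: contrasts must include treatments ",
         paste(setdiff(need, contrasts$treatment), collapse = ", "))
  sig_pos <- function(tr) {
    row <- contrasts[contrasts$treatment == tr, ][1, ]
    isTRUE(row$p_value < alpha) && isTRUE(row$effect > 0)
  }
  n_sig <- sig_pos("N"); p_sig <- sig_pos("P"); np_sig <- sig_pos("NP")
  call <- if (n_sig && p_sig) "NP"
  else if (n_sig) "N"
  else if (p_sig) "P"
  else if (np_sig) "NP"
  else "none"
  list(call = call,
       pattern = c(N = n_sig, P = p_sig, NP = np_sig),
       alpha = alpha)
}

#' Build limitation contrasts from a metric table via ANOVA + Tukey
#'
#' Convenience bridge: one-way ANOVA across the control and the three
#' inorganic-addition treatments on a response column (Delta-R by
#' default), with the Tukey contrasts against the control feeding
#' [classify_limitation()].
#'
#' @param metrics a [metric_table()] for one station/season.
#' @param response column to test (default `"delta_r"`; raw `"chl_avg"`
#'   also supported).
#' @param alpha significance level.
#' @param control control treatment label.
#' @return the [classify_limitation()] result, with the `anova_result`
#'   attached as `$anova`.
#' @export
limitation_from_metrics <- function(metrics, response = "delta_r",
                                    alpha = 0.05, control = "control") {
  need <- c(control, "N", "P", "NP")
  miss <- setdiff(need, metrics$treatment)
  if (length(miss))
    stop("limitation_from_metrics: missing treatments: ",
         paste(miss, collapse = ", "))
  groups <- lapply(need, function(tr)
    metrics[metrics$treatment == tr, response])
  names(groups) <- need
  an <- one_way_anova(groups, alpha = alpha)
  tk <- an$tukey
  ctr <- grepl(paste0("(^", control, "-)|(-", control, "$)"), tk$pair)
  rows <- tk[ctr, ]
  other <- sub(paste0("^", control, "-"), "",
               sub(paste0("-", control, "$"), "", rows$pair))
  # orient the effect as treatment minus control
  sign_flip <- ifelse(startsWith(rows$pair, paste0(control, "-")), -1, 1)
  contrasts <- data.frame(treatment = other,
                          p_value = rows$p_adj,
                          effect = rows$diff * sign_flip)
  out <- classify_limitation(contrasts, alpha)
  out$anova <- an
  out
}

#' Phosphorus-source pattern of an incubation pair
#'
#' From the control and treatment DIP and DOP utilizations, computes the
#' fraction of total P uptake drawn from DOP
#' (`dop_fraction = dDOP+ / (dDIP+ + dDOP+)`, negative utilizations
#' contributing zero) and classifies:
#' pattern I (`I_DIP_main`): DIP is the main P source in both control and
#' treatment (fraction <= 0.5 in both); pattern III (`III_DOP_main`):
#' DOP dominates in both; pattern II (`II_switch`): the treatment flips
#' the community from DIP to DOP as the main source.
#'
#' @param control_delta_dip,control_delta_dop control utilizations, uM.
#' @param treat_delta_dip,treat_delta_dop treatment utilizations, uM.
#' @return list with `pattern`, `dop_fraction` (treatment),
#'   `dop_fraction_control`, `clamped` (any negative utilization
#'   contributed as zero), or pattern `NA` with `undefined = TRUE` when
#'   total utilization is zero in either group.
#' @export
classify_p_source <- function(control_delta_dip, control_delta_dop,
                              treat_delta_dip, treat_delta_dop) {
  vals <- c(control_delta_dip, control_delta_dop,
            treat_delta_dip, treat_delta_dop)
  if (any(!is.finite(vals)))
    stop("classify_p_source: utilizations must be finite")
  frac <- function(ddip, ddop) {
    pos_dip <- max(ddip, 0); pos_dop <- max(ddop, 0)
    tot <- pos_dip + pos_dop
    if (tot == 0) return(NA_real_)
    pos_dop / tot
  }
  f_c <- frac(control_delta_dip, control_delta_dop)
  f_t <- frac(treat_delta_dip, treat_delta_dop)
  clamped <- any(vals < 0)
  if (is.na(f_c) || is.na(f_t)) {
    return(list(pattern = NA_character_, dop_fraction = f_t,
                dop_fraction_control = f_c, clamped = clamped,
                undefined = TRUE))
  }
  pattern <- if (f_c <= 0.5 && f_t <= 0.5) "I_DIP_main"
  else if (f_c > 0.5 && f_t > 0.5) "III_DOP_main"
  else if (f_c <= 0.5 && f_t > 0.5) "II_switch"
  else "I_DIP_main"  # reverse switch (DOP -> DIP): grouped with I
  list(pattern = pattern, dop_fraction = f_t,
       dop_fraction_control = f_c, clamped = clamped,
       undefined = FALSE)
}

#' Empirical always-positive APA-response threshold
#'
#' Scans the observed (Log10(Chl a / DIP), relative APA change) pairs
#' for the smallest index value v such that every observation with index
#' >= v responded positively. This is the empirical construction behind
#' the 1.20 index threshold: above it, additions always increased APA.
#'
#' @param index numeric vector of Log10(Chl a / DIP) values.
#' @param response numeric vector of relative APA changes.
#' @param min_points minimum number of points required (default 5).
#' @return list with `threshold` (NA with `defined = FALSE` when even
#'   the maximum-index point is non-positive) and `n_above`.
#' @export
apa_response_threshold <- function(index, response, min_points = 5) {
  if (length(index) == 0L) stop("apa_response_threshold: empty input")
  if (length(index) != length(response))
    stop("apa_response_threshold: index and response lengths differ")
  ok <- is.finite(index) & is.finite(response)
  index <- index[ok]; response <- response[ok]
  if (length(index) < min_points)
    stop("apa_response_threshold: need at least ", min_points, " points")
  # candidate thresholds are the observed index values, scanned from the
  # top; ties are grouped so the all-positive condition is exact
  uv <- sort(unique(index), decreasing = TRUE)
  thr <- NA_real_
  for (v in uv) {
    if (all(response[index >= v] > 0)) thr <- v else break
  }
  if (is.na(thr))
    return(list(threshold = NA_real_, defined = FALSE, n_above = 0L))
  list(threshold = thr, defined = TRUE,
       n_above = sum(index >= thr))
}
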