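#' Two-segment linear regression for the DIP threshold of APA
#'
#' Fits the continuous broken-line model
#' \deqn{y = b_0 + b_1 x + b_2 (x - \psi)_+}
#' by iterative linearization: at the current breakpoint estimate psi,
#' regress y on x, U = (x - psi) 1[x > psi] and V = -1[x > psi], then
#' update psi by coef(V)/coef(U) until the step falls below
#' `tol * range(x)` or `max_iter` iterations. Multi-start from the
#' 25/50/75 percentiles of x plus the best inter-datapoint midpoints of
#' the RSS profile (best residual sum of squares wins); if no start
#' converges, the reported optimum comes from an exhaustive grid search.
#' Standard errors for psi use the delta method.
#'
#' In the APA application x is the DIP concentration (uM) and y the
#' alkaline phosphatase activity (nM P h-1): the breakpoint estimates the
#' DIP threshold below which the inducible enzyme switches on, with
#' slope_right ~ 0 (constitutive background) and slope_left < 0.
#'
#' @param x,y numeric vectors; at least 6 distinct x values.
#' @param psi_init optional starting breakpoint(s); defaults to the
#'   25/50/75 percentiles of x.
#' @param max_iter maximum linearization iterations per start.
#' @param tol convergence tolerance as a fraction of range(x).
#' @param log_y fit on log10(y) (requires positive y).
#' @param level confidence level for the psi interval.
#' @return object of class `breakpoint_fit`: `psi`, `psi_se`, `psi_ci`,
#'   `slope_left`, `slope_right`, `intercept`, `converged`,
#'   `n_iterations`, `rss_segmented`, `rss_linear`, `boundary`,
#'   `existence_p` (NA until [breakpoint_exists()] is consulted).
#' @export
fit_segmented <- function(x, y, psi_init = NULL, max_iter = 50,
                          tol = 1e-8, log_y = FALSE, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 6L)
    stop("fit_segmented: need at least 6 distinct x values")
  if (log_y) {
    if (any(y <= 0)) stop("fit_segmented: log_y requires positive y")
    y <- log10(y)
  }
  n <- length(x)
  rng <- range(x)
  span <- diff(rng)
  lin <- stats::lm.fit(cbind(1, x), y)
  rss_linear <- sum(lin$residuals^2)

  if (stats::var(y) == 0) {
    return(structure(list(psi = NA_real_, psi_se = NA_real_,
                          psi_ci = c(NA_real_, NA_real_),
                          slope_left = 0, slope_right = 0,
                          intercept = y[1], converged = FALSE,
                          n_iterations = 0L, boundary = FALSE,
                          rss_segmented = 0, rss_linear = rss_linear,
                          existence_p = NA_real_, n = n),
                     class = "breakpoint_fit"))
  }

  starts <- if (is.null(psi_init))
    unname(stats::quantile(x, c(0.25, 0.5, 0.75))) else psi_init
  if (is.null(psi_init)) {
    # RSS(psi) is piecewise smooth with breaks at the data x values, so
    # every local minimum lies between two consecutive distinct x; the
    # best inter-datapoint midpoints seed the iteration in the global
    # basin even when the quantile starts miss it
    xs <- sort(unique(x))
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    mids <- mids[mids > xs[2] & mids < xs[length(xs) - 1L]]
    if (length(mids)) {
      mid_rss <- vapply(mids, function(p) .segmented_rss(x, y, p),
                        numeric(1))
      starts <- c(starts, mids[order(mid_rss)][seq_len(min(3,
                                                   length(mids)))])
    }
  }
  starts <- starts[starts > rng[1] & starts < rng[2]]
  if (!length(starts)) starts <- mean(rng)

  run_from <- function(psi) {
    it <- 0L
    repeat {
      it <- it + 1L
      above <- x > psi
      if (sum(above) < 2L || sum(!above) < 2L)
        return(list(ok = FALSE, boundary = TRUE, it = it))
      X <- cbind(1, x, (x - psi) * above, -as.numeric(above))
      fit <- stats::lm.fit(X, y)
      beta_u <- fit$coefficients[3]
      gamma_v <- fit$coefficients[4]
      if (!is.finite(beta_u) || abs(beta_u) < 1e-12)
        return(list(ok = FALSE, boundary = FALSE, it = it))
      step <- gamma_v / beta_u
      psi_new <- psi + step
      # keep the iterate inside the observed range
      psi_new <- min(max(psi_new, rng[1] + 1e-12 * span),
                     rng[2] - 1e-12 * span)
      if (abs(psi_new - psi) < tol * span) {
        return(list(ok = TRUE, psi = psi_new, it = it,
                    boundary = FALSE))
      }
      psi <- psi_new
      if (it >= max_iter)
        return(list(ok = FALSE, boundary = FALSE, it = it, psi = psi))
    }
  }

  results <- lapply(starts, run_from)
  conv <- Filter(function(r) isTRUE(r$ok), results)
  converged <- length(conv) > 0L
  if (converged) {
    cand <- vapply(conv, function(r) r$psi, numeric(1))
    rss_of <- vapply(cand, function(p) .segmented_rss(x, y, p),
                     numeric(1))
    best <- which.min(rss_of)
    psi <- cand[best]
    n_it <- conv[[best]]$it
  } else {
    # grid-search fallback: the optimum is still reported
    gs <- psi_grid_search(x, y)
    psi <- gs$psi
    n_it <- max(vapply(results, function(r) r$it, integer(1)))
  }
  boundary <- (psi - rng[1]) < 0.01 * span || (rng[2] - psi) < 0.01 * span

  above <- x > psi
  X_fin <- cbind(1, x, (x - psi) * above, -as.numeric(above))
  fit_fin <- stats::lm.fit(X_fin, y)
  rss_seg <- sum(fit_fin$residuals^2)
  beta_u <- fit_fin$coefficients[3]
  # delta-method SE of psi from the V and U coefficients
  dfree <- n - 4L
  sigma2 <- rss_seg / max(dfree, 1L)
  XtX <- crossprod(X_fin)
  vc <- tryCatch(sigma2 * solve(XtX), error = function(e) NULL)
  psi_se <- NA_real_
  if (!is.null(vc) && is.finite(beta_u) && abs(beta_u) > 1e-12) {
    g <- beta_u; v <- fit_fin$coefficients[4]
    # psi_hat = psi + v/g; var by first-order propagation
    grad <- c(0, 0, -v / g^2, 1 / g)
    psi_se <- sqrt(drop(t(grad) %*% vc %*% grad))
  }
  tq <- stats::qt(1 - (1 - level) / 2, max(dfree, 1L))
  slope_left <- unname(fit_fin$coefficients[2])
  slope_right <- unname(fit_fin$coefficients[2] + beta_u)
  structure(list(psi = unname(psi), psi_se = unname(psi_se),
                 psi_ci = unname(c(psi - tq * psi_se,
                                   psi + tq * psi_se)),
                 slope_left = slope_left, slope_right = slope_right,
                 intercept = unname(fit_fin$coefficients[1]),
                 converged = converged, n_iterations = n_it,
                 boundary = boundary,
                 rss_segmented = rss_seg, rss_linear = rss_linear,
                 existence_p = NA_real_, n = n),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (is.na(x$psi)) {
    cat("<breakpoint_fit> no breakpoint (constant response)\n")
    return(invisible(x))
  }
  cat(sprintf("<breakpoint_fit> psi = %.4g (SE %.3g, %s)\n",
              x$psi, x$psi_se,
              if (x$converged) sprintf("converged in %d it.",
                                       x$n_iterations)
              else "grid-search optimum"))
  cat(sprintf("  slopes: left %.4g, right %.4g; RSS %.4g (linear %.4g)\n",
              x$slope_left, x$slope_right, x$rss_segmented,
              x$rss_linear))
  if (x$boundary) cat("  warning: psi at data boundary (non-identifiable)\n")
  invisible(x)
}

.segmented_rss <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  sum(stats::lm.fit(X, y)$residuals^2)
}

#' Exhaustive grid search for the breakpoint
#'
#' Minimizes the broken-line residual sum of squares over a grid of
#' candidate breakpoints: a coarse scan over the interior of range(x)
#' followed by refinement around the best coarse minima down to
#' `resolution`. Used as the independent optimum check for
#' [fit_segmented()] and as its fallback when the iteration does not
#' converge.
#'
#' @param x,y data.
#' @param resolution final grid step (default 1e-5, in x units).
#' @param coarse_step initial scan step (default range/200).
#' @return list with `psi`, `rss`.
#' @export
psi_grid_search <- function(x, y, resolution = 1e-5,
                            coarse_step = NULL) {
  rng <- range(x)
  span <- diff(rng)
  if (is.null(coarse_step)) coarse_step <- span / 200
  lo <- rng[1] + 0.01 * span; hi <- rng[2] - 0.01 * span
  grid <- seq(lo, hi, by = coarse_step)
  rss <- vapply(grid, function(p) .segmented_rss(x, y, p), numeric(1))
  # refine around every local minimum of the coarse scan
  is_min <- which(rss <= c(Inf, rss[-length(rss)]) &
                  rss <= c(rss[-1], Inf))
  best_psi <- grid[which.min(rss)]
  best_rss <- min(rss)
  for (i in is_min) {
    a <- max(lo, grid[i] - coarse_step)
    b <- min(hi, grid[i] + coarse_step)
    fine <- seq(a, b, by = resolution)
    fr <- vapply(fine, function(p) .segmented_rss(x, y, p), numeric(1))
    if (min(fr) < best_rss) {
      best_rss <- min(fr)
      best_psi <- fine[which.min(fr)]
    }
  }
  list(psi = best_psi, rss = best_rss)
}

#' Bootstrap test for the existence of a breakpoint
#'
#' Compares the observed relative RSS improvement of the segmented over
#' the simple linear fit with its null distribution obtained by residual
#' resampling from the linear fit (no breakpoint). The returned score
#' behaves like a p-value: values below alpha support "a threshold was
#' identified"; the package's convention is that a threshold is NOT
#' identified when the score is >= alpha, the fit did not converge, or
#' the breakpoint sits at the data boundary.
#'
#' @param x,y data (as in [fit_segmented()]).
#' @param n_boot bootstrap replicates (default 999).
#' @param seed RNG seed.
#' @param grid_size breakpoint grid used for the (fast) segmented refits
#'   inside the bootstrap.
#' @return list with `score`, `stat_obs`, `n_boot`.
#' @export
breakpoint_exists <- function(x, y, n_boot = 999, seed = 1L,
                              grid_size = 40) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 6L)
    stop("breakpoint_exists: need at least 6 distinct x values")
  if (stats::var(y) == 0)
    return(list(score = 1, stat_obs = 0, n_boot = n_boot))
  Xlin <- cbind(1, x)
  lin <- stats::lm.fit(Xlin, y)
  rss_lin <- sum(lin$residuals^2)
  grid <- stats::quantile(x, probs = seq(0.05, 0.95,
                                         length.out = grid_size))
  grid <- unique(grid)
  seg_rss_min <- function(yy) {
    min(vapply(grid, function(p) .segmented_rss(x, yy, p), numeric(1)))
  }
  stat <- function(yy, rl) if (rl <= 0) 0 else
    (rl - seg_rss_min(yy)) / rl
  stat_obs <- stat(y, rss_lin)
  set.seed(seed)
  fitted_lin <- lin$fitted.values
  resid_lin <- lin$residuals
  stat_null <- vapply(seq_len(n_boot), function(i) {
    yb <- fitted_lin + sample(resid_lin, replace = TRUE)
    rlb <- sum(stats::lm.fit(Xlin, yb)$residuals^2)
    stat(yb, rlb)
  }, numeric(1))
  score <- (1 + sum(stat_null >= stat_obs)) / (n_boot + 1)
  list(score = score, stat_obs = stat_obs, n_boot = n_boot)
}
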