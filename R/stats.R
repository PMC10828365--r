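#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Classical fixed-effects one-way analysis of variance (via
#' [stats::aov()]) followed by Tukey's honest significant difference on
#' all group pairs (via [stats::TukeyHSD()]) and a compact letter display
#' derived by the insert-and-absorb procedure: groups that share a letter
#' are statistically indistinguishable at `alpha`.
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2
#'   values each).
#' @param alpha significance level for letters and flags (default 0.05).
#' @param tukey run the post hoc test (disable for speed when only the
#'   omnibus F is needed).
#' @return object of class `anova_result`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `group_means`, `tukey` (data frame with
#'   pair, diff, q, p_adj, significant), `letters` (named character).
#' @export
one_way_anova <- function(groups, alpha = 0.05, tukey = TRUE) {
  if (length(groups) < 2L)
    stop("one_way_anova: need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("one_way_anova: every group needs at least two values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(y))) stop("one_way_anova: non-finite values")
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  k <- length(groups); n <- length(y)
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  f_stat <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
  ms_within <- an[2, "Mean Sq"]
  if (an[1, "Sum Sq"] < 1e-12 * max(1, sum(y^2)) && ms_within < 1e-12) {
    f_stat <- 0; p <- 1  # all groups identical: no evidence path
  }
  means <- vapply(groups, mean, numeric(1))
  tk <- NULL; letters <- NULL
  if (tukey) {
    if (is.finite(f_stat)) {
      th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
      pairs <- rownames(th)
      ij <- strsplit(pairs, "-", fixed = TRUE)
      gi <- vapply(ij, `[`, character(1), 1)
      gj <- vapply(ij, `[`, character(1), 2)
      se_q <- sqrt(ms_within / 2 * (1 / sizes[gi] + 1 / sizes[gj]))
      q <- abs(th[, "diff"]) / se_q
      tk <- data.frame(pair = pairs, diff = th[, "diff"], q = q,
                       p_adj = th[, "p adj"],
                       significant = th[, "p adj"] < alpha,
                       row.names = NULL)
    } else {
      # degenerate within-group variance with distinct means: every pair
      # is maximally separated
      cmb <- utils::combn(names(groups), 2)
      tk <- data.frame(pair = paste(cmb[2, ], cmb[1, ], sep = "-"),
                       diff = means[cmb[2, ]] - means[cmb[1, ]],
                       q = Inf, p_adj = 0, significant = TRUE,
                       row.names = NULL)
      tk$significant <- abs(tk$diff) > 0
      tk$p_adj[!tk$significant] <- 1
      tk$q[!tk$significant] <- 0
    }
    letters <- cld_letters(names(groups), tk)
  }
  structure(list(f_stat = f_stat, df_between = k - 1L,
                 df_within = n - k, p_value = p,
                 group_means = means, tukey = tk, letters = letters,
                 alpha = alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %s\n",
              x$df_between, x$df_within, x$f_stat,
              format_pvalue(x$p_value)))
  if (!is.null(x$letters)) {
    cat("Group means (groups sharing a letter indistinguishable at",
        sprintf("alpha = %g):\n", x$alpha))
    for (g in names(x$group_means))
      cat(sprintf("  %-12s %10.4g  %s\n", g, x$group_means[[g]],
                  x$letters[[g]]))
  }
  invisible(x)
}

#' Compact letter display from pairwise significance
#'
#' The insert-and-absorb procedure: start from a single letter column
#' holding all groups; for every significant pair split each column that
#' still contains both; absorb columns that are subsets of others;
#' assign letters. Two groups share a letter if and only if their pair is
#' not significant.
#'
#' @param group_names character vector of groups.
#' @param tukey_pairs data frame with columns `pair`
#'   (\code{"b-a"}-style) and `significant`.
#' @return named character vector of letter strings.
#' @export
cld_letters <- function(group_names, tukey_pairs) {
  cols <- list(group_names)
  sig <- tukey_pairs[tukey_pairs$significant, "pair"]
  for (p in sig) {
    ab <- strsplit(p, "-", fixed = TRUE)[[1]]
    new_cols <- list()
    for (col in cols) {
      if (all(ab %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, ab[1])),
                      list(setdiff(col, ab[2])))
      } else new_cols <- c(new_cols, list(col))
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_cols[[i]] %in% new_cols[[j]]) &&
          !(all(new_cols[[j]] %in% new_cols[[i]]) && i < j))
        keep[i] <- FALSE
    }
    cols <- new_cols[keep]
  }
  lab <- letters[seq_along(cols)]
  out <- vapply(group_names, function(g)
    paste0(lab[vapply(cols, function(col) g %in% col, logical(1))],
           collapse = ""),
    character(1))
  out
}

#' Unpaired two-sample t-test
#'
#' Two-sided by default; the equal-variance Student form is the primary
#' contract (`var_equal = TRUE`), with Welch available. Degenerate
#' zero-variance inputs follow the documented limits: equal means give
#' t = 0, p = 1; unequal means give |t| = Inf, p = 0.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param var_equal pool the variance (Student) or not (Welch).
#' @param two_sided two-sided alternative (default).
#' @return list with `t`, `df`, `p`.
#' @export
t_test_unpaired <- function(x, y, var_equal = TRUE, two_sided = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("t_test_unpaired: each sample needs >= 2 values")
  if (any(!is.finite(c(x, y))))
    stop("t_test_unpaired: non-finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = if (two_sided) "two.sided"
                                    else "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average-ranked data (ties receive
#' average ranks); the two-sided p-value uses the t approximation on
#' n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("spearman: x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("spearman: need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman: correlation undefined for a constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Ordinary least squares with a 95 percent confidence band
#'
#' Simple linear regression via [stats::lm()], reporting the
#' coefficients, their standard errors, r-squared, the two-sided p for
#' the slope, and the pointwise confidence band for the mean response on
#' a grid (t quantile at n - 2 df). The band is symmetric about the
#' fitted line and narrowest at the mean of x.
#'
#' @param x,y numeric vectors, n >= 3, x non-constant.
#' @param band_grid x values at which to evaluate the band (default: 50
#'   points over the range of x).
#' @param level confidence level (default 0.95).
#' @return object of class `regression_fit`.
#' @export
linear_fit <- function(x, y, band_grid = NULL, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("linear_fit: need at least 3 points")
  if (stats::sd(x) == 0)
    stop("linear_fit: x is constant (rank-deficient design)")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  if (is.null(band_grid))
    band_grid <- seq(min(x), max(x), length.out = 50)
  pr <- stats::predict(fit, newdata = data.frame(x = band_grid),
                       interval = "confidence", level = level)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_se = sm$coefficients[2, 2],
    intercept_se = sm$coefficients[1, 2],
    r_squared = sm$r.squared,
    p_slope = sm$coefficients[2, 4],
    n = length(x),
    band = data.frame(x = band_grid, fit = pr[, "fit"],
                      lwr = pr[, "lwr"], upr = pr[, "upr"]),
    lm = fit), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "Linear fit: y = %.4g + %.4g x  (r2 = %.3f, slope p = %s, n = %d)\n",
    x$intercept, x$slope, x$r_squared, format_pvalue(x$p_slope), x$n))
  invisible(x)
}

#' Format a p-value for text reports
#'
#' Values below 1e-15 print as `"<1e-15"`; machine outputs keep the exact
#' number.
#'
#' @param p numeric p-value(s).
#' @return character.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-15, "<1e-15", formatC(p, digits = 3, format = "g"))
}
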