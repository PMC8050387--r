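# condition-level statistics: t tests, one-way ANOVA with control
# comparisons, percentile-bootstrap median CIs, significance stars

check_numeric <- function(x, nm) {
  if (!is.numeric(x) || anyNA(x))
    stop_input("statistics error: ", nm, " must be numeric without NA")
}

#' One-sample t test
#'
#' Two-sided Student t test of the mean against `mu0`:
#' `t = (mean - mu0) / (s / sqrt(n))` with `n - 1` degrees of freedom.
#'
#' @param values numeric vector, `n >= 2`, positive variance.
#' @param mu0 null mean.
#' @return list with `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu0) {
  check_numeric(values, "values")
  if (length(values) < 2L)
    stop_input("statistics error: need n >= 2")
  if (var(values) <= 0)
    stop_input("statistics error: zero variance")
  r <- t.test(values, mu = mu0)
  list(t = unname(r$statistic), df = unname(r$parameter), p = r$p.value)
}

#' Two-sample t test (Welch by default)
#'
#' @param a,b numeric vectors, each `n >= 2`.
#' @param equal_var use the classical pooled-variance t instead of Welch.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(a, b, equal_var = FALSE) {
  check_numeric(a, "a"); check_numeric(b, "b")
  if (length(a) < 2L || length(b) < 2L)
    stop_input("statistics error: each group needs n >= 2")
  if (var(a) + var(b) <= 0)
    stop_input("statistics error: zero variance in both groups")
  r <- t.test(a, b, var.equal = isTRUE(equal_var))
  list(t = unname(r$statistic), df = unname(r$parameter), p = r$p.value)
}

#' One-way ANOVA, optionally with each-vs-control comparisons
#'
#' Classical `F = MS_between / MS_within` via [stats::aov()]. When
#' `control` names one group, each other group is additionally compared to
#' it with a t statistic using the pooled within-group mean square
#' (`df = df_within`), and p values are Bonferroni-corrected across the
#' `k - 1` comparisons; raw p values are also reported.
#'
#' @param groups named list of numeric vectors (`>= 2` groups, each
#'   `n >= 2`).
#' @param control optional name (or index) of the control group.
#' @return list with `F`, `df1`, `df2`, `p`, and (when `control` is given)
#'   a data.frame `vs_control` with columns `group`, `t`, `df`, `p_raw`,
#'   `p_adj`, `stars`, `stars_raw`.
#' @export
one_way_anova <- function(groups, control = NULL) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("statistics error: need >= 2 groups")
  lapply(groups, check_numeric, nm = "group values")
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop_input("statistics error: every group needs n >= 2")
  if (sum(vapply(groups, var, numeric(1)) * (ns - 1)) <= 0)
    stop_input("statistics error: zero within-group variance")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), ns),
                                  levels = names(groups)))
  tab <- summary(aov(value ~ group, data = df))[[1]]
  out <- list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
              p = tab$`Pr(>F)`[1])
  if (!is.null(control)) {
    if (is.numeric(control)) control <- names(groups)[control]
    if (!control %in% names(groups))
      stop_input("statistics error: control group '", control, "' not found")
    msw <- tab$`Mean Sq`[2]
    dfw <- tab$Df[2]
    means <- vapply(groups, mean, numeric(1))
    others <- setdiff(names(groups), control)
    tt <- (means[others] - means[control]) /
      sqrt(msw * (1 / ns[others] + 1 / ns[control]))
    p_raw <- 2 * pt(-abs(tt), dfw)
    p_adj <- pmin(1, p_raw * length(others))
    out$vs_control <- data.frame(group = others, t = unname(tt), df = dfw,
                                 p_raw = unname(p_raw), p_adj = unname(p_adj),
                                 stars = p_to_stars(unname(p_adj)),
                                 stars_raw = p_to_stars(unname(p_raw)),
                                 row.names = NULL)
  }
  out
}

#' Percentile-bootstrap confidence interval for the median
#'
#' Resamples `values` with replacement `n_boot` times and returns the
#' `alpha/2` and `1 - alpha/2` quantiles of the bootstrap medians.
#' Deterministic for a given `seed` (the global RNG state is restored).
#'
#' @param values numeric vector, `n >= 3`.
#' @param n_boot number of bootstrap resamples (`>= 1000`; default 10000).
#' @param alpha two-sided miss probability (default 0.05 for a 95% CI).
#' @param seed RNG seed.
#' @return numeric vector `c(lo, hi)` with `lo <= hi`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000, alpha = 0.05,
                                seed = 1) {
  check_numeric(values, "values")
  n <- length(values)
  if (n < 3L) stop_input("statistics error: need n >= 3 for a bootstrap CI")
  if (n_boot < 1000L) stop_input("statistics error: n_boot must be >= 1000")
  meds <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    apply(matrix(values[idx], n, n_boot), 2, median)
  })
  ci <- unname(quantile(meds, c(alpha / 2, 1 - alpha / 2)))
  c(lo = ci[1], hi = ci[2])
}

#' Map a p value to significance stars
#'
#' `p < 0.0001` gives `"****"`, `< 0.001` `"***"`, `< 0.01` `"**"`,
#' `< 0.05` `"*"`, otherwise `"ns"`. Vectorized.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return character vector.
#' @export
p_to_stars <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_input("input error: p must lie in [0, 1]")
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Compare a per-field metric across conditions
#'
#' For every condition: n, median and percentile-bootstrap 95% CI. With two
#' conditions the groups are compared by a two-sample t test (Welch by
#' default); with more, by one-way ANOVA plus Bonferroni-corrected
#' each-vs-control t comparisons when `control` is given. Fields flagged
#' `excluded` are dropped first.
#'
#' @param metrics data.frame from [metrics_table()] / [read_metrics()].
#' @param metric column to compare (default `neurite_length_per_cell_um`).
#' @param control optional control condition name (reference group).
#' @param equal_var passed to [two_sample_t()].
#' @param n_boot,alpha,seed bootstrap settings, see
#'   [bootstrap_median_ci()].
#' @return data.frame of class `condition_comparison`: one row per
#'   condition with `metric`, `group`, `n`, `median`, `ci_lo`, `ci_hi`,
#'   `test`, `statistic`, `df`, `p`, `p_raw`, `stars`.
#' @export
compare_conditions <- function(metrics, metric = "neurite_length_per_cell_um",
                               control = NULL, equal_var = FALSE,
                               n_boot = 10000, alpha = 0.05, seed = 1) {
  if (!metric %in% names(metrics))
    stop_input("metric '", metric, "' not found in metrics")
  keep <- !(metrics$excluded %in% TRUE)
  m <- metrics[keep & !is.na(metrics[[metric]]), ]
  groups <- split(m[[metric]], m$condition)
  if (length(groups) < 2L)
    stop_input("statistics error: need >= 2 conditions to compare")
  if (!is.null(control) && !control %in% names(groups))
    stop_input("statistics error: control condition '", control,
               "' not present")
  # control first so it is the reference row
  ord <- names(groups)
  if (!is.null(control)) ord <- c(control, setdiff(ord, control))
  groups <- groups[ord]

  res <- data.frame(metric = metric, group = ord,
                    n = lengths(groups),
                    median = vapply(groups, median, numeric(1)),
                    ci_lo = NA_real_, ci_hi = NA_real_,
                    test = NA_character_, statistic = NA_real_,
                    df = NA_real_, p = NA_real_, p_raw = NA_real_,
                    stars = NA_character_, row.names = NULL)
  for (i in seq_along(groups)) {
    if (length(groups[[i]]) >= 3L) {  # CI undefined below n = 3
      ci <- bootstrap_median_ci(groups[[i]], n_boot = n_boot, alpha = alpha,
                                seed = derive_seed(seed, i))
      res$ci_lo[i] <- ci[1]; res$ci_hi[i] <- ci[2]
    }
  }
  if (length(groups) == 2L) {
    tt <- two_sample_t(groups[[2]], groups[[1]], equal_var = equal_var)
    res$test[2] <- "two_sample_t"
    res$statistic[2] <- tt$t; res$df[2] <- tt$df
    res$p[2] <- tt$p; res$p_raw[2] <- tt$p
    res$stars[2] <- p_to_stars(tt$p)
  } else {
    av <- one_way_anova(groups, control = if (!is.null(control)) control
                        else names(groups)[1])
    res$test[-1] <- "one_way_anova"
    res$statistic[1] <- av$F; res$df[1] <- av$df1; res$p[1] <- av$p
    res$test[1] <- "one_way_anova_F"
    res$stars[1] <- p_to_stars(av$p)
    vc <- av$vs_control
    mi <- match(vc$group, res$group)
    res$statistic[mi] <- vc$t; res$df[mi] <- vc$df
    res$p[mi] <- vc$p_adj; res$p_raw[mi] <- vc$p_raw
    res$stars[mi] <- vc$stars
  }
  class(res) <- c("condition_comparison", "data.frame")
  res
}
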