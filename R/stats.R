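# Summary-statistic inference: one-way ANOVA, Tukey HSD, Pearson r.

#' Group summaries
#'
#' Builds the `(label, n, mean, sd)` table that drives summary-statistic
#' inference, as printed in published results sections.
#'
#' @param label group names.
#' @param n per-group sample sizes (each >= 2).
#' @param mean,sd group means and standard deviations (sd >= 0).
#' @return a data.frame of class `group_summary`.
#' @examples
#' tear_angles <- group_summary(
#'   c("pgy2", "pgy3", "pgy4", "fellow", "attending"),
#'   n = 5, mean = c(88.4, 70.4, 48.4, 18.4, 6.0),
#'   sd = c(14.3, 7.30, 4.03, 2.7, 1.58))
#' anova_oneway_from_summary(tear_angles)
#' @export
group_summary <- function(label, n, mean, sd) {
  k <- length(label)
  n <- rep_len(n, k); mean <- rep_len(mean, k); sd <- rep_len(sd, k)
  abort_if(anyDuplicated(label) > 0, "group labels must be distinct")
  abort_if(any(n < 2), "each group needs n >= 2")
  abort_if(any(sd < 0) || any(!is.finite(mean)) || any(!is.finite(sd)),
           "means must be finite and sds non-negative")
  out <- data.frame(label = as.character(label), n = as.integer(n),
                    mean = as.numeric(mean), sd = as.numeric(sd))
  class(out) <- c("group_summary", "data.frame")
  out
}

as_group_summary <- function(groups) {
  if (inherits(groups, "group_summary")) return(groups)
  abort_if(!is.data.frame(groups) ||
             !all(c("label", "n", "mean", "sd") %in% names(groups)),
           "`groups` must be a data.frame with columns label, n, mean, sd")
  group_summary(groups$label, groups$n, groups$mean, groups$sd)
}

#' Read group summaries from CSV
#'
#' Expects the columns `label,n,mean,sd`.
#' @param path file path.
#' @return a [group_summary()].
#' @export
read_group_summary_csv <- function(path) {
  d <- read.csv(path)
  as_group_summary(d)
}

#' One-way ANOVA from group summary statistics
#'
#' Computes the standard one-way fixed-effects ANOVA directly from per-
#' group `(n, mean, sd)`: between-group sum of squares
#' `SS_b = sum n_i (m_i - grand mean)^2` with `k - 1` df, pooled
#' within-group mean square `MS_w = sum (n_i - 1) s_i^2 / sum (n_i - 1)`,
#' `F = MS_b / MS_w` and the upper-tail F p-value. This is algebraically
#' identical to a raw-data ANOVA on any data matching the group moments.
#'
#' @param groups a [group_summary()] (or data.frame with columns
#'   `label`, `n`, `mean`, `sd`); at least two groups.
#' @return a list of class `anova_summary`: `F`, `df_between`,
#'   `df_within`, `ms_between`, `ms_within`, `p`, `grand_mean`. When every
#'   group mean is equal and every sd is zero the F ratio is undefined and
#'   reported as `NA` with a `reason` field.
#' @export
anova_oneway_from_summary <- function(groups) {
  g <- as_group_summary(groups)
  abort_if(nrow(g) < 2, "need at least two groups")
  N <- sum(g$n)
  grand <- sum(g$n * g$mean) / N
  df_b <- nrow(g) - 1L
  df_w <- sum(g$n - 1L)
  ss_b <- sum(g$n * (g$mean - grand)^2)
  ms_b <- ss_b / df_b
  ms_w <- sum((g$n - 1) * g$sd^2) / df_w
  if (ms_w == 0 && ms_b == 0) {
    out <- list(F = NA_real_, df_between = df_b, df_within = df_w,
                ms_between = ms_b, ms_within = ms_w, p = NA_real_,
                grand_mean = grand,
                reason = "all group means equal with zero variance")
  } else if (ms_w == 0) {
    out <- list(F = Inf, df_between = df_b, df_within = df_w,
                ms_between = ms_b, ms_within = ms_w, p = 0,
                grand_mean = grand)
  } else {
    f <- ms_b / ms_w
    out <- list(F = f, df_between = df_b, df_within = df_w,
                ms_between = ms_b, ms_within = ms_w,
                p = pf(f, df_b, df_w, lower.tail = FALSE),
                grand_mean = grand)
  }
  class(out) <- "anova_summary"
  out
}

#' @export
print.anova_summary <- function(x, ...) {
  cat(sprintf("One-way ANOVA (summary statistics): F(%d, %d) = %s, p = %s\n",
              x$df_between, x$df_within,
              formatC(x$F, digits = 4, format = "g"),
              formatC(x$p, digits = 4, format = "g")))
  if (!is.null(x$reason)) cat("  note:", x$reason, "\n")
  invisible(x)
}

#' Upper tail of the studentized range distribution
#'
#' `P(Q > q)` for the range of `k` independent group means divided by the
#' pooled standard error, with `df` error degrees of freedom — the null
#' distribution behind Tukey's HSD. Monotone decreasing in `q` and
#' increasing in `k` at fixed `q`.
#'
#' @param q observed studentized range statistic (>= 0).
#' @param k number of groups (>= 2).
#' @param df error degrees of freedom (>= 1).
#' @return upper-tail probability.
#' @examples
#' studentized_range_sf(3.877, k = 3, df = 10) # ~= 0.05
#' @export
studentized_range_sf <- function(q, k, df) {
  check_number(q, "q", lower = 0)
  check_number(k, "k", lower = 2)
  check_number(df, "df", lower = 1)
  ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
}

#' Tukey HSD from group summary statistics
#'
#' All-pairs Tukey honestly-significant-difference comparisons computed
#' from `(label, n, mean, sd)` summaries with equal per-group `n` (the
#' study design): `q_ij = |m_i - m_j| / sqrt(MS_w / n)` referred to the
#' studentized range distribution with `k` groups and `sum(n_i - 1)`
#' degrees of freedom. Unequal group sizes are rejected (the Tukey-Kramer
#' extension is out of scope).
#'
#' @param groups a [group_summary()]; >= 2 groups, equal `n`.
#' @param alpha significance level for the `significant` flag.
#' @return a data.frame of class `tukey_summary` with one row per
#'   unordered pair: `group1`, `group2`, `mean_diff` (`mean1 - mean2`),
#'   `se`, `q`, `p`, `significant`; attributes `ms_within`, `df_within`,
#'   `alpha`.
#' @examples
#' tear_angles <- group_summary(
#'   c("pgy2", "pgy3", "pgy4", "fellow", "attending"),
#'   n = 5, mean = c(88.4, 70.4, 48.4, 18.4, 6.0),
#'   sd = c(14.3, 7.30, 4.03, 2.7, 1.58))
#' tukey_hsd_from_summary(tear_angles)
#' @export
tukey_hsd_from_summary <- function(groups, alpha = 0.05) {
  g <- as_group_summary(groups)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  abort_if(nrow(g) < 2, "need at least two groups")
  abort_if(length(unique(g$n)) != 1,
           "Tukey HSD from summaries requires equal group sizes")
  n <- g$n[1]
  k <- nrow(g)
  df_w <- sum(g$n - 1L)
  ms_w <- sum((g$n - 1) * g$sd^2) / df_w
  se <- sqrt(ms_w / n)
  pairs <- combn(k, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  diff <- g$mean[i] - g$mean[j]
  if (se == 0) {
    q <- ifelse(diff == 0, 0, Inf)
    p <- ifelse(diff == 0, 1, 0)
  } else {
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
  }
  out <- data.frame(group1 = g$label[i], group2 = g$label[j],
                    mean_diff = diff, se = se, q = q, p = p,
                    significant = p < alpha)
  attr(out, "ms_within") <- ms_w
  attr(out, "df_within") <- df_w
  attr(out, "alpha") <- alpha
  class(out) <- c("tukey_summary", "data.frame")
  out
}

#' Pearson correlation with t-based significance
#'
#' Standard product-moment correlation with the two-sided p-value from the
#' `t = r * sqrt((n - 2) / (1 - r^2))` transform on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return a list of class `correlation_result`: `r`, `r_squared`, `n`,
#'   `p`.
#' @examples
#' pearson_correlation(1:5, c(26, 33.6, 45.4, 51, 54.4))
#' @export
pearson_correlation <- function(x, y) {
  abort_if(length(x) != length(y), "`x` and `y` must have equal length")
  abort_if(length(x) < 3, "need at least 3 observations")
  abort_if(any(!is.finite(x)) || any(!is.finite(y)),
           "inputs must be finite")
  abort_if(sd(x) == 0 || sd(y) == 0,
           "inputs must have nonzero variance")
  n <- length(x)
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, r_squared = r^2, n = n, p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (r^2 = %.4f), n = %d, p = %s\n",
              x$r, x$r_squared, x$n,
              formatC(x$p, digits = 4, format = "g")))
  invisible(x)
}
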