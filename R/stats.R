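# Statistical layer: t-tests (raw values or printed summaries), Pearson
# chi-squared, balanced mixed-design ANOVA, simple effects, Benjamini-
# Hochberg FDR, and metric-score correlation. All tests are implemented from
# their definitional formulas so they can be checked against independent
# oracles.

stat_result <- function(test, statistic, df, p, comparison = "",
                        p_adjusted = NA_real_, extra = list()) {
  out <- c(list(test = test, statistic = statistic, df = df, p_raw = p,
                p_adjusted = p_adjusted, comparison = comparison), extra)
  class(out) <- "ms_stat"
  out
}

#' @export
print.ms_stat <- function(x, ...) {
  cat(sprintf("<%s> %s: stat=%.4f df=%s p=%.4g%s\n", x$test, x$comparison,
              x$statistic, paste(signif(x$df, 6), collapse = ","), x$p_raw,
              if (!is.na(x$p_adjusted)) sprintf(" (FDR %.4g)", x$p_adjusted)
              else ""))
  invisible(x)
}

#' Independent-samples t-test (pooled variance)
#'
#' Two-sided Student t-test with pooled variance, from raw samples or from
#' printed summaries `list(n=, mean=, sd=)`. A `welch = TRUE` flag switches
#' to the unpooled (Welch-Satterthwaite) variant.
#'
#' @param x,y numeric vectors, or lists with `n`, `mean`, `sd`.
#' @param welch use the unequal-variance variant.
#' @return An `ms_stat`.
#' @export
ttest_independent <- function(x, y, welch = FALSE) {
  s <- function(v) {
    if (is.list(v)) {
      if (v$n < 2 || v$sd <= 0) stop_invalid("need n >= 2 and sd > 0")
      v
    } else {
      if (length(v) < 2) stop_invalid("need n >= 2 per group")
      list(n = length(v), mean = mean(v), sd = stats::sd(v))
    }
  }
  a <- s(x); b <- s(y)
  if (a$sd == 0 && b$sd == 0) stop("degenerate: zero variance in both groups")
  if (welch) {
    se2 <- a$sd^2 / a$n + b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / (a$sd^4 / (a$n^2 * (a$n - 1)) + b$sd^4 / (b$n^2 * (b$n - 1)))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 == 0) stop("degenerate: zero pooled variance")
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  stat_result(if (welch) "welch_t" else "student_t", t, df,
              2 * stats::pt(-abs(t), df))
}

#' Paired t-test
#'
#' Two-sided paired t-test, i.e. a one-sample t-test on the differences.
#'
#' @param x,y matched numeric vectors of equal length (>= 2).
#' @return An `ms_stat`.
#' @export
ttest_paired <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_invalid("need matched samples of equal length >= 2")
  }
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("degenerate: zero variance of paired differences")
  t <- mean(d) / (sd_d / sqrt(length(d)))
  df <- length(d) - 1
  stat_result("paired_t", t, df, 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param yates apply the continuity correction.
#' @return An `ms_stat` (df = 1).
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop_invalid("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop_invalid("counts must be nonnegative integers")
  }
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in 2x2 table")
  E <- outer(rs, cs) / n
  dev <- abs(table - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  x2 <- sum(dev^2 / E)
  stat_result(if (yates) "chi2_yates" else "chi2", x2, 1,
              stats::pchisq(x2, 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `p_(i) * m / i`, cumulative minimum from the
#' largest p down, capped at 1. Monotone in the raw p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# ---- mixed-design ANOVA -------------------------------------------------

#' Balanced mixed-design (split-plot) ANOVA
#'
#' Classical decomposition for one between-subjects factor and one
#' within-subjects factor on a balanced complete design: the between-subject
#' sum of squares splits into the group effect and subjects-within-groups;
#' the within-subject sum of squares into the within factor, the interaction,
#' and the residual. F ratios use the conventional error terms
#' (subjects-within-groups for the between effect; the residual for the
#' within effect and the interaction). No sphericity correction is applied.
#'
#' @param data data.frame in long form.
#' @param dv name of the numeric response column.
#' @param within name of the within-subject factor column.
#' @param between name of the between-subject factor column.
#' @param subject name of the subject-id column.
#' @return An `ms_anova`: data.frame with effect, ss, df, ms, f, p (rows:
#'   between, subjects_within_groups, within, interaction, residual, total).
#' @export
mixed_anova <- function(data, dv = "value", within = "condition",
                        between = "group", subject = "subject") {
  d <- data.frame(y = as.numeric(data[[dv]]),
                  w = factor(data[[within]]),
                  g = factor(data[[between]]),
                  s = factor(data[[subject]]))
  if (anyNA(d)) stop_invalid("missing values in design")
  tab <- table(d$s, d$w)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    stop("unbalanced design: each subject needs each within level exactly ",
         "once; offending cells: ",
         paste(rownames(tab)[bad[, 1]], colnames(tab)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  gw <- table(unique(d[, c("s", "g")])$g)
  if (length(unique(gw)) != 1L) {
    stop("unbalanced design: unequal group sizes (",
         paste(names(gw), gw, sep = "=", collapse = ", "), ")")
  }
  a <- nlevels(d$g); b <- nlevels(d$w); n <- unname(gw[1])
  if (a < 2L || b < 2L) stop_invalid("need >= 2 levels per factor")
  grand <- mean(d$y)
  mean_s <- tapply(d$y, d$s, mean)
  mean_g <- tapply(d$y, d$g, mean)
  mean_w <- tapply(d$y, d$w, mean)
  mean_gw <- tapply(d$y, list(d$g, d$w), mean)
  ss_total <- sum((d$y - grand)^2)
  ss_between_subj <- b * sum((mean_s - grand)^2)
  ss_group <- n * b * sum((mean_g - grand)^2)
  ss_subj <- ss_between_subj - ss_group
  ss_within_factor <- a * n * sum((mean_w - grand)^2)
  ss_int <- n * sum((mean_gw - outer(mean_g - grand, mean_w - grand, "+") -
                       grand)^2)
  ss_resid <- ss_total - ss_between_subj - ss_within_factor - ss_int
  df <- c(group = a - 1, subj = a * (n - 1), within = b - 1,
          int = (a - 1) * (b - 1), resid = a * (n - 1) * (b - 1))
  ms <- c(ss_group, ss_subj, ss_within_factor, ss_int, ss_resid) / df
  f <- c(ms[1] / ms[2], NA, ms[3] / ms[5], ms[4] / ms[5], NA)
  p <- c(stats::pf(f[1], df[1], df[2], lower.tail = FALSE), NA,
         stats::pf(f[3], df[3], df[5], lower.tail = FALSE),
         stats::pf(f[4], df[4], df[5], lower.tail = FALSE), NA)
  out <- data.frame(
    effect = c("between", "subjects_within_groups", "within", "interaction",
               "residual", "total"),
    ss = c(ss_group, ss_subj, ss_within_factor, ss_int, ss_resid, ss_total),
    df = c(df, sum(df)),
    ms = c(ms, NA),
    f = c(f, NA),
    p = c(p, NA))
  class(out) <- c("ms_anova", "data.frame")
  out
}

#' One-way between-subjects ANOVA (definitional)
#' @param y response vector.
#' @param g factor of group membership.
#' @return An `ms_stat`.
#' @export
oneway_anova <- function(y, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop_invalid("need >= 2 groups")
  grand <- mean(y)
  mg <- tapply(y, g, mean); ng <- tabulate(g)
  ssb <- sum(ng * (mg - grand)^2)
  ssw <- sum((y - mg[g])^2)
  df1 <- nlevels(g) - 1; df2 <- length(y) - nlevels(g)
  f <- (ssb / df1) / (ssw / df2)
  stat_result("oneway_f", f, c(df1, df2),
              stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Simple-effects analysis after a mixed ANOVA
#'
#' One-way ANOVA of the between factor at each within level, and a
#' repeated-measures one-way ANOVA of the within factor at each between
#' level; each family is FDR-adjusted separately.
#'
#' @inheritParams mixed_anova
#' @return data.frame: at (level held fixed), effect, f, df1, df2, p_raw,
#'   p_fdr.
#' @export
simple_effects <- function(data, dv = "value", within = "condition",
                           between = "group", subject = "subject") {
  d <- data.frame(y = as.numeric(data[[dv]]), w = factor(data[[within]]),
                  g = factor(data[[between]]), s = factor(data[[subject]]))
  rows <- list()
  for (lev in levels(d$w)) {
    sub <- d[d$w == lev, ]
    r <- oneway_anova(sub$y, sub$g)
    rows[[length(rows) + 1L]] <- data.frame(
      at = lev, effect = "between", f = r$statistic, df1 = r$df[1],
      df2 = r$df[2], p_raw = r$p_raw)
  }
  for (lev in levels(d$g)) {
    sub <- d[d$g == lev, ]
    # RM one-way: within factor with subject blocking
    grand <- mean(sub$y)
    mw <- tapply(sub$y, sub$w, mean); msub <- tapply(sub$y, sub$s, mean)
    nb <- nlevels(sub$w); ns <- nlevels(droplevels(sub$s))
    ssw <- ns * sum((mw - grand)^2)
    sss <- nb * sum((msub[unique(as.character(sub$s))] - grand)^2)
    sst <- sum((sub$y - grand)^2)
    sse <- sst - ssw - sss
    df1 <- nb - 1; df2 <- (nb - 1) * (ns - 1)
    f <- (ssw / df1) / (sse / df2)
    rows[[length(rows) + 1L]] <- data.frame(
      at = lev, effect = "within", f = f, df1 = df1, df2 = df2,
      p_raw = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (e in unique(out$effect)) {
    out$p_fdr[out$effect == e] <- fdr_adjust(out$p_raw[out$effect == e])
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation between a microstate metric and a score
#'
#' Two-sided Pearson correlation test. Batch use (e.g. across subgroups and
#' classes) FDR-adjusts the collected `p_raw` values with [fdr_adjust()], as
#' the pipeline's correlation table does.
#'
#' @param x,y paired numeric vectors (>= 3 observations).
#' @return An `ms_stat` with element `r`.
#' @export
correlate_metric_score <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_invalid("need >= 3 paired observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- stats::cor(x, y)
  df <- length(x) - 2
  t <- r * sqrt(df / (1 - r^2))
  stat_result("pearson_r", t, df, 2 * stats::pt(-abs(t), df),
              extra = list(r = r))
}
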