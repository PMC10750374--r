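# Statistical layer against definitional and stats:: oracles.

test_that("pooled t reproduces the printed TFI comparison and edge cases", {
  r <- ttest_independent(list(n = 22, mean = 94.76, sd = 61.60),
                         list(n = 22, mean = 94.45, sd = 52.08))
  expect_equal(round(r$p_raw, 3), 0.986)
  x <- c(1, 2, 3, 4)
  r2 <- ttest_independent(x, x)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_raw, 1)
  expect_error(ttest_independent(list(n = 1, mean = 0, sd = 1),
                                 list(n = 5, mean = 0, sd = 1)), "n >= 2")
})

test_that("independent t agrees with stats::t.test and permutation", {
  set.seed(12)
  x <- rnorm(6); y <- rnorm(6) + 1
  r <- ttest_independent(x, y)
  expect_equal(r$p_raw, stats::t.test(x, y, var.equal = TRUE)$p.value)
  rw <- ttest_independent(x, y, welch = TRUE)
  expect_equal(rw$p_raw, stats::t.test(x, y)$p.value)
  # brute-force permutation oracle on the pooled-t statistic
  pooled <- c(x, y)
  obs <- abs(r$statistic)
  set.seed(13)
  perm <- replicate(20000, {
    idx <- sample(12, 6)
    abs(ttest_independent(pooled[idx], pooled[-idx])$statistic)
  })
  p_perm <- mean(perm >= obs - 1e-12)
  # parametric and permutation nulls differ slightly at n = 6; allow the
  # Monte-Carlo band plus a small-sample discrepancy margin
  expect_lt(abs(p_perm - r$p_raw), 3 * sqrt(p_perm * (1 - p_perm) / 20000) +
              0.025)
})

test_that("paired t: closed form, sign symmetry, degenerate input", {
  set.seed(14)
  x <- rnorm(10)
  y <- x + 0.8 + rnorm(10, sd = 0.5)
  r <- ttest_paired(x, y)
  d <- x - y
  t_one <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r$statistic, t_one)
  expect_equal(r$p_raw, 2 * pt(-abs(t_one), 9))
  expect_equal(r$p_raw, stats::t.test(x, y, paired = TRUE)$p.value)
  r_swap <- ttest_paired(y, x)
  expect_equal(r_swap$statistic, -r$statistic)
  expect_equal(r_swap$p_raw, r$p_raw)
  expect_error(ttest_paired(x, x), "zero variance")
})

test_that("chi-squared: gender table, proportional table, oracle equality", {
  r <- chi2_2x2(matrix(c(11, 12, 11, 10), 2), yates = TRUE)
  expect_equal(r$statistic, 0)
  expect_gt(r$p_raw, 0.999)
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(chi2_2x2(prop, yates = FALSE)$statistic, 0)
  expect_equal(chi2_2x2(prop, yates = FALSE)$p_raw, 1)
  set.seed(15)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chi2_2x2(tab, yates = TRUE)$p_raw,
                 stats::chisq.test(tab, correct = TRUE)$p.value)
    expect_equal(chi2_2x2(tab, yates = FALSE)$p_raw,
                 stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("BH-FDR: hand case, p.adjust oracle, monotonicity", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(16)
  for (i in 1:200) {
    p <- runif(sample(2:30, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) > -1e-12))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mixed ANOVA matches aov and conserves sums of squares", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    d <- expand.grid(subject = paste0("s", seq_len(2 * n)),
                     condition = c("w1", "w2", "w3"))
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n, "g1", "g2")
    d$value <- rnorm(nrow(d)) + as.numeric(d$condition == "w2") * 0.4
    av <- mixed_anova(d, "value", "condition", "group", "subject")
    fit <- stats::aov(value ~ group * condition + Error(subject / condition),
                      data = d)
    s <- summary(fit)
    bt <- s[["Error: subject"]][[1]]
    wt <- s[["Error: subject:condition"]][[1]]
    expect_equal(av$ss[av$effect == "between"], bt["group", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(av$ss[av$effect == "within"], wt["condition", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(av$ss[av$effect == "interaction"],
                 wt["group:condition", "Sum Sq"], tolerance = 1e-8)
    expect_equal(av$p[av$effect == "between"], bt["group", "Pr(>F)"],
                 tolerance = 1e-8)
    expect_equal(av$p[av$effect == "interaction"],
                 wt["group:condition", "Pr(>F)"], tolerance = 1e-8)
    # SS conservation
    comp <- av$ss[av$effect != "total"]
    expect_equal(sum(comp), av$ss[av$effect == "total"], tolerance = 1e-8)
  }
})

test_that("mixed ANOVA: symmetric groups give F ~ 0, unbalance errors", {
  d <- expand.grid(subject = paste0("s", 1:8), condition = c("w1", "w2"))
  d$group <- rep(c("g1", "g2"), each = 4)[match(d$subject,
                                                paste0("s", 1:8))]
  base <- c(1, 2, 3, 4)
  d$value <- base[as.integer(sub("s", "", d$subject)) %% 4 + 1] +
    as.numeric(d$condition == "w2")
  av <- mixed_anova(d, "value", "condition", "group", "subject")
  expect_lt(av$f[av$effect == "between"], 1e-12)
  expect_error(mixed_anova(d[-1, ], "value", "condition", "group", "subject"),
               "unbalanced")
})

test_that("simple effects localize a single-level effect", {
  set.seed(18)
  d <- expand.grid(subject = paste0("s", 1:20), condition = c("w1", "w2", "w3"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 10, "g1", "g2")
  d$value <- rnorm(nrow(d), sd = 0.5) +
    ifelse(d$condition == "w2" & d$group == "g1", 3, 0)
  se <- simple_effects(d, "value", "condition", "group", "subject")
  bet <- se[se$effect == "between", ]
  expect_true(bet$p_fdr[bet$at == "w2"] < 0.01)
  expect_true(all(bet$p_fdr[bet$at != "w2"] > 0.05))
  # between-effect rows reduce to the one-way ANOVA at each level
  w1 <- d[d$condition == "w1", ]
  expect_equal(bet$p_raw[bet$at == "w1"],
               oneway_anova(w1$value, w1$group)$p_raw)
})

test_that("simple effects control false positives on null data", {
  set.seed(21)
  hits <- replicate(300, {
    d <- expand.grid(subject = paste0("s", 1:12), condition = c("w1", "w2"))
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 6, "g1", "g2")
    d$value <- rnorm(nrow(d))
    se <- simple_effects(d, "value", "condition", "group", "subject")
    any(se$p_fdr[se$effect == "between"] < 0.05)
  })
  # per-family false-positive rate at most the nominal q (binomial slack)
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("correlation: exact, errors, simulation calibration", {
  x <- c(1, 3, 2, 5, 4)
  r <- correlate_metric_score(x, x)
  expect_equal(r$r, 1)
  expect_error(correlate_metric_score(x, rep(1, 5)), "constant")
  expect_error(correlate_metric_score(1:2, 1:2), ">= 3")
  set.seed(99)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(correlate_metric_score(a, b)$p_raw,
               stats::cor.test(a, b)$p.value)
  # r_true = 0.5, n = 22: mean estimate within 0.05 over 300 reps
  set.seed(19)
  rs <- replicate(300, {
    a <- rnorm(22)
    b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(22)
    correlate_metric_score(a, b)$r
  })
  expect_lt(abs(mean(rs) - 0.5), 0.05)
  # independent variables: type-I close to nominal
  set.seed(20)
  hits <- replicate(400, correlate_metric_score(rnorm(22),
                                                rnorm(22))$p_raw < 0.05)
  expect_lt(abs(mean(hits) - 0.05), 0.035)
})
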