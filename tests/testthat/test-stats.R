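test_that("condition summaries match direct computation", {
  set.seed(3)
  rec <- data.frame(condition = "x", R = rnorm(25, 2.5, 0.4))
  rec$positive <- rec$R >= 2
  s <- summarize_condition(rec)
  tt <- t.test(rec$R)
  expect_equal(s$mean_R, mean(rec$R))
  expect_equal(c(s$ci_low, s$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-10)
  expect_equal(s$percent_positive, 100 * mean(rec$positive))
  expect_equal(s$n, 25)
})

test_that("identical values give a degenerate confidence interval", {
  rec <- data.frame(condition = "x", R = rep(2.2, 10), positive = TRUE)
  s <- summarize_condition(rec)
  expect_equal(s$ci_low, 2.2)
  expect_equal(s$ci_high, 2.2)
  expect_error(summarize_condition(rec[1, ]), "insufficient data")
})

test_that("percent positive counts reproduce the published proportions", {
  rec <- data.frame(condition = "wt", R = c(rep(3, 51), rep(1.2, 9)))
  rec$positive <- classify_positive(rec$R)
  expect_equal(summarize_condition(rec)$percent_positive, 85)
  rec2 <- data.frame(condition = "mut", R = c(rep(3, 10), rep(1.2, 50)))
  rec2$positive <- classify_positive(rec2$R)
  expect_equal(round(summarize_condition(rec2)$percent_positive), 17)
})

test_that("two-group ANOVA reduces to the pooled t-test (F = t^2)", {
  set.seed(8)
  g <- list(a = rnorm(20, 2.8, 0.5), b = rnorm(24, 1.5, 0.5))
  res <- anova_with_bonferroni(g, reference = "b")
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(res$F_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$posthoc$raw_p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$posthoc$adjusted_p, res$posthoc$raw_p) # m = 1
})

test_that("post-hoc p-values match pairwise t-tests with pooled SD", {
  set.seed(15)
  g <- list(ctrl = rnorm(15, 1.5, 0.4), mid = rnorm(15, 1.8, 0.4),
            high = rnorm(15, 2.9, 0.4))
  res <- anova_with_bonferroni(g, reference = "ctrl")
  pw <- pairwise.t.test(unlist(g), rep(names(g), each = 15),
                        p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(res$posthoc$raw_p[res$posthoc$condition == "mid"],
               pw$p.value["mid", "ctrl"], tolerance = 1e-10)
  expect_equal(res$posthoc$raw_p[res$posthoc$condition == "high"],
               pw$p.value["high", "ctrl"], tolerance = 1e-10)
  expect_equal(res$posthoc$adjusted_p,
               pmin(1, 2 * res$posthoc$raw_p))
  expect_true(all(res$posthoc$adjusted_p >= res$posthoc$raw_p))
  expect_true(all(res$posthoc$adjusted_p <= 1))
})

test_that("all-pairs mode compares every pair with the right correction", {
  set.seed(2)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10), d = rnorm(10))
  res <- anova_with_bonferroni(g, all_pairs = TRUE)
  expect_equal(nrow(res$posthoc), 6)
  expect_equal(res$posthoc$adjusted_p, pmin(1, 6 * res$posthoc$raw_p))
})

test_that("degenerate inputs are rejected", {
  expect_error(anova_with_bonferroni(list(a = 1:5)), "at least 2 groups")
  expect_error(anova_with_bonferroni(list(a = 1:5, b = 2)),
               "at least 2 values")
  expect_error(anova_with_bonferroni(list(a = 1:5, b = 1:5), reference = "z"),
               "reference")
})

test_that("significance codes follow the star convention", {
  stars <- opticr:::signif_stars(c(0.0005, 0.005, 0.03, 0.2))
  expect_equal(as.character(stars), c("***", "**", "*", "ns"))
})
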