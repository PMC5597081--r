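# Statistical layer.

test_that("two-way interaction F matches a hand-computed balanced 2x2", {
  # textbook fixture, n = 2 per cell
  d <- data.frame(age = rep(c("y", "y", "o", "o"), each = 2),
                  genotype = rep(c("wt", "mut"), each = 2, times = 2),
                  value = c(10, 12, 20, 22, 30, 32, 52, 54))
  res <- twoway_interaction(d)
  # oracle: balanced SS decomposition by hand
  m <- tapply(d$value, list(d$age, d$genotype), mean)
  ga <- rowMeans(m); gb <- colMeans(m); gg <- mean(d$value)
  ss_int <- 2 * sum((m - outer(ga, rep(1, 2)) -
                       outer(rep(1, 2), gb) + gg)^2)
  ss_err <- sum((d$value - ave(d$value,
                               interaction(d$age, d$genotype)))^2)
  f_oracle <- (ss_int / 1) / (ss_err / 4)
  expect_equal(res$F, f_oracle, tolerance = 1e-12)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 4L)
})

test_that("interaction test validates its design", {
  d <- data.frame(age = c("y", "y", "o"), genotype = c("wt", "wt", "wt"),
                  value = 1:3)
  expect_error(twoway_interaction(d), "2 levels")
  d2 <- data.frame(age = rep(c("y", "o"), each = 4),
                   genotype = rep(c("wt", "mut"), times = 4), value = rnorm(8))
  d2 <- d2[!(d2$age == "o" & d2$genotype == "mut"), ]
  expect_error(twoway_interaction(d2), "empty design cell")
})

test_that("two-way interaction: null calibration and power", {
  # type-I error at alpha = 0.05 over null simulations (scaled to 400 sims
  # here; the acceptance suite runs the full 1000)
  set.seed(101)
  rej <- mean(replicate(400, {
    d <- expand.grid(age = c("y", "o"), genotype = c("wt", "mut"), r = 1:4)
    d$value <- rnorm(nrow(d))
    twoway_interaction(d)$p < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  # crossed +/-delta interaction with delta >> sigma
  d <- expand.grid(age = c("y", "o"), genotype = c("wt", "mut"), r = 1:5)
  d$value <- ifelse(d$age == "y", 1, -1) * ifelse(d$genotype == "wt", 1, -1) *
    10 + rnorm(nrow(d), 0, 0.5)
  expect_lt(twoway_interaction(d)$p, 1e-6)
})

test_that("Tukey-Kramer equals the pooled t-test for two groups", {
  set.seed(11)
  d <- data.frame(group = rep(c("a", "b"), c(7, 9)), value = rnorm(16))
  tk <- oneway_posthoc(d, "tukey_kramer")
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)
})

test_that("identical groups give adjusted p near 1; stars at paper thresholds", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                  value = rep(c(1, 2, 3, 4, 5), 3))
  tk <- oneway_posthoc(d, "tukey_kramer")
  expect_true(all(tk$p_adj > 0.99))
  expect_equal(gjflux:::significance_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
})

test_that("Dunnett requires a control and reduces to the t-test at k = 1", {
  d <- data.frame(group = rep(c("ctrl", "t1"), each = 8),
                  value = c(rnorm(8), rnorm(8, 1)))
  expect_error(oneway_posthoc(d, "dunnett"), "control")
  dn <- oneway_posthoc(d, "dunnett", control = "ctrl")
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(dn$p_adj, tt$p.value, tolerance = 1e-4)
})

test_that("post hoc familywise error is controlled at 0.05", {
  set.seed(202)
  fam_tk <- mean(replicate(300, {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                    value = rnorm(15))
    any(oneway_posthoc(d, "tukey_kramer")$p_adj < 0.05)
  }))
  expect_lte(fam_tk, 0.07)     # 0.05 plus Monte-Carlo slack at 300 sims
  fam_dn <- mean(replicate(200, {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                    value = rnorm(15))
    any(oneway_posthoc(d, "dunnett", control = "a")$p_adj < 0.05)
  }))
  expect_lte(fam_dn, 0.08)
})

test_that("normality check: preconditions, null calibration, power", {
  expect_error(normality_check(c(1, 2, 3, 4)), "5 observations")
  expect_error(normality_check(rep(2, 10)), "zero variance")
  # null p-values approximately uniform
  set.seed(303)
  ps <- replicate(200, normality_check(rnorm(60))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # exponential alternative: p < 0.01 in >= 95% of seeds
  hits <- mean(replicate(100, normality_check(rexp(200))$p < 0.01))
  expect_gte(hits, 0.95)
})

test_that("group summaries report mean and SEM definitionally", {
  d <- data.frame(group = rep(c("a", "b"), c(4, 6)),
                  value = c(1, 2, 3, 4, 2, 4, 6, 8, 10, 12))
  sm <- summarize_groups(d)
  expect_equal(sm$mean, c(2.5, 7))
  expect_equal(sm$sem, c(sd(1:4) / 2, sd(c(2, 4, 6, 8, 10, 12)) / sqrt(6)))
  rep_lines <- report_markdown(d)
  expect_true(any(grepl("Means", rep_lines)))
  expect_true(any(grepl("b - a", rep_lines)))
})
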