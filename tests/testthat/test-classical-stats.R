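test_that("K-S normality statistic and calibration behave as expected", {
  # single observation at the reference mean: CDF gap is exactly 0.5
  r <- ks_normality(0, mean = 0, sd = 1)
  expect_equal(r$statistic, 0.5)

  # a big uniform sample is flagrantly non-normal even after fitting
  set.seed(1)
  u <- runif(1000)
  expect_lt(ks_normality(u)$p_value, 0.01)

  # constant sample cannot be fitted
  expect_error(ks_normality(rep(3, 10)), "constant")

  # drawing from the fixed reference itself gives uniform p-values
  set.seed(2)
  ps <- replicate(200, ks_normality(rnorm(1000), mean = 0, sd = 1)$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.05)
})

test_that("repeated-measures ANOVA matches independent decompositions", {
  # subject offsets plus residuals with equal column means: F = 0 exactly
  M0 <- outer(c(1, 5, 9, 2), rep(1, 3)) +
    rbind(c(1, -1, 0), c(-1, 1, 0), c(0, 1, -1), c(0, -1, 1))
  expect_equal(rm_anova(M0)$statistic, 0)

  # hand-sized table against the cell-by-cell sum-of-squares oracle
  M <- rbind(c(3, 5, 7), c(2, 4, 9), c(6, 7, 8), c(1, 2, 2))
  r <- rm_anova(M)
  expect_equal(r$statistic, brute_rm_F(M), tolerance = 1e-12)
  expect_equal(r$df, c(2, 6))

  # and against the aov() within-subject decomposition
  df <- data.frame(y = as.vector(M),
                   subj = factor(rep(1:4, 3)),
                   time = factor(rep(1:3, each = 4)))
  fit <- summary(aov(y ~ time + Error(subj/time), data = df))
  F_aov <- fit[["Error: subj:time"]][[1]]["time", "F value"]
  expect_equal(r$statistic, F_aov, tolerance = 1e-10)

  # identical columns plus subject offsets: degenerate error term
  Md <- outer(c(1, 2, 3), rep(1, 3))
  expect_error(rm_anova(Md), "degenerate")
})

test_that("rm_anova type-I error is calibrated at the study's sample size", {
  set.seed(99)
  rej <- mean(replicate(2000, {
    M <- matrix(rnorm(16 * 3), 16, 3)
    rm_anova(M)$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Tukey HSD matches the studentized-range formula and TukeyHSD()", {
  # equal means: q = 0, p = 1
  t0 <- tukey_hsd(c(a = 2, b = 2, c = 2), ms_error = 1.3,
                  n_per_group = 5, df_error = 12)
  expect_true(all(t0$q == 0))
  expect_true(all(t0$p_value == 1))

  # arithmetic oracle on hand-set values
  th <- tukey_hsd(c(a = 2, b = 4, c = 7), ms_error = 2,
                  n_per_group = 5, df_error = 12)
  q_ab <- abs(4 - 2) / sqrt(2 / 5)
  expect_equal(th$q[th$group_i == "a" & th$group_j == "b"], q_ab)
  expect_equal(th$p_value[1],
               ptukey(q_ab, nmeans = 3, df = 12, lower.tail = FALSE))

  # p monotone decreasing in q at fixed df
  qs <- seq(0.5, 5, by = 0.5)
  ps <- ptukey(qs, nmeans = 3, df = 12, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  # relabeling invariance
  th_rev <- tukey_hsd(c(c = 7, b = 4, a = 2), ms_error = 2,
                      n_per_group = 5, df_error = 12)
  expect_setequal(round(th$p_value, 12), round(th_rev$p_value, 12))

  # agreement with stats::TukeyHSD on a balanced one-way layout
  set.seed(4)
  g <- factor(rep(1:3, each = 6))
  y <- rnorm(18) + as.numeric(g)
  fit <- aov(y ~ g)
  ref <- TukeyHSD(fit)$g[, "p adj"]
  ow <- one_way_anova(split(y, g))
  mine <- tukey_hsd(ow$means, ow$ms_error, 6, ow$df_error)
  expect_equal(unname(mine$p_value), unname(ref), tolerance = 1e-8)
})

test_that("one-way ANOVA equals hand decomposition and the t-test square", {
  r <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$statistic, 1.5)
  expect_equal(r$df, c(1, 4))

  set.seed(10)
  a <- rnorm(8); b <- rnorm(9, 0.5)
  r2 <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-10)

  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "variance")
})

test_that("power_min_r inverts the correlation power function", {
  # minimal detectable r shrinks as the sample grows
  rs <- vapply(c(10, 16, 30, 60, 120), power_min_r, 0)
  expect_true(all(diff(rs) < 0))

  # as target power approaches alpha, the detectable effect vanishes
  r_seq <- vapply(c(0.06, 0.2, 0.5, 0.8), function(p)
    power_min_r(16, alpha = 0.05, power = p), 0)
  expect_true(all(diff(r_seq) > 0))
  expect_lt(r_seq[1], 0.1)

  # round trip: the returned r really attains the requested power, where
  # power is recomputed by direct numerical integration of the exact
  # sampling density of the correlation coefficient
  r100 <- power_min_r(100, alpha = 0.05, power = 0.8)
  dens <- function(r, rho, n) {
    hyp <- function(x) {
      s <- 1; term <- 1
      for (k in 0:500) {
        term <- term * (0.5 + k)^2 / ((n - 0.5 + k) * (k + 1)) * x
        s <- s + term
        if (abs(term) < 1e-15 * s) break
      }
      s
    }
    (n - 2) * exp(lgamma(n - 1) - lgamma(n - 0.5)) *
      (1 - rho^2)^((n - 1) / 2) * (1 - r^2)^((n - 4) / 2) /
      (sqrt(2 * pi) * (1 - rho * r)^(n - 1.5)) *
      vapply(r, function(ri) hyp((rho * ri + 1) / 2), 0)
  }
  tc <- qt(0.975, 98); rc <- tc / sqrt(tc^2 + 98)
  pow <- integrate(dens, rc, 1, rho = r100, n = 100)$value +
    integrate(dens, -1, -rc, rho = r100, n = 100)$value
  expect_equal(pow, 0.8, tolerance = 1e-4)

  # agreement with the plain Fisher-z closed form for moderate n
  for (n in c(30, 60, 120)) {
    z <- (qnorm(0.975) + qnorm(0.8)) / sqrt(n - 3)
    expect_lt(abs(power_min_r(n) - tanh(z)), 0.03)
  }

  expect_error(power_min_r(3), "n >= 4")
})

test_that("reference-norm classification uses the 1-SD band", {
  norm <- reference_norm("Anxiety", 4.25, 3.53)
  expect_equal(compare_to_reference(4.25, norm), "within_1sd")
  expect_equal(compare_to_reference(7.79, norm), "above_1sd")
  expect_equal(compare_to_reference(0.5, norm), "below")
  expect_error(reference_norm("Anxiety", 4, -1))
})

test_that("cohort_stats produces a tidy, complete summary", {
  co <- make_complete_cohort(12, seed = 3)
  st <- cohort_stats(co)
  expect_true(all(c("ks_normality", "rm_anova", "tukey_hsd",
                    "one_way_anova", "norm_comparison") %in% st$analysis))
  # 8 RM rows, 3 Tukey pairs each, 3 gender contrasts per subscale
  expect_equal(sum(st$analysis == "rm_anova"), 8)
  expect_equal(sum(st$analysis == "tukey_hsd"), 24)
  expect_equal(sum(st$analysis == "one_way_anova"), 24)
  expect_true(all(st$p_value >= 0 & st$p_value <= 1, na.rm = TRUE))
  # empty cohort degrades to an empty frame
  empty <- cohort_table(as.data.frame(co)[0, ])
  expect_equal(nrow(cohort_stats(empty)), 0)
})
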