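test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(43)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, stepup_bh(p))
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("Cohen's d is the pooled-sd standardised mean difference", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x), 0)

  set.seed(47)
  a <- rnorm(200, 0, 1)
  b <- rnorm(200, 1, 1)
  d <- cohens_d(a, b)
  expect_equal(d, abs(mean(a) - mean(b)) /
                 sqrt(((199) * var(a) + (199) * var(b)) / 398))
  expect_equal(cohens_d(10 * a, 10 * b), d)       # scale invariance
  expect_equal(cohens_d(b, a), d)                 # unsigned

  expect_warning(nd <- cohens_d(c(1, 1), c(1, 1)), "zero pooled sd")
  expect_true(is.na(nd))
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("effect-size bins use the 0.2 / 0.5 / 0.8 cut-offs", {
  expect_equal(effect_category(c(0, 0.19, 0.2, 0.49, 0.5, 0.79, 0.8, 2)),
               c("none", "none", "small", "small", "medium", "medium",
                 "large", "large"))
  expect_error(effect_category(-0.1), ">= 0")
})

test_that("nerve t-test is symmetric and sane", {
  set.seed(53)
  a <- rnorm(10)
  expect_equal(nerve_ttest(a, a), 1, tolerance = 1e-12)
  b <- rnorm(12, 0.5)
  expect_equal(nerve_ttest(a, b), nerve_ttest(b, a))
  expect_warning(p <- nerve_ttest(c(2, 2), c(2, 2)), "zero variance")
  expect_true(is.na(p))
})

test_that("boxplot summary follows the Q1/Q3 +/- 1.5 IQR convention", {
  s <- boxplot_summary(1:5)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$median, 3)
  expect_equal(s$whisker_lo, -1)
  expect_equal(s$whisker_hi, 7)
  expect_length(s$outliers, 0)

  const <- boxplot_summary(rep(3, 10))
  expect_equal(const$q1, const$q3)
  expect_equal(const$mean, 3)
  expect_length(const$outliers, 0)

  set.seed(59)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1))
    s <- boxplot_summary(x)
    expect_setequal(s$outliers, x[x < s$whisker_lo | x > s$whisker_hi])
  }
})

test_that("significance labels follow the annotation convention", {
  expect_equal(significance_label(c(0.2, 0.1, 0.02, 0.005, 5e-4, 5e-5)),
               c("ns", "*", "*", "**", "***", "****"))
})

test_that("with zero animal variance the LMM reduces to a two-sample comparison", {
  tab <- simulate_metric_table(c(A = 0, B = 0.4), 6, 3, animal_sd = 0,
                               resid_sd = 0.3, seed = 63)
  fit <- suppressMessages(fit_metric_lmm(tab, "value",
                                         condition_cols = "condition",
                                         log_transform = FALSE))
  expect_true(fit$boundary_fit)
  p_t <- t.test(tab$value[tab$condition == "A"],
                tab$value[tab$condition == "B"], var.equal = TRUE)$p.value
  expect_lt(abs(fit$results$p - p_t) / p_t, 0.1)
  # Satterthwaite df never exceeds the fixed-effects residual df
  expect_lte(fit$results$df, nrow(tab) - 2)
})

test_that("the animal random factor absorbs duplicated image rows", {
  tab <- simulate_metric_table(c(A = 0, B = 0.5), 6, 4, animal_sd = 0.3,
                               resid_sd = 0.15, seed = 67)
  fit1 <- suppressMessages(fit_metric_lmm(tab, "value",
                                          condition_cols = "condition",
                                          log_transform = FALSE))
  fit2 <- suppressMessages(fit_metric_lmm(rbind(tab, tab), "value",
                                          condition_cols = "condition",
                                          log_transform = FALSE))
  expect_lt(abs(fit2$results$p - fit1$results$p) / fit1$results$p, 0.05)
})

test_that("the fitted object carries the full contrast table", {
  tab <- simulate_metric_table(c(A = 0.2, B = 0.6, C = 1.1), 4, 3,
                               animal_sd = 0.2, resid_sd = 0.2, seed = 71)
  tab$ftr <- exp(tab$value)
  fit <- suppressMessages(fit_metric_lmm(tab, "ftr",
                                         condition_cols = "condition"))
  res <- fit$results
  expect_equal(nrow(res), 3)                       # all pairwise contrasts
  expect_true(all(res$q >= res$p - 1e-15))
  expect_identical(res$significant, res$q < 0.1)
  expect_true(all(res$d_category %in% c("none", "small", "medium", "large")))
  expect_equal(res$estimate_ratio, exp(res$estimate))
  expect_true(fit$log_transform)

  sub <- suppressMessages(fit_metric_lmm(tab, "ftr",
                                         condition_cols = "condition",
                                         contrasts = res$contrast[1]))
  expect_equal(nrow(sub$results), 1)
  expect_output(print(fit), "Satterthwaite")

  # undefined metric rows are dropped with a message
  tab$ftr[1] <- NA
  expect_message(fit_metric_lmm(tab, "ftr", condition_cols = "condition"),
                 "dropping 1")

  expect_error(fit_metric_lmm(tab, "nope", condition_cols = "condition"),
               "not in table")
  few <- tab[tab$animal_id %in% c("A_a01", "B_a01", "C_a01"), ]
  expect_error(suppressMessages(
    fit_metric_lmm(few, "ftr", condition_cols = "condition")),
    "at least 2 animals")
})

test_that("metric-table simulation honours its generative parameters", {
  tab <- simulate_metric_table(c(A = 1, B = 2), 50, 6, animal_sd = 0.5,
                               resid_sd = 0.1, seed = 73)
  expect_equal(nrow(tab), 2 * 50 * 6)
  per_animal <- tapply(tab$value, tab$animal_id, mean)
  grp <- tapply(tab$value, tab$condition, mean)
  # group contrast is 1 +/- sd ~ 0.11 from the animal effects
  expect_lt(abs(unname(grp["B"] - grp["A"]) - 1), 0.45)
  a_sd <- sd(per_animal[grepl("^A", names(per_animal))])
  expect_gt(a_sd, 0.3)
  expect_lt(a_sd, 0.7)

  crossed <- simulate_metric_table(c(A = 0, B = 1), 8, 2, animal_sd = 0.4,
                                   resid_sd = 0.1, crossed = TRUE, seed = 79)
  expect_equal(length(unique(crossed$animal_id)), 8)
  expect_equal(nrow(crossed), 8 * 2 * 2)
})
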