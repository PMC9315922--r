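test_that("product-limit estimate matches the hand calculation", {
  km <- km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$table$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  expect_equal(km$table$n_risk, c(4, 3, 2, 1))

  # all censored: flat at 1, median undefined
  km2 <- km_fit(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km2$table$surv == 1))
  expect_true(is.na(km2$median))

  # single event
  km3 <- km_fit(5, TRUE)
  expect_equal(km3$table$surv, 0)
  expect_equal(km3$median, 5)

  expect_error(km_fit(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("KM with censoring agrees with the survfit oracle", {
  skip_if_not_installed("survival")
  set.seed(21)
  t <- round(rexp(120, 0.3), 2) + 0.01
  e <- runif(120) < 0.7
  km <- km_fit(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(km$table$surv, sf$surv, tolerance = 1e-12)
  expect_equal(km$table$time, sf$time)
  expect_equal(km$table$n_event, sf$n.event)
  expect_equal(km$median,
               unname(summary(sf)$table["median"]))
})

test_that("KM equals the empirical survival function when nothing is censored", {
  set.seed(33)
  for (rep in 1:10) {
    t <- sample(1:30, 40, replace = TRUE)
    km <- km_fit(t, rep(TRUE, 40))
    emp <- vapply(km$table$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$table$surv, emp, tolerance = 1e-12)
  }
})

test_that("log-rank: self-comparison is zero, separation is highly significant", {
  t <- c(1.5, 2.1, 3.3, 4.8, 6.0)
  e <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)

  set.seed(41)
  ta <- runif(50, 1, 2); tb <- runif(50, 10, 11)
  lr2 <- logrank_test(c(ta, tb), rep(TRUE, 100), rep(c("a", "b"), each = 50))
  expect_lt(lr2$p_value, 1e-4)
})

test_that("log-rank agrees with survdiff and is invariant to time rescaling", {
  skip_if_not_installed("survival")
  set.seed(52)
  t <- rexp(150, 0.2); e <- runif(150) < 0.8
  g <- rep(c("x", "y"), length.out = 150)
  lr <- logrank_test(t, e, g)
  sd_ <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$chi_square, sd_$chisq, tolerance = 1e-10)
  # symmetric in group labels; invariant under monotone time transform
  lr_sw <- logrank_test(t, e, ifelse(g == "x", "y", "x"))
  expect_equal(lr_sw$chi_square, lr$chi_square)
  lr_mono <- logrank_test(log1p(t), e, g)
  expect_equal(lr_mono$chi_square, lr$chi_square)
})

test_that("Cox estimates match coxph to high precision (Efron and Breslow)", {
  skip_if_not_installed("survival")
  set.seed(63)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.2 * exp(0.8 * x))
  e <- runif(n) < 0.85
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(t, e, x, ties = ties)
    ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = ties)
    expect_lt(abs(fit$coefficients - coef(ref)) / abs(coef(ref)), 1e-6)
    expect_equal(unname(fit$se), sqrt(diag(ref$var)), tolerance = 1e-6)
    expect_true(fit$converged)
  }
  # tied times exercise the Efron correction
  tt <- round(t, 0) + 1
  fit_t <- cox_fit(tt, e, x, ties = "efron")
  ref_t <- survival::coxph(survival::Surv(tt, e) ~ x, ties = "efron")
  expect_lt(abs(fit_t$coefficients - coef(ref_t)) / abs(coef(ref_t)), 1e-6)
})

test_that("two-variable Cox matches coxph and the score test equals the log-rank", {
  skip_if_not_installed("survival")
  set.seed(74)
  n <- 300
  x1 <- rpois(n, 8)
  x2 <- rnorm(n)
  t <- rexp(n, 0.2 * exp(-0.06 * x1 + 0.1 * x2))
  e <- runif(n) < 0.8
  fit <- cox_fit(t, e, cbind(burden = x1, lr = x2))
  ref <- survival::coxph(survival::Surv(t, e) ~ x1 + x2)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$ci_lower),
               unname(exp(coef(ref) - 1.96 * sqrt(diag(ref$var)))),
               tolerance = 1e-5)

  # Breslow score test at beta=0 for a binary covariate == log-rank chi-square
  xb <- rbinom(n, 1, 0.4)
  fit_b <- cox_fit(t, e, xb, ties = "breslow")
  lr <- logrank_test(t, e, xb)
  expect_equal(fit_b$score_test$chi_square, lr$chi_square, tolerance = 1e-8)
})

test_that("degenerate covariates and zero events are rejected", {
  expect_error(cox_fit(1:5, rep(TRUE, 5), rep(2, 5)), "degenerate covariate")
  expect_error(cox_fit(1:5, rep(FALSE, 5), rnorm(5)), "at least one event")
  expect_error(logrank_test(1:4, rep(FALSE, 4), c("a", "a", "b", "b")),
               "no events")
})

test_that("binary-arm hazard ratio of 2 is recovered at n = 2000", {
  set.seed(85)
  n <- 2000
  x <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.1 * exp(log(2) * x))
  fit <- cox_fit(t, rep(TRUE, n), x)
  # asymptotic tolerance: 3 standard errors around the true log-HR
  expect_lt(abs(fit$coefficients - log(2)), 3 * fit$se)
})

test_that("stratified TTFT report carries curves, medians and pairwise tests", {
  fx <- fixture_small()
  cohort <- run_pipeline(fx$rearrangements,
                         data.frame(id = names(fx$germline),
                                    nt_sequence = unname(fx$germline)),
                         fx$clinical, min_overlap = 10)
  rep_ <- ttft_report(cohort, "status")
  expect_setequal(rep_$strata$stratum, c("unmutated", "mutated"))
  expect_equal(sum(rep_$strata$n), 12)
  expect_true(!is.null(rep_$pairwise))
  expect_equal(dim(rep_$pairwise$p_value), c(2L, 2L))

  # within-group comparison via subset
  rep_low <- ttft_report(cohort, "status",
                         subset = cohort$ratio_group == "low")
  expect_equal(sum(rep_low$strata$n), 3)

  # empty-stratum warning for unused factor levels
  expect_warning(ttft_report(cohort, "mutation_bin"), "omitted")

  expect_equal(format_p(c(0.5, 2e-5)), c("0.5", "< 0.0001"))
})
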