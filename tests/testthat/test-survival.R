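test_that("Kaplan-Meier estimator matches the hand-computed worked fixture", {
  # 6 subjects: event 1, censor 2+, events 3, 4, 4, censor 5+
  time <- c(1, 2, 3, 4, 4, 5)
  event <- c(1, 0, 1, 1, 1, 0)
  cur <- km_curves(time, event)

  # hand product-limit: S(1)=5/6, S(3)=5/6*3/4=0.625, S(4)=0.625*1/3
  expect_equal(cur$surv[cur$time == 1], 5 / 6)
  expect_equal(cur$surv[cur$time == 3], 5 / 6 * 3 / 4)
  expect_equal(cur$surv[cur$time == 4], 5 / 6 * 3 / 4 * 1 / 3)
  expect_equal(cur$n_risk[cur$time == 4], 3)
  expect_equal(cur$surv[cur$time == 5], 5 / 6 * 3 / 4 * 1 / 3)

  # all censored: curve flat at 1, log-rank refuses
  flat <- km_curves(c(2, 3, 4), c(0, 0, 0))
  expect_true(all(flat$surv == 1))
  expect_error(km_logrank(c(2, 3, 4, 5), c(0, 0, 0, 0),
                          c("a", "a", "b", "b")), "no events")
  expect_error(km_logrank(time, event, rep("a", 6)), "two groups")

  # two identical groups: log-rank p ~ 1
  lr <- km_logrank(rep(time, 2), rep(event, 2), rep(c("a", "b"), each = 6))
  expect_gt(lr$test$p_value, 0.99)
  expect_identical(lr$test$df, 1L)
})

test_that("log-rank detects a strong simulated group effect", {
  set.seed(21)
  n <- 500
  grp <- rep(c(0, 1), each = n / 2)
  t_ev <- rexp(n, 0.001 * ifelse(grp == 1, 3, 1))
  t_c <- rexp(n, 0.001)
  lr <- km_logrank(pmin(t_ev, t_c), as.integer(t_ev <= t_c), grp)
  expect_lt(lr$test$p_value, 1e-6)
})

test_that("Cox fit recovers a known hazard ratio and rejects bad input", {
  set.seed(5)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.001 * exp(log(1.8) * x))
  t_c <- rexp(n, 0.0012)
  time <- pmin(t_ev, t_c); event <- as.integer(t_ev <= t_c)

  fit <- cox_fit(time, event, data.frame(x = x))
  hr <- fit$coefficients$hazard_ratio
  expect_gt(hr, 1.6); expect_lt(hr, 2.0)
  expect_equal(hr, exp(fit$coefficients$coef))
  expect_true(fit$coefficients$ci95_low < hr & hr < fit$coefficients$ci95_high)
  expect_identical(fit$n_events, sum(event))

  expect_error(cox_fit(time, event, data.frame(z = rep(0, n))), "constant")
  # the under-determined warning fires even when the fit then degenerates
  expect_warning(
    tryCatch(cox_fit(1:8, c(0, 0, 0, 0, 0, 0, 1, 1),
                     data.frame(a = c(2, 1, 3, 1, 2, 3, 1, 1),
                                b = c(1, 2, 2, 3, 1, 2, 3, 3),
                                c = c(3, 2, 1, 2, 3, 1, 2, 2))),
             error = function(e) NULL),
    "fewer events")

  # Breslow ties give a (slightly) different partial likelihood with ties
  tt <- round(time[1:300]); ev <- event[1:300]
  f1 <- cox_fit(tt, ev, data.frame(x = x[1:300]), ties = "efron")
  f2 <- cox_fit(tt, ev, data.frame(x = x[1:300]), ties = "breslow")
  expect_false(identical(f1$coefficients$coef, f2$coefficients$coef))
})

test_that("Harrell's C equals the O(n^2) pairwise oracle", {
  # perfect risk ordering, no censoring -> C = 1
  expect_equal(harrell_c(c(4, 3, 2, 1), rep(1, 4), c(1, 2, 3, 4)), 1)
  # constant risk scores -> C = 1/2
  expect_equal(harrell_c(c(4, 3, 2, 1), rep(1, 4), rep(2, 4)), 0.5)

  set.seed(33)
  for (i in 1:5) {
    n <- sample(15:50, 1)
    time <- round(rexp(n, 0.01), 6)       # continuous, no ties
    event <- rbinom(n, 1, 0.6)
    risk <- sample(1:5, n, replace = TRUE) # risk ties exercised
    if (sum(event) == 0) event[1] <- 1L
    expect_equal(harrell_c(time, event, risk),
                 oracle_harrell_c(time, event, risk),
                 tolerance = 1e-12)
  }
})

test_that("model metrics and comparison reproduce AIC/BIC arithmetic", {
  set.seed(9)
  n <- 300
  x <- rbinom(n, 1, 0.5); z <- rnorm(n)
  t_ev <- rexp(n, 0.002 * exp(0.6 * x + 0.3 * z))
  t_c <- rexp(n, 0.002)
  time <- pmin(t_ev, t_c); event <- as.integer(t_ev <= t_c)

  fit1 <- cox_fit(time, event, data.frame(x = x))
  fit2 <- cox_fit(time, event, data.frame(x = x, z = z))
  m1 <- model_metrics(fit1); m2 <- model_metrics(fit2)

  ll1 <- fit1$loglik[2]
  expect_equal(m1$aic, -2 * ll1 + 2 * 1)
  expect_equal(m1$bic, -2 * ll1 + 1 * log(fit1$n_events))
  expect_equal(model_metrics(fit1, bic_n = "n")$bic,
               -2 * ll1 + 1 * log(fit1$n))
  # C from the fit equals the standalone risk-score concordance
  expect_equal(m2$harrell_c,
               harrell_c(time, event,
                         predict(fit2$model, type = "lp")),
               tolerance = 1e-9)

  cmp <- compare_models(fit1, fit2)
  expect_equal(cmp$delta_bic, m1$bic - m2$bic)
  expect_identical(cmp$evidence_label, bic_evidence_label(cmp$delta_bic))
})

test_that("Kass-Raftery evidence bands label BIC differences", {
  expect_identical(bic_evidence_label(0.5), "none")
  expect_identical(bic_evidence_label(5), "positive")
  expect_identical(bic_evidence_label(-7), "strong")
  expect_identical(bic_evidence_label(13.443), "very_strong")
})
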