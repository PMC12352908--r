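library(survival)

test_that("Kaplan-Meier product-limit on tiny hand cases", {
  cv <- km_curve(c(1, 2), c(1, 1))
  expect_equal(cv$surv, c(0.5, 0))
  expect_equal(cv$n_risk, c(2, 1))

  all_cens <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(all_cens), 0L)
  expect_equal(km_surv(all_cens, 2.5), 1)

  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
  expect_error(km_curve(c(1, 2), c(1, 2)), "0/1")
})

test_that("KM agrees with survfit and is order/censoring stable", {
  withr::with_seed(30, {
    t <- rexp(80, 0.1); c_ <- rexp(80, 0.05)
    time <- pmin(t, c_); event <- as.integer(t <= c_)
    cv <- km_curve(time, event)
    sf <- summary(survfit(Surv(time, event) ~ 1), times = cv$time)
    expect_equal(cv$surv, sf$surv, tolerance = 1e-12)
    expect_equal(cv$se, sf$std.err, tolerance = 1e-6)
    # record order invariance
    perm <- sample(length(time))
    cv2 <- km_curve(time[perm], event[perm])
    expect_equal(cv, cv2)
    # a subject censored before the first event enters no risk set,
    # so the curve is unchanged
    cv3 <- km_curve(c(time, min(cv$time) / 2), c(event, 0))
    expect_equal(cv3$surv, cv$surv)
  })
})

test_that("KM tracks the exponential closed form within Greenwood error", {
  withr::with_seed(31, {
    lam <- 0.08
    t <- rexp(1000, lam); c_ <- rexp(1000, 0.02)
    time <- pmin(t, c_); event <- as.integer(t <= c_)
    cv <- km_curve(time, event)
    for (q in quantile(time[event == 1], c(0.25, 0.5, 0.75))) {
      i <- max(which(cv$time <= q))
      expect_lt(abs(cv$surv[i] - exp(-lam * cv$time[i])), 3 * cv$se[i])
    }
  })
})

test_that("log-rank statistic agrees with survdiff and handles K groups", {
  withr::with_seed(32, {
    time <- c(rexp(60, 0.1), rexp(60, 0.2))
    event <- rbinom(120, 1, 0.8)
    grp <- rep(c("a", "b"), each = 60)
    lr <- logrank_test(time, event, grp)
    sd_ <- survdiff(Surv(time, event) ~ grp)
    expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-9)
    expect_equal(lr$df, 1)

    # identical groups: statistic 0
    lr0 <- logrank_test(rep(time[1:30], 2), rep(event[1:30], 2),
                        rep(c("a", "b"), each = 30))
    expect_equal(lr0$statistic, 0, tolerance = 1e-12)
    expect_equal(lr0$p.value, 1)

    # three groups
    time3 <- rexp(90, 0.1); event3 <- rbinom(90, 1, 0.9)
    grp3 <- rep(c("a", "b", "c"), each = 30)
    lr3 <- logrank_test(time3, event3, grp3)
    sd3 <- survdiff(Surv(time3, event3) ~ grp3)
    expect_equal(lr3$statistic, sd3$chisq, tolerance = 1e-9)
    expect_equal(lr3$df, 2)

    # invariance under common time rescaling
    lr_s <- logrank_test(time * 7.3, event, grp)
    expect_equal(lr_s$statistic, lr$statistic, tolerance = 1e-12)
  })
  expect_error(logrank_test(1:5, rep(1, 5), rep("a", 5)), "two groups")
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "no events")
})

test_that("small-sample log-rank p is consistent with a permutation oracle", {
  time <- c(1.1, 2.3, 3.7, 4.1, 5.9, 6.4, 7.8, 9.2)
  event <- rep(1L, 8)
  grp <- c("a", "a", "a", "a", "b", "b", "b", "b")
  obs <- logrank_test(time, event, grp)$statistic
  withr::with_seed(33, {
    perm_stats <- replicate(4000, {
      g <- sample(grp)
      logrank_test(time, event, g)$statistic
    })
  })
  p_perm <- mean(perm_stats >= obs - 1e-12)
  p_asym <- logrank_test(time, event, grp)$p.value
  expect_lt(abs(p_perm - p_asym), 0.05)
})

test_that("Cox fit matches coxph under both tie conventions", {
  withr::with_seed(34, {
    n <- 150
    x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
    t <- rexp(n, 0.1 * exp(0.6 * x1 - 0.3 * x2))
    c_ <- rexp(n, 0.03)
    time <- round(pmin(t, c_), 1)   # induce ties
    event <- as.integer(t <= c_)
    X <- cbind(x1 = x1, x2 = x2)
    for (ties in c("efron", "breslow")) {
      fit <- cox_ph_fit(time, event, X, ties = ties)
      ref <- coxph(Surv(time, event) ~ x1 + x2, ties = ties)
      expect_equal(unname(fit$coefficients), unname(coef(ref)),
                   tolerance = 1e-6)
      expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                   tolerance = 1e-6)
      expect_equal(unname(fit$loglik["final"]), ref$loglik[2],
                   tolerance = 1e-6)
    }
  })
})

test_that("Cox score test at beta = 0 equals the log-rank chi-square without ties", {
  withr::with_seed(35, {
    n <- 120
    grp <- rbinom(n, 1, 0.5)
    time <- rexp(n, 0.1 * exp(0.5 * grp))  # continuous: no ties
    event <- rbinom(n, 1, 0.85)
    fit <- cox_ph_fit(time, event, cbind(g = grp))
    lr <- logrank_test(time, event, grp)
    expect_equal(fit$score_test$statistic, lr$statistic, tolerance = 1e-9)
  })
})

test_that("degenerate Cox inputs are diagnosed", {
  # identical groups: coefficient is zero
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- rep(1L, 8)
  x <- rep(c(0, 1), each = 4)
  fit <- cox_ph_fit(time, event, cbind(g = x))
  expect_lt(abs(fit$coefficients), 1e-8)

  # complete separation: all events in one arm, monotone likelihood
  t2 <- c(1, 2, 3, 4, 10, 11, 12, 13)
  e2 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x2 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_error(cox_ph_fit(t2, e2, cbind(sep = x2)), "separation")

  # collinear covariates
  x3 <- rbinom(20, 1, 0.5)
  expect_error(cox_ph_fit(rexp(20), rep(1, 20),
                          cbind(a = x3, b = 2 * x3)), "collinear")
  expect_error(cox_ph_fit(1:4, rep(0, 4), cbind(x = 1:4)), "no events")
})

test_that("planted hazard ratios are recovered on simulated cohorts", {
  withr::with_seed(36, {
    errs <- replicate(10, {
      n <- 800
      x <- rbinom(n, 1, 0.5)
      t <- rexp(n, 0.05 * exp(0.7 * x))
      c_ <- rexp(n, 0.0125)
      fit <- cox_ph_fit(pmin(t, c_), as.integer(t <= c_), cbind(x = x))
      fit$coefficients - 0.7
    })
    expect_lt(abs(median(errs)), 0.1)
  })
})

test_that("the interaction model structure is estimable on cohort output", {
  cohort <- simulate_cohort(n_samples = 250, seed = 37)
  status <- cohort_status_table(cohort)
  surv <- cohort_survival_analysis(cohort, status)
  expect_s3_class(surv$logrank, "cs_test")
  if (!is.null(surv$cox)) {
    expect_named(surv$cox$coefficients, c("ERCC2", "TP53", "interaction"))
    expect_true(all(surv$cox$hazard_ratios > 0))
  }
  expect_true(all(diff(surv$km$surv[surv$km$group == surv$km$group[1]]) <= 0))
})
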