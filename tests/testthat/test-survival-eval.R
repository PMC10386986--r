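test_that("C-index hits its bounds on fully ordered data", {
  expect_equal(as.numeric(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))), 1)
  expect_equal(as.numeric(c_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1))), 0)
  expect_error(c_index(c(1, 2), c(5, 5), c(0, 0)), "no usable pairs|undefined")
})

test_that("C-index equals the O(n^2) pairwise oracle under censoring", {
  for (seed in 1:8) {
    d <- random_surv(50, seed, tie_prob = if (seed %% 2) 0.5 else 0)
    expect_equal(as.numeric(c_index(d$scores, d$times, d$events)),
                 brute_cindex(d$scores, d$times, d$events))
  }
})

test_that("negating tie-free scores reflects the C-index", {
  d <- random_surv(40, 31)
  ci <- as.numeric(c_index(d$scores, d$times, d$events))
  expect_equal(as.numeric(c_index(-d$scores, d$times, d$events)), 1 - ci)
})

test_that("C-index agrees with the survival package concordance", {
  d <- random_surv(80, 12)
  ours <- as.numeric(c_index(d$scores, d$times, d$events))
  ref <- survival::concordance(
    survival::Surv(d$times, as.numeric(d$events)) ~ d$scores,
    reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("bootstrap CI brackets the point estimate deterministically", {
  d <- random_surv(60, 77)
  c1 <- c_index(d$scores, d$times, d$events, ci = TRUE, n_boot = 200,
                seed = 5)
  c2 <- c_index(d$scores, d$times, d$events, ci = TRUE, n_boot = 200,
                seed = 5)
  expect_identical(attr(c1, "ci"), attr(c2, "ci"))
  expect_lte(attr(c1, "ci")[[1]], as.numeric(c1))
  expect_gte(attr(c1, "ci")[[2]], as.numeric(c1))
})

test_that("Kaplan-Meier matches the product-limit arithmetic", {
  km <- km_estimate(c(5, 8, 10, 12), c(1, 0, 0, 0))
  expect_equal(pathomics:::km_surv_at(km, 5), 0.75)
  # no censoring: KM equals the empirical survival function
  set.seed(4)
  t <- sample(1:30, 15, replace = TRUE)
  km2 <- km_estimate(t, rep(1, 15))
  for (tt in sort(unique(t))) {
    expect_equal(pathomics:::km_surv_at(km2, tt), mean(t > tt))
  }
})

test_that("log-rank matches both a hand summation and survdiff", {
  expect_equal(logrank(c(1, 2, 3), c(1, 0, 1),
                       c(1, 2, 3), c(1, 0, 1))$statistic, 0)
  for (seed in 1:6) {
    set.seed(seed)
    ta <- sample(1:12, 10, replace = TRUE); ea <- rbinom(10, 1, 0.7)
    tb <- sample(1:12, 10, replace = TRUE); eb <- rbinom(10, 1, 0.5)
    if (sum(ea) + sum(eb) == 0) next
    lr <- logrank(ta, ea, tb, eb)
    expect_equal(lr$statistic, brute_logrank(ta, ea, tb, eb),
                 tolerance = 1e-12)
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, each = 10))
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
    expect_equal(lr$p_value, pchisq(sd$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  expect_error(logrank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
})

test_that("time-dependent AUC is exact on toys and calibrated under null", {
  # perfectly separating scores
  scores <- c(5, 4, 3, 2, 1, 0)
  times <- c(2, 4, 6, 20, 25, 30)
  events <- c(1, 1, 1, 0, 0, 0)
  td <- td_roc(scores, times, events, horizons = c(10))
  expect_equal(td$auc, 1)
  # six-patient toy equals exhaustive case-control pair counting
  set.seed(9)
  s <- rnorm(6); t <- c(1, 3, 5, 9, 11, 14); e <- c(1, 0, 1, 1, 0, 1)
  td2 <- td_roc(s, t, e, horizons = 8)
  case <- e == 1 & t <= 8; ctrl <- t > 8
  expect_equal(td2$auc, brute_auc(c(s[case], s[ctrl]),
                                  c(rep(TRUE, sum(case)),
                                    rep(FALSE, sum(ctrl)))))
  # chance level for uninformative scores
  set.seed(10)
  n <- 500
  tt <- rexp(n, 0.1); ee <- runif(n) < 0.8; ss <- rnorm(n)
  td3 <- td_roc(ss, tt, ee, horizons = median(tt))
  expect_lt(abs(td3$auc - 0.5), 0.06)
  # horizons with no cases are reported absent
  td4 <- td_roc(scores, times, events, horizons = 1)
  expect_true(is.na(td4$auc))
})

test_that("calibration recovers simulated risks and degenerates gracefully", {
  set.seed(11)
  n <- 1000
  horizon <- 12
  p <- runif(n, 0.05, 0.95)
  times <- rexp(n, rate = -log(1 - p) / horizon)
  events <- rep(1, n)
  cal <- calibration(p, times, events, horizon, n_bins = 4)
  expect_lt(max(abs(cal$predicted - cal$observed)), 0.1)
  # constant predictions: single effective bin at the cohort event rate
  cal2 <- calibration(rep(0.3, 50), times[1:50], events[1:50], horizon)
  expect_identical(nrow(cal2), 1L)
  expect_equal(cal2$observed,
               1 - pathomics:::km_surv_at(km_estimate(times[1:50],
                                                      events[1:50]),
                                          horizon))
})

test_that("Cox fits recover effects and reject collinearity", {
  set.seed(12)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  times <- rexp(n, 0.05 * exp(1.0 * x))
  cens <- rexp(n, 0.03)
  f <- cox_fit(data.frame(x = x), pmin(times, cens), times <= cens)
  expect_lt(abs(f$table$beta - 1.0), 0.25)
  expect_true(f$table$ci_lower <= f$table$hr &
                f$table$hr <= f$table$ci_upper)
  expect_error(cox_fit(data.frame(a = x, b = x), pmin(times, cens),
                       times <= cens), "collinear")
})

test_that("the Cox score test equals the log-rank statistic on tie-free data", {
  set.seed(13)
  n <- 40
  x <- rep(0:1, each = n / 2)
  times <- rexp(n, 0.1 * exp(0.8 * x)) + cumsum(rep(1e-6, n))  # tie-free
  events <- rep(1, n)
  fit <- survival::coxph(survival::Surv(times, events) ~ x,
                         data = data.frame(times, events, x))
  lr <- logrank(times[x == 1], events[x == 1],
                times[x == 0], events[x == 0])
  expect_equal(unname(summary(fit)$sctest["test"]), lr$statistic,
               tolerance = 1e-6)
})

test_that("univariate screening feeds the multivariate model", {
  set.seed(14)
  n <- 300
  good <- rnorm(n); junk <- rnorm(n)
  times <- rexp(n, 0.05 * exp(0.9 * good))
  cens <- rexp(n, 0.03)
  res <- cox_screen(data.frame(good = good, junk = junk),
                    pmin(times, cens), times <= cens)
  expect_true("good" %in% res$selected)
  expect_false("junk" %in% res$selected)
  expect_s3_class(res$multivariate$fit, "coxph")
})
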