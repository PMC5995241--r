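test_that("Kaplan-Meier matches hand product-limit results", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring at t = 2: S(1) = 2/3 and no further drop until 3
  km2 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(survival_at(km2, 1), 2 / 3)
  expect_equal(survival_at(km2, 2), 2 / 3)
  expect_equal(survival_at(km2, 3), 0)
  expect_equal(survival_at(km2, 0.5), 1)
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("without censoring the KM curve is the empirical survival function", {
  set.seed(31)
  t <- round(rexp(40, 0.1), 1)
  km <- km_estimate(t, rep(TRUE, 40))
  for (q in c(2, 5, 10, 20))
    expect_equal(survival_at(km, q), mean(t > q))
})

test_that("survival_at(96) reads the 8-year step", {
  km <- km_estimate(c(50, 90, 100), c(TRUE, TRUE, TRUE))
  expect_equal(survival_at(km, 96), 1 / 3)
})

test_that("log-rank statistic matches the O-E tabulation oracle", {
  g <- list(a = list(times = c(1, 2), events = c(TRUE, TRUE)),
            b = list(times = c(3, 4), events = c(TRUE, TRUE)))
  lr <- logrank_test(g)
  expect_equal(lr$statistic,
               logrank_oracle(c(1, 2), c(1, 1), c(3, 4), c(1, 1)),
               tolerance = 1e-12)
  expect_equal(lr$df, 1)
  set.seed(7)
  for (i in 1:10) {
    t1 <- rexp(20, 0.1); t2 <- rexp(25, 0.15)
    e1 <- runif(20) < 0.8; e2 <- runif(25) < 0.8
    lr2 <- logrank_test(list(list(times = t1, events = e1),
                             list(times = t2, events = e2)))
    expect_equal(lr2$statistic, logrank_oracle(t1, e1, t2, e2),
                 tolerance = 1e-8)
  }
})

test_that("identical groups give statistic 0, p = 1; empty groups error", {
  g <- list(times = c(2, 5, 9), events = c(TRUE, FALSE, TRUE))
  lr <- logrank_test(list(a = g, b = g))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1)
  expect_error(logrank_test(list(a = g, b = list(times = numeric(0),
                                                 events = logical(0)))),
               "n = 0")
})

test_that("Cox fit matches the brute-force partial-likelihood grid on tiny data", {
  set.seed(12)
  for (i in 1:5) {
    n <- 8
    z <- rep(c(0, 1), 4)
    t <- round(rexp(n, 0.1 * exp(0.7 * z)), 3)  # continuous: no ties
    d <- data.frame(z = z, os_time = t, os_event = TRUE)
    fit <- cox_fit(d, "z", endpoint = "os")
    expect_equal(fit$table$coef, cox_grid_mle(t, rep(1, n), z),
                 tolerance = 1e-3)
  }
})

test_that("Cox recovers a known hazard ratio and reports Wald intervals", {
  set.seed(9)
  n <- 1000
  z <- rbinom(n, 1, 0.4)
  t <- rexp(n, 0.02 * 2^z)
  cens <- pmin(rexp(n, 0.004), 120)
  d <- data.frame(z = z, dss_time = pmin(t, cens), dss_event = t <= cens)
  fit <- cox_fit(d, "z", endpoint = "dss")
  expect_gt(fit$table$hr, 1.8); expect_lt(fit$table$hr, 2.2)
  expect_true(fit$table$ci_lo <= fit$table$hr & fit$table$hr <= fit$table$ci_hi)
  expect_equal(fit$table$ci_hi / fit$table$hr,
               exp(1.96 * fit$table$se), tolerance = 1e-10)
})

test_that("degenerate Cox inputs raise informative errors", {
  d <- data.frame(z = rep(1, 20), os_time = rexp(20), os_event = TRUE)
  expect_error(cox_fit(d, "z", "os"), "constant covariate")
  d2 <- data.frame(z = rbinom(20, 1, 0.5), os_time = rexp(20), os_event = FALSE)
  expect_error(cox_fit(d2, "z", "os"), "zero events")
  # complete separation: all events in one arm, monotone likelihood
  d3 <- data.frame(z = rep(c(1, 0), each = 10),
                   os_time = c(1:10, 101:110),
                   os_event = rep(c(TRUE, FALSE), each = 10))
  expect_error(cox_fit(d3, "z", "os"), "monotone|penali")
})

test_that("forward selection enters the truly associated covariate first", {
  set.seed(20)
  hits <- vapply(1:10, function(i) {
    n <- 500
    z <- rbinom(n, 1, 0.4)
    noise <- matrix(rbinom(3 * n, 1, 0.5), n)
    t <- rexp(n, 0.02 * 3^z)
    cens <- pmin(rexp(n, 0.004), 120)
    d <- data.frame(z = z, n1 = noise[, 1], n2 = noise[, 2], n3 = noise[, 3],
                    dss_time = pmin(t, cens), dss_event = t <= cens)
    fit <- cox_fit(d, c("n1", "n2", "z", "n3"), "dss", selection = "forward")
    nrow(fit$trace) >= 1 && fit$trace$term[1] == "z"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the log-rank test agrees with the Cox score test on two groups", {
  set.seed(40)
  diffs <- replicate(30, {
    n <- 120
    z <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.02 * 1.3^z)
    cens <- pmin(rexp(n, 0.005), 120)
    ti <- pmin(t, cens); ev <- t <= cens
    lr <- logrank_test(split(data.frame(times = ti, events = ev), z))$p.value
    sc <- mibcSubtyper:::cox_score_p(
      data.frame(z = z, tt = ti, ee = as.integer(ev)), "tt", "ee",
      character(0), "z", "efron")
    abs(lr - sc)
  })
  expect_lt(median(diffs), 0.01)
})

test_that("covariate encoding applies the standard dichotomizations", {
  co <- generate_cohort(simulation_config(n_samples = 30, seed = 14))
  cl <- co$clinical
  cov <- encode_covariates(cl)
  expect_equal(cov$stage_t34, as.integer(cl$stage %in% c("pT3", "pT4")))
  expect_equal(cov$node_pos, as.integer(cl$node == "N+"))
  expect_equal(cov$sex_m, as.integer(cl$sex == "M"))
})
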