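test_that("null fit with no covariates reproduces the Nelson-Aalen closed form", {
  ch <- cohort(data.frame(time = c(1, 2, 3), status = c(1, 1, 1)))
  fit <- cox_null(ch)
  expect_equal(fit$cum_baseline$jump, c(1 / 3, 1 / 2, 1))
  expect_equal(fit$cum_baseline$hazard, cumsum(c(1 / 3, 1 / 2, 1)))
  expect_equal(fit$residuals, c(2 / 3, 1 / 6, -5 / 6))
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-12)
})

test_that("an all-censored cohort has zero hazard and zero residuals", {
  ch <- cohort(data.frame(time = 1:4, status = rep(0, 4)))
  fit <- cox_null(ch)
  expect_equal(nrow(fit$cum_baseline), 0)
  expect_equal(fit$residuals, rep(0, 4))
})

test_that("covariate coefficient matches a brute-force partial-likelihood grid", {
  withr::with_seed(7, {
    time <- c(1.1, 2.3, 3.2, 4.8, 6.4)
    status <- c(1, 1, 1, 1, 1)
    x <- c(1, 0, 1, 0, 0)
  })
  d <- data.frame(time = time, status = status, z1 = x)
  fit <- cox_null(cohort(d, covariates = "z1"))
  expect_equal(unname(fit$gamma_hat), grid_cox_1d(time, status, x),
               tolerance = 1e-3)
})

test_that("residuals match survival::coxph martingale residuals", {
  ch <- random_cohort(n = 60, q_cov = 2, seed = 42)
  fit <- cox_null(ch)
  ref <- survival::coxph(
    survival::Surv(time, status) ~ z1 + z2, data = as.data.frame(ch),
    ties = "breslow")
  expect_equal(unname(fit$gamma_hat), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$residuals,
               unname(residuals(ref, type = "martingale")),
               tolerance = 1e-6)
})

test_that("martingale residual invariants hold on random cohorts", {
  for (s in 1:50) {
    q <- s %% 3  # cycle through 0, 1, 2 covariates
    ch <- random_cohort(n = 25 + s %% 7, q_cov = q, seed = s)
    fit <- cox_null(ch)
    expect_lt(abs(sum(fit$residuals)), 1e-8)
    expect_true(all(fit$residuals <= 1))
    expect_true(all(fit$residuals[ch$status == 0] <= 0))
    expect_gte(fit$loglik, fit$loglik_null - 1e-10)
    if (q == 0) {
      # with no covariates, residuals equal delta - NelsonAalen(T) exactly
      na <- coxmdr:::cum_hazard_at(fit$cum_baseline, ch$time)
      expect_equal(fit$residuals, ch$status - na)
    }
  }
})

test_that("degenerate inputs fail loudly", {
  d <- data.frame(time = 1:4, status = rep(0, 4), z1 = rnorm(4))
  expect_error(cox_null(cohort(d, covariates = "z1")), "no events")

  # perfectly separating covariate: all events in one group, early
  d2 <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                   status = c(1, 1, 1, 0, 0, 0),
                   z1 = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_null(cohort(d2, covariates = "z1")),
               "monotone likelihood")

  withr::with_seed(5, {
    z1 <- rnorm(20)
    d3 <- data.frame(time = rexp(20), status = rbinom(20, 1, 0.7),
                     z1 = z1, z2 = 2 * z1)
  })
  expect_error(cox_null(cohort(d3, covariates = c("z1", "z2"))),
               "collinear")
})

test_that("cohort validation names offenders", {
  d <- data.frame(id = c("a", "b"), time = c(-1, 2), status = c(1, 0))
  expect_error(validate_cohort(cohort(d)), "a")
  d2 <- data.frame(id = c("a", "b"), time = c(1, 2), status = c(1, 2))
  expect_error(validate_cohort(cohort(d2)), "status")
  d3 <- data.frame(id = c("a", "a"), time = c(1, 2), status = c(1, 0))
  expect_error(validate_cohort(cohort(d3)), "duplicated")
})
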