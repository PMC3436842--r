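test_that("simulated cohorts respect the stated design", {
  m <- penetrance_model(0.2, 0.2, seed = 1)
  ch <- simulate_cohort(m, seed = 2)
  truth <- cohort_truth(ch)
  expect_equal(nrow(ch), 400)
  expect_equal(sum(truth$x), 200)
  expect_equal(length(snp_cols(ch)), 10)
  expect_true(all(ch$time > 0 & ch$time <= 4))
  expect_equal(length(truth$causal), 2)
  expect_no_error(validate_cohort(ch))
  # deterministic given the seed
  ch2 <- simulate_cohort(m, seed = 2)
  expect_equal(as.data.frame(ch), as.data.frame(ch2))
})

test_that("null loci match HWE proportions (chi-square GOF, alpha = 0.01)", {
  m <- penetrance_model(0.3, 0.2, seed = 3)
  cfg <- sim_config(n_high = 5000, n_low = 5000)
  ch <- simulate_cohort(m, cfg, seed = 4)
  truth <- cohort_truth(ch)
  w <- coxmdr:::hwe_probs(0.3)
  null_cols <- setdiff(seq_along(snp_cols(ch)), truth$causal)
  g <- snp_matrix(ch)
  pvals <- vapply(null_cols, function(j) {
    obs <- tabulate(g[, j] + 1L, 3)
    suppressWarnings(stats::chisq.test(obs, p = w)$p.value)
  }, 0)
  expect_gt(min(pvals), 0.01 / length(null_cols))  # Bonferroni at alpha 0.01
})

test_that("the Cox fit on the true risk status recovers beta = 1", {
  m <- penetrance_model(0.2, 0.3, seed = 5)
  ests <- vapply(1:40, function(s) {
    ch <- simulate_cohort(m, seed = 100 + s)
    x <- cohort_truth(ch)$x
    fit <- survival::coxph(survival::Surv(ch$time, ch$status) ~ x,
                           ties = "breslow")
    unname(coef(fit))
  }, 0)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1), 3 * se + 0.02)
})

test_that("high-risk subjects die earlier: KM curve ordering", {
  m <- penetrance_model(0.2, 0.3, seed = 6)
  cfg <- sim_config(n_high = 2000, n_low = 2000)
  ch <- simulate_cohort(m, cfg, seed = 7)
  x <- cohort_truth(ch)$x
  fit <- survival::survfit(survival::Surv(ch$time, ch$status) ~ x)
  qs <- c(0.5, 1, 1.5, 2)
  surv_at <- function(grp, t) summary(fit[grp], times = t, extend = TRUE)$surv
  # x = 0 (first stratum) must lie above x = 1 at every printed quantile
  expect_true(all(surv_at(1, qs) >= surv_at(2, qs)))
})

test_that("a penetrance of zero everywhere makes the quota unreachable", {
  m <- penetrance_model(0.2, 0.2, seed = 1)
  m$f[] <- 0
  expect_error(simulate_cohort(m, sim_config(n_high = 10, n_low = 10),
                               seed = 1, max_batches = 3),
               "quota unreachable")
})
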