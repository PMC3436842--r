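test_that("single-SNP coefficient matches a brute-force grid oracle", {
  withr::with_seed(11, {
    time <- sort(rexp(6)) + 0.1
    g <- c(0, 1, 2, 0, 1, 2)
  })
  d <- data.frame(time = time, status = rep(1, 6), SNP1 = g)
  ch <- cohort(d)
  res <- cox_snp_test(ch, "SNP1", covariates = character(0))
  expect_equal(res$estimate, grid_cox_1d(time, rep(1, 6), g),
               tolerance = 1e-3)
})

test_that("single-SNP fit recovers a log hazard ratio of 1 at large n", {
  n <- 5000
  withr::with_seed(21, {
    g <- sample(0:2, n, replace = TRUE, prob = c(.49, .42, .09))
    t_ev <- rexp(n, exp(1 * g))
    c_ev <- runif(n, 0, 2)
  })
  d <- data.frame(time = pmin(t_ev, c_ev), status = as.integer(t_ev <= c_ev),
                  SNP1 = g)
  res <- cox_snp_test(cohort(d), "SNP1")
  expect_lt(abs(res$estimate - 1), 3 * res$std.error)
})

test_that("collinear and constant SNPs fail explicitly", {
  d <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 1, 0),
                  age = c(0, 1, 2, 0), SNP1 = c(0, 1, 2, 0),
                  SNP2 = c(1, 1, 1, 1))
  ch <- cohort(d, covariates = "age")
  expect_error(cox_snp_test(ch, "SNP1", covariates = "age"), "collinear")
  expect_error(cox_snp_test(ch, "SNP2"), "constant")
})

test_that("subjects missing the tested genotype are excluded", {
  d <- data.frame(time = c(1, 2, 3, 4, 5), status = c(1, 1, 1, 1, 0),
                  SNP1 = c(0, 1, NA, 2, 1))
  res <- cox_snp_test(cohort(d), "SNP1", covariates = character(0))
  expect_equal(res$n_used, 4)
})

test_that("cox_screen records failures without aborting and ranks by p", {
  ch <- random_cohort(n = 50, m_snps = 4, q_cov = 1, seed = 5)
  d <- as.data.frame(ch)
  d$SNP4 <- 1  # constant
  ch2 <- cohort(d, covariates = "z1")
  scr <- cox_screen(ch2)
  expect_equal(nrow(scr), 4)
  expect_true(any(!is.na(scr$note)))
  ok <- !is.na(scr$p.value)
  expect_false(is.unsorted(scr$p.value[ok]))
  expect_true(all(scr$fdr[ok] >= scr$p.value[ok]))
})

test_that("BH adjustment is a valid step-up in a wider family", {
  expect_equal(bh_fdr(0.03, m_total = 1), 0.03)
  # permutation invariance
  p <- c(0.04, 0.001, 0.02, 0.8, 0.001)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p, 10)[perm], bh_fdr(p[perm], 10))
  # adjusted values non-decreasing in rank order and >= raw p
  adj <- bh_fdr(p, 20)
  expect_true(all(adj >= p))
  expect_false(is.unsorted(adj[order(p)]))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, 0.2), m_total = 1), "m_total")
})
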