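test_that("per-cell labels match a literal survdiff-based oracle", {
  ch <- random_cohort(n = 40, m_snps = 2, q_cov = 0, seed = 51)
  labels <- survmdr_classify(ch, c(1, 2))
  cells <- assign_cells(ch, c(1, 2))
  for (cc in 0:8) {
    members <- !is.na(cells) & cells == cc
    if (!any(members) || all(members)) {
      expect_false(labels[cc + 1])
      next
    }
    sd <- survival::survdiff(
      survival::Surv(ch$time, ch$status) ~ members)
    oe <- sd$obs[2] - sd$exp[2]   # in-cell group
    expect_equal(unname(labels[cc + 1]), unname(oe > 0))
  }
})

test_that("a cell duplicating the complement's survival gets O-E = 0 -> low", {
  # cell members are exact copies of the outside group
  d <- data.frame(time = rep(c(1, 2, 3, 4), 2),
                  status = rep(c(1, 0, 1, 1), 2),
                  SNP1 = rep(c(0, 1), each = 4))
  ch <- cohort(d)
  labels <- survmdr_classify(ch, 1)
  oe <- attr(labels, "oe")
  expect_equal(oe[1], 0)
  expect_false(labels[1])  # tie -> low by the strict threshold
})

test_that("a cell holding all early deaths is labelled high", {
  d <- data.frame(time = c(0.1, 0.2, 0.3, 5, 6, 7),
                  status = c(1, 1, 1, 0, 0, 0),
                  SNP1 = c(0, 0, 0, 1, 1, 1))
  labels <- survmdr_classify(cohort(d), 1)
  expect_true(labels[1])
  expect_false(labels[2])
})

test_that("constant SNP combinations are flagged degenerate", {
  d <- data.frame(time = 1:6, status = rep(1, 6), SNP1 = rep(1, 6))
  labels <- survmdr_classify(cohort(d), 1)
  expect_true(attr(labels, "degenerate"))
})

test_that("covariates never influence Surv-MDR (mutation test)", {
  ch <- random_cohort(n = 50, m_snps = 3, q_cov = 1, seed = 55)
  d <- as.data.frame(ch)
  d2 <- d
  d2$z1 <- d2$z1 * 100 + 7  # radically different covariate
  ch1 <- cohort(d, covariates = "z1")
  ch2 <- cohort(d2, covariates = "z1")
  s1 <- mdr_search(ch1, k = 2, folds = 5, repeats = 2, seed = 5,
                   method = "survmdr")
  s2 <- mdr_search(ch2, k = 2, folds = 5, repeats = 2, seed = 5,
                   method = "survmdr")
  expect_equal(tidy(s1), tidy(s2))
})

test_that("the model score flips sign but keeps magnitude under label swap", {
  ch <- random_cohort(n = 40, m_snps = 2, q_cov = 0, seed = 57)
  high <- withr::with_seed(58, sample(c(TRUE, FALSE), 40, replace = TRUE))
  a <- survmdr_score(ch, high)
  b <- survmdr_score(ch, !high)
  expect_equal(abs(as.numeric(a)), abs(as.numeric(b)))
  expect_equal(as.numeric(a), -as.numeric(b))
})

test_that("one-sided groupings score zero with a degeneracy flag", {
  ch <- random_cohort(n = 20, m_snps = 2, q_cov = 0, seed = 59)
  s <- survmdr_score(ch, rep(TRUE, 20))
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
})

test_that("separating all events from all censored maximises excess deaths", {
  # the O-E excess-death count (not the variance-scaled chi-square, whose
  # variance shrinks faster than O-E for small high groups) is maximal for
  # the perfect event/censored split; checked by full enumeration
  d <- data.frame(time = c(0.5, 0.6, 0.7, 8, 9, 10),
                  status = c(1, 1, 1, 0, 0, 0), SNP1 = rep(0, 6))
  oe_of <- function(h) {
    coxmdr:::logrank_oe(d$time, d$status, as.integer(h), 2L)$oe[2]
  }
  perfect <- oe_of(c(rep(TRUE, 3), rep(FALSE, 3)))
  for (m in 1:62) {
    h <- as.logical(intToBits(m)[1:6])
    expect_lte(oe_of(h), perfect + 1e-12)
  }
  # and its signed chi-square score is large and positive
  expect_gt(as.numeric(survmdr_score(cohort(d), c(rep(TRUE, 3), rep(FALSE, 3)))),
            qchisq(0.95, 1))
})

test_that("each subject sits in exactly one in-cell group per combination", {
  ch <- random_cohort(n = 30, m_snps = 2, q_cov = 0, seed = 61)
  cells <- assign_cells(ch, c(1, 2))
  counts <- tabulate(cells + 1L, 9)
  # the with-genotype groups partition the sample; every complement has the
  # remaining n - n_c subjects, the overlap structure Surv-MDR relies on
  expect_equal(sum(counts), nrow(ch))
  expect_equal(counts + (nrow(ch) - counts), rep(nrow(ch), 9))
})

test_that("null attributes give a mean chi-square near 1", {
  stats <- vapply(1:200, function(s) {
    ch <- random_cohort(n = 40, m_snps = 1, q_cov = 0, seed = 700 + s)
    high <- withr::with_seed(900 + s,
                             sample(c(TRUE, FALSE), 40, replace = TRUE))
    abs(as.numeric(survmdr_score(ch, high)))
  }, 0)
  se <- sqrt(2 * 200) / 200  # SE of the mean of chi-square(1) draws
  expect_lt(abs(mean(stats) - 1), 3 * sqrt(stats::var(stats) / 200) + 3 * se)
})

test_that("fold splits are shared between methods for identical seeds", {
  f1 <- coxmdr:::make_folds(rep(c(0, 1), 20), 5, 2, seed = 123)
  f2 <- coxmdr:::make_folds(rep(c(0, 1), 20), 5, 2, seed = 123)
  expect_identical(f1, f2)
})
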