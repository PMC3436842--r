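test_that("cell assignment is base-3 over the tuple order", {
  g <- rbind(c(0, 0), c(2, 2), c(1, 0), c(0, 1), c(NA, 2))
  cells <- assign_cells(g, c(1, 2))
  expect_equal(cells, c(0L, 8L, 1L, 3L, NA))
  # k = 2 spans exactly 9 possible cells
  full <- as.matrix(expand.grid(0:2, 0:2))
  expect_equal(sort(assign_cells(full, c(1, 2))), 0:8)
  expect_error(assign_cells(g, c(1, 1)), "duplicate")
  expect_error(assign_cells(g, c(1, 3)), "range")
})

test_that("cells are labelled by the sign of the residual sum", {
  cells <- c(0L, 0L, 1L, 2L)
  # cell 0 sums to 0.3 -> high; cell 1 is exactly 0 -> high; cell 2 negative
  labels <- classify_cells(c(0.5, -0.2, 0, -0.1), cells, k = 1)
  expect_equal(labels, c(TRUE, TRUE, FALSE))
  # training-empty cells default to low risk
  labels2 <- classify_cells(c(1, 1), c(0L, 0L), k = 1)
  expect_equal(labels2, c(TRUE, FALSE, FALSE))
})

test_that("balanced accuracy reproduces the confusion-matrix definition", {
  # TP=4, FN=1, TN=3, FP=2 -> (0.8 + 0.6)/2 = 0.7
  pred <- c(rep(TRUE, 4), rep(FALSE, 1), rep(FALSE, 3), rep(TRUE, 2))
  case <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(as.numeric(balanced_accuracy(pred, case)), 0.7)
  expect_equal(as.numeric(balanced_accuracy(case, case)), 1)
  # constant predictor with both classes present
  ba <- balanced_accuracy(rep(TRUE, 10), case)
  expect_equal(as.numeric(ba), 0.5)
  expect_false(attr(ba, "degenerate"))
  # one class absent: absent term contributes 0, flagged
  ba2 <- balanced_accuracy(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_true(attr(ba2, "degenerate"))
  expect_equal(as.numeric(ba2), 0.25)
})

test_that("flipping every label maps balanced accuracy to 1 - BA", {
  withr::with_seed(9, {
    pred <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    case <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  })
  expect_equal(as.numeric(balanced_accuracy(!pred, case)),
               1 - as.numeric(balanced_accuracy(pred, case)))
})

test_that("cross-validated evaluation is deterministic given the seed", {
  ch <- random_cohort(n = 40, m_snps = 3, q_cov = 1, seed = 13)
  a <- mdr_evaluate(ch, c("SNP1", "SNP2"), folds = 5, repeats = 3, seed = 99)
  b <- mdr_evaluate(ch, c("SNP1", "SNP2"), folds = 5, repeats = 3, seed = 99)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(attr(a, "mean_test"), attr(b, "mean_test"))
})

test_that("leave-one-out evaluation ignores the seed", {
  ch <- random_cohort(n = 15, m_snps = 2, q_cov = 0, seed = 17)
  a <- mdr_evaluate(ch, 1:2, folds = 15, repeats = 1, seed = 1)
  b <- mdr_evaluate(ch, 1:2, folds = 15, repeats = 1, seed = 2)
  expect_equal(attr(a, "mean_test"), attr(b, "mean_test"))
})

test_that("fast CV path equals a literal loop-and-cell oracle", {
  for (s in 1:5) {
    ch <- random_cohort(n = 12 + s, m_snps = 3, q_cov = s %% 2, seed = 300 + s)
    fit <- cox_null(ch)
    cells <- assign_cells(ch, c(1, 3))
    fold_mat <- coxmdr:::make_folds(ch$status, folds = 2, repeats = 2,
                                    seed = 400 + s)
    fast <- coxmdr:::eval_combo_core(fit$residuals, cells, fold_mat, 9L)
    slow <- cv_oracle(fit$residuals, cells, fold_mat, k = 2)
    expect_equal(fast$train_ba, slow$train_ba)
    expect_equal(fast$test_ba, slow$test_ba)
  }
})

test_that("missing genotypes drop subjects from affected combinations only", {
  ch <- random_cohort(n = 20, m_snps = 3, q_cov = 0, seed = 23)
  d <- as.data.frame(ch)
  d$SNP1[1:3] <- NA
  ch2 <- cohort(d)
  cells <- assign_cells(ch2, c(1, 2))
  expect_true(all(is.na(cells[1:3])))
  expect_false(anyNA(assign_cells(ch2, c(2, 3))))
  # evaluation still works with the exclusions
  ev <- mdr_evaluate(ch2, 1:2, folds = 4, repeats = 1, seed = 1)
  expect_true(all(is.finite(ev$test_score) | is.na(ev$test_score)))
})

test_that("search ranking equals exhaustive independent re-computation", {
  ch <- random_cohort(n = 20, m_snps = 4, q_cov = 1, seed = 31)
  search <- mdr_search(ch, k = 2, folds = 4, repeats = 2, seed = 77)
  expect_equal(nrow(search), choose(4, 2))

  fit <- cox_null(ch)
  fold_mat <- coxmdr:::make_folds(ch$status, 4, 2, seed = 77)
  combos <- combn(4, 2, simplify = FALSE)
  oracle_means <- vapply(combos, function(ix) {
    cells <- assign_cells(ch, ix)
    mean(cv_oracle(fit$residuals, cells, fold_mat, 2)$test_ba, na.rm = TRUE)
  }, 0)
  labels <- vapply(combos, function(ix)
    paste(snp_cols(ch)[ix], collapse = ","), "")
  expect_equal(search$snps, labels[order(-oracle_means)])
  expect_equal(search$mean_test, sort(oracle_means, decreasing = TRUE))
})

test_that("a two-SNP cohort has a single candidate model", {
  ch <- random_cohort(n = 20, m_snps = 2, q_cov = 0, seed = 37)
  search <- mdr_search(ch, k = 2, folds = 4, repeats = 1, seed = 1)
  expect_equal(nrow(search), 1)
  expect_error(mdr_search(ch, k = 3), "fewer SNPs")
})

test_that("search is invariant to SNP column permutation up to relabeling", {
  ch <- random_cohort(n = 25, m_snps = 4, q_cov = 0, seed = 41)
  d <- as.data.frame(ch)
  perm_cols <- c("SNP3", "SNP1", "SNP4", "SNP2")
  d2 <- d[, c("id", "time", "status", perm_cols)]
  ch2 <- cohort(d2, snps = perm_cols)
  s1 <- mdr_search(ch, k = 2, folds = 5, repeats = 2, seed = 5)
  s2 <- mdr_search(ch2, k = 2, folds = 5, repeats = 2, seed = 5)
  norm <- function(s) {
    lab <- vapply(strsplit(s$snps, ","), function(x)
      paste(sort(x), collapse = ","), "")
    s$mean_test[order(lab)]
  }
  expect_equal(norm(s1), norm(s2))
})

test_that("per-fold residual recomputation is available and close to default", {
  ch <- random_cohort(n = 40, m_snps = 2, q_cov = 1, seed = 43)
  a <- mdr_evaluate(ch, 1:2, folds = 4, repeats = 1, seed = 3)
  b <- mdr_evaluate(ch, 1:2, folds = 4, repeats = 1, seed = 3,
                    recompute_residuals = TRUE)
  expect_equal(attr(b, "folds"), 4)
  expect_lt(abs(attr(a, "mean_train") - attr(b, "mean_train")), 0.25)
})
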