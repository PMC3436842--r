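#' Surv-MDR cell classification by per-cell log-rank
#'
#' The Surv-MDR classifier labels each genotype cell by a two-sample
#' log-rank comparison of the subjects *in* the cell against all subjects
#' outside it: the cell is high risk when the in-cell group shows strictly
#' more deaths than expected (`O - E > 0`), low risk otherwise (ties and
#' empty cells are low). Unlike Cox-MDR every subject enters the "without"
#' group of every cell it does not belong to, so individuals contribute to
#' many comparisons. No covariate adjustment is possible.
#'
#' @param data A [cohort()] (training subjects).
#' @param snps SNP names or indices forming the combination.
#' @return Logical vector of length `3^k` (`TRUE` = high risk) with
#'   attributes `oe` (per-cell observed minus expected) and `degenerate`
#'   (`TRUE` when one cell holds the entire sample, i.e. the k SNPs are
#'   constant).
#' @export
survmdr_classify <- function(data, snps) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  idx <- resolve_snps(data, snps)
  cells <- assign_cells(data, idx)
  survmdr_classify_core(data$time, data$status, cells, 3L^length(idx))
}

survmdr_classify_core <- function(time, status, cells, ncell) {
  keep <- !is.na(cells)
  time <- time[keep]
  status <- status[keep]
  cells <- cells[keep]
  if (sum(status) == 0) {
    stop("Surv-MDR classification needs at least one event", call. = FALSE)
  }
  counts <- tabulate(cells + 1L, ncell)
  degenerate <- any(counts == length(cells))
  oe <- numeric(ncell)
  occupied <- counts > 0 & counts < length(cells)
  res <- logrank_oe(time, status, cells, ncell)
  oe[occupied] <- res$oe[occupied]
  structure(oe > 0 & counts > 0 & !degenerate,
            oe = oe, degenerate = degenerate)
}

#' Signed log-rank score of a high/low attribute
#'
#' The Surv-MDR model score: the two-group log-rank chi-square statistic
#' between predicted-high and predicted-low subjects, signed by the
#' direction of `O - E` in the high group. Degenerate groupings (everyone on
#' one side, or zero log-rank variance) score 0 with a `degenerate`
#' attribute.
#'
#' @param data A [cohort()] (the subjects to score, e.g. a test fold).
#' @param high Logical, `TRUE` = predicted high risk; `NA` excluded.
#' @return Signed statistic (numeric scalar) with attribute `degenerate`.
#' @export
survmdr_score <- function(data, high) {
  stopifnot(inherits(data, "coxmdr_cohort"), length(high) == nrow(data))
  keep <- !is.na(high)
  signed_logrank_stat(data$time[keep], data$status[keep], high[keep])
}

# Vectorised CV evaluation of one combination under Surv-MDR: per
# (repeat, fold), classify cells on the training subjects and score training
# and test subjects with the learned labels. Covariates never enter.
survmdr_eval_core <- function(time, status, cells, fold_mat, ncell) {
  keep_all <- !is.na(cells)
  folds <- max(fold_mat)
  repeats <- ncol(fold_mat)
  train_st <- matrix(NA_real_, folds, repeats)
  test_st <- matrix(NA_real_, folds, repeats)
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      tr <- keep_all & fold_mat[, r] != f
      te <- keep_all & fold_mat[, r] == f
      if (sum(status[tr]) == 0) next  # fold recorded as missing
      high <- survmdr_classify_core(time[tr], status[tr], cells[tr], ncell)
      train_st[f, r] <- signed_logrank_stat(time[tr], status[tr],
                                            high[cells[tr] + 1L])
      test_st[f, r] <- signed_logrank_stat(time[te], status[te],
                                           high[cells[te] + 1L])
    }
  }
  list(train_ba = train_st, test_ba = test_st)
}

#' Cross-validated Surv-MDR evaluation of one SNP combination
#'
#' Same cross-validation scaffolding as [mdr_evaluate()] (identical fold
#' splits for identical seeds) but with Surv-MDR's per-cell log-rank
#' classifier and the signed log-rank statistic as the train/test score.
#'
#' @inheritParams mdr_evaluate
#' @return A `coxmdr_cv` tibble whose `train_score`/`test_score` columns hold
#'   signed log-rank statistics (`score` attribute `"logrank"`).
#' @export
survmdr_evaluate <- function(data, snps, folds = 10, repeats = 10, seed = 1L) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  idx <- resolve_snps(data, snps)
  cells <- assign_cells(data, idx)
  fold_mat <- make_folds(data$status, folds, repeats, seed)
  res <- survmdr_eval_core(data$time, data$status, cells, fold_mat,
                           3L^length(idx))
  cv_result(res, snp_cols(data)[idx], folds, repeats, score = "logrank")
}
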