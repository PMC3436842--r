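#' Map subjects to multi-locus genotype cells
#'
#' For a k-SNP combination each subject falls in one of the `3^k` cells of
#' the genotype contingency table. Cells are encoded in base 3 over the tuple
#' order: `cell = sum_j g_j * 3^(j-1)` (0-based), so `(0,0) -> 0` and
#' `(2,2) -> 8` for k = 2. Subjects missing any involved genotype get `NA`
#' and are excluded downstream.
#'
#' @param genotypes A genotype matrix (subjects x SNPs, values 0/1/2/NA) or a
#'   [cohort()].
#' @param snp_indices Ordered tuple of distinct column indices (or names).
#' @return Integer vector of 0-based cell indices with `NA` for subjects
#'   missing any involved genotype.
#' @export
assign_cells <- function(genotypes, snp_indices) {
  if (inherits(genotypes, "coxmdr_cohort")) genotypes <- snp_matrix(genotypes)
  if (is.character(snp_indices)) {
    snp_indices <- match(snp_indices, colnames(genotypes))
  }
  k <- length(snp_indices)
  if (k < 1) stop("need at least one SNP index", call. = FALSE)
  if (anyDuplicated(snp_indices)) {
    stop("duplicate SNP indices in the combination", call. = FALSE)
  }
  if (anyNA(snp_indices) || any(snp_indices < 1 | snp_indices > ncol(genotypes))) {
    stop("SNP indices out of range", call. = FALSE)
  }
  g <- genotypes[, snp_indices, drop = FALSE]
  as.integer(g %*% 3^(seq_len(k) - 1))
}

#' Label genotype cells from martingale residual sums
#'
#' The Cox-MDR classifier: each genotype cell is labelled high risk when the
#' sum of the martingale residuals of the (training) subjects in it is
#' greater than or equal to zero, low risk otherwise. Cells with no training
#' subjects are labelled low risk, so every future subject remains
#' classifiable.
#'
#' @param residuals Martingale residuals of the training subjects.
#' @param cells 0-based cell indices from [assign_cells()] (`NA` excluded).
#' @param k Interaction order (labels cover all `3^k` cells).
#' @return Logical vector of length `3^k`: `TRUE` = high risk.
#' @export
classify_cells <- function(residuals, cells, k) {
  ncell <- 3L^k
  keep <- !is.na(cells)
  sums <- numeric(ncell)
  occupied <- logical(ncell)
  if (any(keep)) {
    agg <- rowsum(residuals[keep], cells[keep])
    idx <- as.integer(rownames(agg)) + 1L
    sums[idx] <- agg
    occupied[idx] <- TRUE
  }
  sums >= 0 & occupied
}

#' Balanced accuracy of a high/low classification
#'
#' Mean of sensitivity and specificity,
#' `0.5 * (TP/(TP+FN) + TN/(TN+FP))`, where "cases" are subjects whose
#' martingale residual is positive (more events observed than the
#' covariate-only model expects) and "positives" are subjects predicted high
#' risk. When one of the two classes is absent its term is defined as 0 and
#' the result carries a `degenerate` attribute.
#'
#' @param predicted Logical, `TRUE` = predicted high risk; `NA` predictions
#'   are excluded together with their subjects.
#' @param case Logical, `TRUE` = case (positive residual).
#' @return Balanced accuracy in \[0, 1\] with attribute `degenerate`.
#' @export
balanced_accuracy <- function(predicted, case) {
  keep <- !is.na(predicted)
  predicted <- predicted[keep]
  case <- case[keep]
  pos <- sum(case)
  neg <- sum(!case)
  if (pos + neg == 0 || (pos == 0 && neg == 0)) {
    stop("no classifiable subjects", call. = FALSE)
  }
  if (pos == 0 || neg == 0) {
    tp <- sum(predicted & case)
    tn <- sum(!predicted & !case)
    term <- if (pos > 0) tp / pos else tn / neg
    return(structure(term / 2, degenerate = TRUE))
  }
  sens <- sum(predicted & case) / pos
  spec <- sum(!predicted & !case) / neg
  structure((sens + spec) / 2, degenerate = FALSE)
}

# ---------------------------------------------------------------------------
# Vectorised cross-validated evaluation of one SNP combination.
#
# For one repeat the whole 10-fold loop collapses into a handful of rowsum()
# calls: residual sums, case counts and subject counts per (fold, cell) give
# the training cell sums (total minus fold), the learned labels, and the
# train/test confusion counts by matrix arithmetic. This is what keeps the
# 45-pair x 10x10-CV search tractable over hundreds of simulated datasets.
# ---------------------------------------------------------------------------
eval_combo_core <- function(resid, cells, fold_mat, ncell) {
  keep <- !is.na(cells)
  resid <- resid[keep]
  cells <- cells[keep]
  case <- as.numeric(resid > 0)
  folds <- max(fold_mat)
  repeats <- ncol(fold_mat)
  train_ba <- matrix(NA_real_, folds, repeats)
  test_ba <- matrix(NA_real_, folds, repeats)

  for (r in seq_len(repeats)) {
    f <- fold_mat[keep, r]
    key <- cells * folds + f
    s_fc <- matrix(0, folds, ncell)   # residual sums per (fold, cell)
    a_fc <- matrix(0, folds, ncell)   # case counts
    n_fc <- matrix(0, folds, ncell)   # subject counts
    agg <- rowsum(cbind(resid, case, 1), key)
    keys <- as.integer(rownames(agg))
    cell_of <- keys %/% folds
    fold_of <- keys - cell_of * folds
    wrap <- fold_of == 0
    fold_of[wrap] <- folds
    cell_of[wrap] <- cell_of[wrap] - 1L
    lin <- fold_of + cell_of * folds
    s_fc[lin] <- agg[, 1]
    a_fc[lin] <- agg[, 2]
    n_fc[lin] <- agg[, 3]

    tot_s <- colSums(s_fc)
    tot_a <- colSums(a_fc)
    tot_n <- colSums(n_fc)
    tr_s <- sweep(-s_fc, 2, tot_s, "+")
    tr_n <- sweep(-n_fc, 2, tot_n, "+")
    # training labels: residual sum >= 0 among occupied training cells;
    # training-empty cells default to low risk
    high <- tr_s >= 0 & tr_n > 0

    c_fc <- n_fc - a_fc
    tr_a <- sweep(-a_fc, 2, tot_a, "+")
    tr_c <- tr_n - tr_a

    low <- !high
    test_ba[, r] <- ba_from_counts(
      tp = rowSums(high * a_fc), fn = rowSums(low * a_fc),
      tn = rowSums(low * c_fc), fp = rowSums(high * c_fc)
    )
    train_ba[, r] <- ba_from_counts(
      tp = rowSums(high * tr_a), fn = rowSums(low * tr_a),
      tn = rowSums(low * tr_c), fp = rowSums(high * tr_c)
    )
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

# Balanced accuracy from confusion counts, one value per fold; an absent
# class contributes 0 to its term, both classes absent -> NA (fold recorded
# as missing rather than dropped).
ba_from_counts <- function(tp, fn, tn, fp) {
  pos <- tp + fn
  neg <- tn + fp
  sens <- ifelse(pos > 0, tp / pos, 0)
  spec <- ifelse(neg > 0, tn / neg, 0)
  out <- (sens + spec) / 2
  out[pos + neg == 0] <- NA_real_
  out
}

#' Cross-validated evaluation of one SNP combination (Cox-MDR)
#'
#' Evaluates a single k-SNP combination by repeated stratified
#' cross-validation. Per fold, cell labels are learned on the training part
#' (residual-sum sign) and the training and testing balanced accuracies are
#' computed against the residual-sign case status. Martingale residuals are
#' by default computed once on the full cohort before cross-validation (the
#' GMDR-style score); set `recompute_residuals = TRUE` to refit the null
#' model inside every training fold for sensitivity analysis.
#'
#' @param data A [cohort()].
#' @param snps SNP names or indices forming the combination.
#' @param folds,repeats Cross-validation geometry (default 10 x 10).
#' @param covariates Covariates for the null model; defaults to the cohort's.
#' @param seed Seed controlling fold shuffling.
#' @param residuals Optional precomputed martingale residuals (full cohort).
#' @param recompute_residuals Refit the null model per training fold.
#' @return A `coxmdr_cv` tibble with one row per (repeat, fold):
#'   `repeat_`, `fold`, `train_ba`, `test_ba`. Attributes carry `snps`,
#'   `mean_train`, `mean_test`, `folds`, `repeats`. Use [glance()] for the
#'   one-row summary.
#' @export
mdr_evaluate <- function(data, snps, folds = 10, repeats = 10,
                         covariates = NULL, seed = 1L, residuals = NULL,
                         recompute_residuals = FALSE) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  idx <- resolve_snps(data, snps)
  k <- length(idx)
  cells <- assign_cells(data, idx)
  fold_mat <- make_folds(data$status, folds, repeats, seed)

  if (recompute_residuals) {
    res <- eval_combo_perfold(data, cells, fold_mat, 3L^k, covariates)
  } else {
    residuals <- residuals %||% martingale_residuals(cox_null(data, covariates))
    res <- eval_combo_core(residuals, cells, fold_mat, 3L^k)
  }
  cv_result(res, snp_cols(data)[idx], folds, repeats)
}

# Sensitivity-analysis path: refit the null Cox model on each training fold
# and score the test fold with training-fold labels; test-subject case status
# still needs residuals, taken from the full-cohort fit (their own survival
# never enters the training fit).
eval_combo_perfold <- function(data, cells, fold_mat, ncell, covariates) {
  full_res <- martingale_residuals(cox_null(data, covariates))
  folds <- max(fold_mat)
  repeats <- ncol(fold_mat)
  train_ba <- matrix(NA_real_, folds, repeats)
  test_ba <- matrix(NA_real_, folds, repeats)
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      tr <- fold_mat[, r] != f
      te <- !tr
      sub <- data[tr, , drop = FALSE]
      sub <- new_cohort(sub, snp_cols(data), covariate_cols(data))
      rtr <- martingale_residuals(cox_null(sub, covariates))
      high <- classify_cells(rtr, cells[tr], round(log(ncell, 3)))
      pred_tr <- high[cells[tr] + 1L]
      pred_tr[is.na(cells[tr])] <- NA
      pred_te <- high[cells[te] + 1L]
      pred_te[is.na(cells[te])] <- NA
      train_ba[f, r] <- tryCatch(
        as.numeric(balanced_accuracy(pred_tr, rtr > 0)),
        error = function(e) NA_real_)
      test_ba[f, r] <- tryCatch(
        as.numeric(balanced_accuracy(pred_te, full_res[te] > 0)),
        error = function(e) NA_real_)
    }
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

resolve_snps <- function(data, snps) {
  if (is.character(snps)) {
    idx <- match(snps, snp_cols(data))
    if (anyNA(idx)) {
      stop("unknown SNP column(s): ",
           paste(snps[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    idx
  } else {
    as.integer(snps)
  }
}

cv_result <- function(res, snp_names, folds, repeats, score = "balanced_accuracy") {
  out <- tibble::tibble(
    repeat_ = rep(seq_len(repeats), each = folds),
    fold = rep(seq_len(folds), repeats),
    train_score = as.vector(res$train_ba),
    test_score = as.vector(res$test_ba)
  )
  structure(out,
            snps = snp_names,
            folds = folds, repeats = repeats,
            score = score,
            mean_train = mean(out$train_score, na.rm = TRUE),
            mean_test = mean(out$test_score, na.rm = TRUE),
            class = c("coxmdr_cv", class(out)))
}

#' @export
print.coxmdr_cv <- function(x, ...) {
  cat(sprintf("<coxmdr_cv> %s | %d-fold x %d repeats | mean train %.4f, mean test %.4f (%s)\n",
              paste(attr(x, "snps"), collapse = " * "),
              attr(x, "folds"), attr(x, "repeats"),
              attr(x, "mean_train"), attr(x, "mean_test"), attr(x, "score")))
  NextMethod()
}

#' Glance at a cross-validated combination evaluation
#'
#' @param x A `coxmdr_cv` object.
#' @param ... Unused.
#' @return One-row tibble: combination label, mean training and testing
#'   score, number of missing folds, CV geometry.
#' @export
glance.coxmdr_cv <- function(x, ...) {
  tibble::tibble(
    snps = paste(attr(x, "snps"), collapse = ","),
    mean_train = attr(x, "mean_train"),
    mean_test = attr(x, "mean_test"),
    missing_folds = sum(is.na(x$test_score)),
    folds = attr(x, "folds"),
    repeats = attr(x, "repeats"),
    score = attr(x, "score")
  )
}
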