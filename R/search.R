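#' Exhaustive cross-validated search over k-way SNP combinations
#'
#' Evaluates every `choose(M, k)` SNP combination by repeated stratified
#' cross-validation and ranks them by mean testing score: balanced accuracy
#' against the residual-sign case status for `method = "coxmdr"`, or the
#' signed log-rank statistic for `method = "survmdr"`. Cross-validation
#' consistency counts, per combination, the (repeat, fold) splits in which it
#' achieved the best *training* score among all candidates — the classical
#' MDR fold-best tally. Ties in the ranking are broken by CV consistency,
#' then mean training score, then lexicographic tuple order.
#'
#' @param data A [cohort()].
#' @param k Interaction order (number of SNPs per combination).
#' @param folds,repeats Cross-validation geometry; the default 10 x 10 is the
#'   simulation-study configuration, `folds = 2, repeats = 100` the
#'   small-sample real-data one.
#' @param covariates Covariates for the Cox null model (`method = "coxmdr"`
#'   only; defaults to the cohort's covariates; `character(0)` = unadjusted).
#'   Ignored by Surv-MDR, which cannot adjust.
#' @param seed Seed for the fold shuffling, shared across all combinations
#'   and both methods so fold splits are identical for identical seeds.
#' @param method `"coxmdr"` (default) or `"survmdr"`.
#' @param max_combos Guard against accidental combinatorial explosions.
#' @return A `coxmdr_search` tibble with one row per combination, ranked:
#'   `rank`, `snps` (comma-joined label), `mean_train`, `mean_test`,
#'   `cv_consistency`, plus a `snp_idx` list-column of index tuples.
#' @examples
#' \donttest{
#' mod <- penetrance_model(maf = 0.2, h2 = 0.3, seed = 1)
#' ch <- simulate_cohort(mod, seed = 1)
#' mdr_search(ch, k = 2, repeats = 2, seed = 1)
#' }
#' @export
mdr_search <- function(data, k = 2, folds = 10, repeats = 10,
                       covariates = NULL, seed = 1L,
                       method = c("coxmdr", "survmdr"),
                       max_combos = 20000L) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  method <- match.arg(method)
  m <- length(snp_cols(data))
  if (m < k) stop("fewer SNPs (", m, ") than the interaction order k = ", k,
                  call. = FALSE)
  n_combos <- choose(m, k)
  if (n_combos > max_combos) {
    stop(n_combos, " combinations exceed max_combos = ", max_combos,
         "; raise the cap explicitly if intended", call. = FALSE)
  }
  combos <- utils::combn(m, k, simplify = FALSE)
  fold_mat <- make_folds(data$status, folds, repeats, seed)
  ncell <- 3L^k
  geno <- snp_matrix(data)

  if (method == "coxmdr") {
    resid <- martingale_residuals(cox_null(data, covariates))
    evals <- lapply(combos, function(ix) {
      cells <- as.integer(geno[, ix, drop = FALSE] %*% 3^(seq_len(k) - 1))
      eval_combo_core(resid, cells, fold_mat, ncell)
    })
  } else {
    evals <- lapply(combos, function(ix) {
      cells <- as.integer(geno[, ix, drop = FALSE] %*% 3^(seq_len(k) - 1))
      survmdr_eval_core(data$time, data$status, cells, fold_mat, ncell)
    })
  }

  mean_train <- vapply(evals, function(e) mean(e$train_ba, na.rm = TRUE), 0)
  mean_test <- vapply(evals, function(e) mean(e$test_ba, na.rm = TRUE), 0)

  # fold-best tally on training score
  cvc <- integer(length(combos))
  tr_mat <- vapply(evals, function(e) as.vector(e$train_ba),
                   numeric(folds * repeats))
  if (is.null(dim(tr_mat))) tr_mat <- matrix(tr_mat, nrow = 1)
  for (s in seq_len(nrow(tr_mat))) {
    row <- tr_mat[s, ]
    if (all(is.na(row))) next
    best <- which.max(row)  # first index wins ties -> lexicographic tuple
    cvc[best] <- cvc[best] + 1L
  }

  labels <- vapply(combos, function(ix) paste(snp_cols(data)[ix], collapse = ","),
                   character(1))
  ord <- order(-mean_test, -cvc, -mean_train, labels)
  out <- tibble::tibble(
    rank = seq_along(combos),
    snps = labels[ord],
    mean_train = mean_train[ord],
    mean_test = mean_test[ord],
    cv_consistency = cvc[ord],
    snp_idx = combos[ord]
  )
  structure(out,
            method = method, k = k, folds = folds, repeats = repeats,
            seed = seed,
            covariates = if (method == "coxmdr")
              covariates %||% covariate_cols(data) else character(0),
            score = if (method == "coxmdr") "balanced_accuracy" else "logrank",
            class = c("coxmdr_search", class(out)))
}

#' @export
print.coxmdr_search <- function(x, n = 10, ...) {
  cat(sprintf("<coxmdr_search> method = %s, k = %d, %d-fold x %d repeats, %d combinations\n",
              attr(x, "method"), attr(x, "k"), attr(x, "folds"),
              attr(x, "repeats"), nrow(x)))
  NextMethod()
}

#' Tidy a combination search
#'
#' @param x A `coxmdr_search` object.
#' @param ... Unused.
#' @return The ranking as a plain tibble without the index list-column.
#' @export
tidy.coxmdr_search <- function(x, ...) {
  tibble::as_tibble(x)[, c("rank", "snps", "mean_train", "mean_test",
                           "cv_consistency")]
}

#' Glance at a combination search
#'
#' @param x A `coxmdr_search` object.
#' @param ... Unused.
#' @return One-row tibble describing the best model and the search geometry.
#' @export
glance.coxmdr_search <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"), k = attr(x, "k"),
    n_combinations = nrow(x),
    best_snps = x$snps[1],
    best_mean_test = x$mean_test[1],
    best_cv_consistency = x$cv_consistency[1],
    folds = attr(x, "folds"), repeats = attr(x, "repeats")
  )
}

#' Refit the best (or any ranked) attribute on the full cohort
#'
#' Recomputes the high/low cell labels of a ranked combination on the whole
#' cohort — with the method's own classifier — and returns the per-subject
#' binary attribute, the input to survival-curve plots and permutation tests.
#'
#' @param data The cohort the search was run on.
#' @param search A `coxmdr_search` result.
#' @param rank Which ranked model to refit (default the best).
#' @return A list of class `coxmdr_attribute`: `snps`, `snp_idx`, `high`
#'   (per-cell labels, length `3^k`), `subject_high` (per-subject logical,
#'   `NA` when a genotype is missing) and `method`.
#' @export
mdr_attribute <- function(data, search, rank = 1) {
  stopifnot(inherits(search, "coxmdr_search"))
  idx <- search$snp_idx[[match(rank, search$rank)]]
  k <- length(idx)
  cells <- assign_cells(data, idx)
  if (attr(search, "method") == "coxmdr") {
    resid <- martingale_residuals(cox_null(data, attr(search, "covariates")))
    high <- classify_cells(resid, cells, k)
  } else {
    high <- survmdr_classify(data, idx)
  }
  subject_high <- high[cells + 1L]
  subject_high[is.na(cells)] <- NA
  structure(
    list(snps = snp_cols(data)[idx], snp_idx = idx, k = k,
         high = as.logical(high), subject_high = subject_high,
         method = attr(search, "method")),
    class = "coxmdr_attribute"
  )
}

#' @export
print.coxmdr_attribute <- function(x, ...) {
  cat(sprintf("<coxmdr_attribute> %s (%s): %d/%d cells high risk\n",
              paste(x$snps, collapse = " * "), x$method,
              sum(x$high), length(x$high)))
  invisible(x)
}
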