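#' Univariate Cox test for one SNP
#'
#' Fits a Cox model with the additively coded SNP (minor-allele count 0/1/2)
#' plus the adjusting covariates, and reports the SNP coefficient, its
#' standard error from the observed information, and the two-sided Wald
#' p-value. Subjects missing the genotype at this SNP are excluded.
#'
#' @param data A [cohort()].
#' @param snp SNP column name (or index into [snp_cols()]).
#' @param covariates Covariate column names to adjust for; defaults to the
#'   cohort's covariates. `character(0)` for no adjustment.
#' @param ties Tie handling passed to the Cox fit.
#' @return One-row tibble: `snp`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `n_used`.
#' @export
cox_snp_test <- function(data, snp, covariates = NULL,
                         ties = c("breslow", "efron")) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  ties <- match.arg(ties)
  covariates <- covariates %||% covariate_cols(data)
  if (is.numeric(snp)) snp <- snp_cols(data)[snp]
  if (!snp %in% snp_cols(data)) stop("unknown SNP column '", snp, "'", call. = FALSE)

  g <- data[[snp]]
  keep <- !is.na(g)
  g <- g[keep]
  if (length(unique(g)) < 2) {
    stop("SNP '", snp, "' is constant among non-missing subjects", call. = FALSE)
  }
  z <- cbind(snp = g, covariate_matrix(data, covariates)[keep, , drop = FALSE])
  colnames(z)[1] <- snp
  fit <- fit_coxph_guarded(data$time[keep], data$status[keep], z, ties,
                           iter_max = 50L)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinearity: SNP '", snp,
         "' is linearly dependent on the adjusting covariates", call. = FALSE)
  }
  est <- cf[[1]]
  se <- sqrt(fit$var[1, 1])
  zstat <- est / se
  tibble::tibble(
    snp = snp, estimate = est, std.error = se, statistic = zstat,
    p.value = 2 * stats::pnorm(-abs(zstat)), n_used = sum(keep)
  )
}

#' Per-SNP Cox regression screen with FDR control
#'
#' Runs [cox_snp_test()] on every SNP of the cohort and appends
#' Benjamini-Hochberg adjusted values computed against `m_total` tests.
#' SNPs whose fit fails (constant genotype, monotone likelihood, ...) get
#' `NA` results and the failure message in `note`; they still count towards
#' the default `m_total`.
#'
#' @inheritParams cox_snp_test
#' @param m_total Total number of tests for the FDR adjustment; defaults to
#'   the number of SNPs screened.
#' @return Tibble with one row per SNP, ordered by p-value: `snp`,
#'   `estimate`, `std.error`, `statistic`, `p.value`, `fdr`, `note`.
#' @export
cox_screen <- function(data, covariates = NULL, m_total = NULL,
                       ties = c("breslow", "efron")) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  ties <- match.arg(ties)
  snps <- snp_cols(data)
  m_total <- m_total %||% length(snps)
  rows <- purrr::map(snps, function(s) {
    tryCatch(
      dplyr::mutate(cox_snp_test(data, s, covariates, ties), note = NA_character_),
      error = function(e) tibble::tibble(
        snp = s, estimate = NA_real_, std.error = NA_real_,
        statistic = NA_real_, p.value = NA_real_, n_used = NA_integer_,
        note = conditionMessage(e)
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p.value)
  out$fdr <- NA_real_
  out$fdr[ok] <- bh_fdr(out$p.value[ok], m_total = m_total)
  dplyr::arrange(out, .data$p.value)
}

#' Benjamini-Hochberg adjusted p-values against a wider test family
#'
#' Step-up adjustment `min over j >= i of p_(j) * m_total / j`, capped at 1
#' and returned in the input order. Unlike [stats::p.adjust()], the family
#' size `m_total` may exceed the number of p-values supplied: tests not
#' listed are assumed to have larger p-values than every listed one, which is
#' how FDR columns for "top hits" tables are computed.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m_total Family size, at least `length(p)`.
#' @return Adjusted values in the input order.
#' @examples
#' bh_fdr(c(0.0029, 0.04), m_total = 139)
#' @export
bh_fdr <- function(p, m_total = length(p)) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  if (m_total < length(p)) {
    stop("m_total must be at least length(p)", call. = FALSE)
  }
  o <- order(p)
  raw <- p[o] * m_total / seq_along(p)
  adj <- pmin(rev(cummin(rev(raw))), 1)
  out <- numeric(length(p))
  out[o] <- adj
  out
}
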