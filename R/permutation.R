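#' Permutation p-value for a SNP combination's high/low attribute
#'
#' Measures the survival association of a combination's binary high/low
#' attribute by the Wald chi-square of the attribute in a Cox model adjusting
#' for covariates, and calibrates it by permutation: the phenotype block
#' (time, status, covariates) is permuted jointly against the genotype rows —
#' breaking any genotype-survival association while preserving the
#' covariate-survival one — and the cell labels and statistic are re-derived
#' for every permutation. The p-value uses the add-one estimator
#' `(1 + #\{perm >= observed\}) / (B + 1)`.
#'
#' @param data A [cohort()].
#' @param snps SNP names or indices of the combination.
#' @param covariates Covariates for the null model and the attribute fit;
#'   defaults to the cohort's covariates.
#' @param B Number of permutations.
#' @param seed Seed for the permutation stream.
#' @param method Classifier used to label cells: `"coxmdr"` (residual sums)
#'   or `"survmdr"` (per-cell log-rank, unadjusted).
#' @return The p-value, with attributes `statistic` (observed Wald
#'   chi-square) and `degenerate` (`TRUE` when the observed attribute puts
#'   every subject in one group; the p-value is then reported as 1).
#' @export
permutation_pvalue <- function(data, snps, covariates = NULL, B = 1000L,
                               seed = 1L, method = c("coxmdr", "survmdr")) {
  stopifnot(inherits(data, "coxmdr_cohort"), B >= 1)
  method <- match.arg(method)
  covariates <- covariates %||% covariate_cols(data)
  idx <- resolve_snps(data, snps)
  k <- length(idx)
  cells <- assign_cells(data, idx)
  time <- data$time
  status <- data$status
  z <- covariate_matrix(data, covariates)
  n <- nrow(data)

  stat_for <- function(perm) {
    t_p <- time[perm]
    s_p <- status[perm]
    z_p <- z[perm, , drop = FALSE]
    high <- if (method == "coxmdr") {
      ch <- tibble::tibble(id = data$id, time = t_p, status = s_p)
      covn <- if (ncol(z_p) > 0) colnames(z_p) else character(0)
      if (length(covn)) ch <- cbind(ch, as.data.frame(z_p))
      fit <- cox_null(new_cohort(ch, character(0), covn), covariates = covn)
      classify_cells(martingale_residuals(fit), cells, k)
    } else {
      survmdr_classify_core(t_p, s_p, cells, 3L^k)
    }
    x <- high[cells + 1L]
    x[is.na(cells)] <- NA
    wald_chisq_attribute(t_p, s_p, z_p, x)
  }

  obs <- stat_for(seq_len(n))
  if (is.na(obs)) {
    return(structure(1, statistic = NA_real_, degenerate = TRUE))
  }
  perms <- withr::with_seed(seed,
                            replicate(B, sample.int(n), simplify = FALSE))
  null_stats <- vapply(perms, function(p) {
    s <- stat_for(p)
    if (is.na(s)) 0 else s
  }, 0)
  p <- (1 + sum(null_stats >= obs)) / (B + 1)
  structure(p, statistic = obs, degenerate = FALSE)
}

# Wald chi-square of the binary high/low attribute in a Cox model with
# covariates; NA when the attribute is one-sided or the fit fails.
wald_chisq_attribute <- function(time, status, z, x) {
  keep <- !is.na(x)
  x <- as.numeric(x[keep])
  if (length(unique(x)) < 2) return(NA_real_)
  zz <- cbind(attr_high = x, z[keep, , drop = FALSE])
  fit <- tryCatch(
    fit_coxph_guarded(time[keep], status[keep], zz, "breslow", 50L),
    error = function(e) NULL
  )
  if (is.null(fit) || is.na(stats::coef(fit)[1])) return(NA_real_)
  unname(stats::coef(fit)[1]^2 / fit$var[1, 1])
}
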