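#' Fit the covariate-only ("null") Cox model and martingale residuals
#'
#' Fits a Cox proportional-hazards model containing only the adjusting
#' covariates (no SNP terms), estimates the Breslow cumulative baseline
#' hazard, and returns the martingale residual of every subject,
#' \deqn{M_i = \delta_i - \hat\Lambda_0(T_i) \exp(\hat\gamma' Z_i),}
#' the difference between the observed and the model-expected number of
#' events. Positive residuals mark subjects dying earlier than the
#' covariate-only model predicts; these residuals are the score that Cox-MDR
#' uses to label genotype cells. With no covariates the fit reduces to the
#' Nelson-Aalen estimator and \eqn{M_i = \delta_i - \hat\Lambda_0(T_i)}.
#'
#' Ties are handled with the Breslow approximation (so that residuals sum to
#' zero exactly); the Efron approximation is available for sensitivity
#' analysis but breaks that identity.
#'
#' @param data A [cohort()].
#' @param covariates Covariate column names to adjust for; defaults to every
#'   covariate recorded in the cohort. Use `character(0)` for an unadjusted
#'   (intercept-free, Nelson-Aalen) fit.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param iter_max Newton-Raphson iteration cap.
#' @return An object of class `coxmdr_null`: a list with elements
#'   `gamma_hat` (named coefficient vector, length 0 when unadjusted), `se`,
#'   `cum_baseline` (tibble of jump `time`, jump size `jump` and cumulative
#'   `hazard`), `residuals`, `linear_predictor`, `loglik` (maximised Breslow
#'   log partial likelihood), `loglik_null` (at gamma = 0), `n`, `n_events`,
#'   `ties` and `covariates`.
#' @examples
#' ch <- cohort(data.frame(time = c(1, 2, 3), status = c(1, 1, 1)))
#' fit <- cox_null(ch)
#' fit$residuals  # 2/3, 1/6, -5/6
#' @export
cox_null <- function(data, covariates = NULL, ties = c("breslow", "efron"),
                     iter_max = 50L) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  ties <- match.arg(ties)
  covariates <- covariates %||% covariate_cols(data)
  z <- covariate_matrix(data, covariates)
  time <- data$time
  status <- data$status
  n <- length(time)
  q <- ncol(z)

  if (q > 0) {
    if (any(!is.finite(z))) {
      stop("covariate matrix contains non-finite values", call. = FALSE)
    }
    if (sum(status) == 0) {
      stop("cannot estimate covariate effects: no events in the cohort",
           call. = FALSE)
    }
    fit <- fit_coxph_guarded(time, status, z, ties, iter_max)
    gamma_hat <- stats::coef(fit)
    if (anyNA(gamma_hat)) {
      stop("collinear covariates: coefficient(s) inestimable for ",
           paste(names(gamma_hat)[is.na(gamma_hat)], collapse = ", "),
           call. = FALSE)
    }
    se <- sqrt(diag(fit$var))
    names(se) <- names(gamma_hat)
    lp <- as.vector(z %*% gamma_hat)
  } else {
    gamma_hat <- stats::setNames(numeric(0), character(0))
    se <- gamma_hat
    lp <- numeric(n)
  }

  base <- breslow_baseline(time, status, lp)
  lambda_at_t <- cum_hazard_at(base, time)
  residuals <- status - lambda_at_t * exp(lp)

  structure(
    list(
      gamma_hat = gamma_hat,
      se = se,
      cum_baseline = base,
      residuals = residuals,
      linear_predictor = lp,
      loglik = breslow_loglik(time, status, lp),
      loglik_null = breslow_loglik(time, status, numeric(n)),
      n = n,
      n_events = sum(status),
      ties = ties,
      covariates = covariates
    ),
    class = "coxmdr_null"
  )
}

# coxph with explicit failure modes: iteration cap and monotone likelihood
# are reported as errors, not silent warnings.
fit_coxph_guarded <- function(time, status, z, ties, iter_max) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(time, status) ~ z,
      ties = ties,
      control = survival::coxph.control(eps = 1e-10, iter.max = iter_max)
    ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (anyNA(stats::coef(fit))) {
    bad <- colnames(z)[is.na(stats::coef(fit))]
    stop("collinear predictors: coefficient(s) inestimable for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(grepl("Ran out of iterations", msgs))) {
    stop("Cox fit did not converge within ", iter_max, " iterations",
         call. = FALSE)
  }
  if (any(grepl("infinite", msgs))) {
    stop("monotone likelihood: a covariate perfectly separates the risk sets ",
         "(coefficient diverges)", call. = FALSE)
  }
  names(fit$coefficients) <- colnames(z) %||%
    paste0("z", seq_along(fit$coefficients))
  fit
}

# Breslow estimator of the cumulative baseline hazard: at each distinct event
# time t, jump d_t / sum_{j at risk} exp(lp_j).
breslow_baseline <- function(time, status, lp) {
  ord <- order(time)
  t_s <- time[ord]
  d_s <- status[ord]
  w_s <- exp(lp[ord])
  # risk denominator just before each sorted position (ties share the value
  # at the first occurrence of their time)
  rev_cum <- rev(cumsum(rev(w_s)))
  first_at <- !duplicated(t_s)
  denom_at_time <- rev_cum[first_at]
  ut <- t_s[first_at]
  d_t <- as.vector(rowsum(d_s, match(t_s, ut)))
  keep <- d_t > 0
  jump <- d_t[keep] / denom_at_time[keep]
  tibble::tibble(time = ut[keep], jump = jump, hazard = cumsum(jump))
}

# Right-continuous evaluation of the cumulative baseline hazard.
cum_hazard_at <- function(base, times) {
  if (nrow(base) == 0) return(numeric(length(times)))
  idx <- findInterval(times, base$time)
  c(0, base$hazard)[idx + 1]
}

# Breslow-tie log partial likelihood at a given linear predictor.
breslow_loglik <- function(time, status, lp) {
  ord <- order(time)
  t_s <- time[ord]
  d_s <- status[ord]
  w_s <- exp(lp[ord])
  rev_cum <- rev(cumsum(rev(w_s)))
  first_at <- !duplicated(t_s)
  denom <- rev_cum[first_at][match(t_s, t_s[first_at])]
  sum(d_s * (lp[ord] - log(denom)))
}

#' @export
print.coxmdr_null <- function(x, ...) {
  cat(sprintf("<coxmdr_null> n = %d (%d events), %d covariate(s), loglik = %.4f\n",
              x$n, x$n_events, length(x$gamma_hat), x$loglik))
  if (length(x$gamma_hat)) {
    print(tidy(x))
  }
  invisible(x)
}

#' Tidy a null Cox fit
#'
#' @param x A `coxmdr_null` object.
#' @param ... Unused.
#' @return One row per covariate with `term`, `estimate`, `std.error`,
#'   `statistic` (Wald z) and `p.value`.
#' @export
tidy.coxmdr_null <- function(x, ...) {
  z <- x$gamma_hat / x$se
  tibble::tibble(
    term = names(x$gamma_hat),
    estimate = unname(x$gamma_hat),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' Glance at a null Cox fit
#'
#' @param x A `coxmdr_null` object.
#' @param ... Unused.
#' @return A one-row tibble with sample size, event count, maximised log
#'   partial likelihood and the value at gamma = 0.
#' @export
glance.coxmdr_null <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    loglik = x$loglik, loglik_null = x$loglik_null,
    n_covariates = length(x$gamma_hat)
  )
}

#' Martingale residuals of a null Cox fit
#'
#' @param fit A `coxmdr_null` object.
#' @return Numeric vector, one residual per subject, summing to zero under
#'   Breslow ties.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "coxmdr_null"))
  fit$residuals
}
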