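# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately literal (loops, hand-built risk tables),
# never calling the code paths it is used to check.

# Breslow-tie log partial likelihood for a single coefficient, written as a
# direct double loop over risk sets.
breslow_pl_1d <- function(gamma, time, status, x) {
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      at_risk <- time >= time[i]
      ll <- ll + gamma * x[i] - log(sum(exp(gamma * x[at_risk])))
    }
  }
  ll
}

# Grid-search maximiser of the Breslow partial likelihood over [-5, 5].
grid_cox_1d <- function(time, status, x, step = 1e-4) {
  grid <- seq(-5, 5, by = step)
  ll <- vapply(grid, breslow_pl_1d, 0, time = time, status = status, x = x)
  grid[which.max(ll)]
}

# Random survival cohort with optional covariates and SNPs.
random_cohort <- function(n = 30, m_snps = 3, q_cov = 1, seed = 1,
                          censor = 0.3) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * q_cov), n, q_cov)
    lp <- if (q_cov > 0) z %*% rep(0.5, q_cov) else numeric(n)
    t_ev <- rexp(n, exp(lp))
    c_ev <- rexp(n, censor)
    d <- data.frame(
      id = paste0("s", seq_len(n)),
      time = pmin(t_ev, c_ev),
      status = as.integer(t_ev <= c_ev)
    )
    if (q_cov > 0) {
      colnames(z) <- paste0("z", seq_len(q_cov))
      d <- cbind(d, z)
    }
    g <- matrix(sample(0:2, n * m_snps, replace = TRUE), n, m_snps)
    colnames(g) <- paste0("SNP", seq_len(m_snps))
    d <- cbind(d, g)
    cohort(d, covariates = if (q_cov > 0) paste0("z", seq_len(q_cov))
           else character(0))
  })
}

# Literal reimplementation of one Cox-MDR cross-validation run: explicit
# loops over repeats, folds and cells. Residuals are taken as given (the
# full-cohort convention).
cv_oracle <- function(resid, cells, fold_mat, k) {
  ncell <- 3^k
  folds <- max(fold_mat)
  repeats <- ncol(fold_mat)
  train_ba <- matrix(NA_real_, folds, repeats)
  test_ba <- matrix(NA_real_, folds, repeats)
  case <- resid > 0
  ba_literal <- function(pred, cs) {
    keep <- !is.na(pred)
    pred <- pred[keep]
    cs <- cs[keep]
    tp <- sum(pred & cs); fn <- sum(!pred & cs)
    tn <- sum(!pred & !cs); fp <- sum(pred & !cs)
    if (tp + fn + tn + fp == 0) return(NA_real_)
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    (sens + spec) / 2
  }
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      tr <- fold_mat[, r] != f & !is.na(cells)
      te <- fold_mat[, r] == f & !is.na(cells)
      high <- logical(ncell)
      for (cc in 0:(ncell - 1)) {
        members <- tr & cells == cc
        if (any(members)) high[cc + 1] <- sum(resid[members]) >= 0
      }
      train_ba[f, r] <- ba_literal(high[cells[tr] + 1], case[tr])
      test_ba[f, r] <- ba_literal(high[cells[te] + 1], case[te])
    }
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

# Two-group log-rank via survival::survdiff (the independent reference).
survdiff_chisq <- function(time, status, group) {
  sd <- survival::survdiff(survival::Surv(time, status) ~ group)
  unname(sd$chisq)
}
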