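#' Two-sample log-rank test
#'
#' Standard two-sample log-rank test: at each distinct event time the
#' observed number of events in the first group is compared with its
#' hypergeometric expectation given the risk sets, and the contributions are
#' summed. The signed observed-minus-expected total is returned so callers
#' can read off the direction of excess risk (positive = more deaths than
#' expected in the first group).
#'
#' @param time Observed times.
#' @param status Event indicator, 1 = event.
#' @param group Two-level grouping. The statistic is reported for the first
#'   factor level; a logical vector reports the `TRUE` group.
#' @return A one-row tibble with `observed_minus_expected`, `variance`,
#'   `chi_square` and `p_value` (chi-square, 1 df).
#' @examples
#' logrank_test(c(1, 3, 2, 4), c(1, 0, 1, 1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
logrank_test <- function(time, status, group) {
  stopifnot(length(time) == length(status), length(time) == length(group))
  g <- if (is.logical(group)) {
    factor(group, levels = c(TRUE, FALSE))
  } else {
    as.factor(group)
  }
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("log-rank test needs two non-empty groups", call. = FALSE)
  }
  if (sum(status) == 0) {
    stop("log-rank test needs at least one event", call. = FALSE)
  }
  in1 <- as.integer(g == levels(g)[1])
  res <- logrank_oe(time, status, cells = in1, ncell = 2L)
  oe <- res$oe[2]         # cell index 1 = first level
  v <- res$var[2]
  chi <- if (v > 0) oe^2 / v else 0
  tibble::tibble(
    observed_minus_expected = oe,
    variance = v,
    chi_square = chi,
    p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE)
  )
}

# Simultaneous one-vs-rest log-rank accumulation for all genotype cells.
# `cells` holds 0-based cell indices (NA rows must be removed by the caller).
# Returns, for each cell c, the observed-minus-expected event count of the
# in-cell group versus everyone else, and the hypergeometric variance.
# This single pass is what makes Surv-MDR's per-cell scan affordable: the
# risk-set table is built once and shared by all cells.
logrank_oe <- function(time, status, cells, ncell) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]
  d_s <- status[ord]
  c_s <- cells[ord]
  first <- !duplicated(t_s)
  tid <- cumsum(first)
  K <- tid[n]
  n_t <- rev(cumsum(rev(tabulate(tid, K))))
  d_t <- as.vector(rowsum(d_s, tid))

  # per (time, cell) counts packed into K x ncell matrices via linear keys
  key <- c_s * K + tid
  cnt <- matrix(0, K, ncell)
  agg <- rowsum(rep(1, n), key)
  cnt[as.integer(rownames(agg))] <- agg
  dth <- matrix(0, K, ncell)
  agg <- rowsum(d_s, key)
  dth[as.integer(rownames(agg))] <- agg

  atrisk <- apply(cnt, 2, function(x) rev(cumsum(rev(x))))
  if (K == 1) atrisk <- matrix(atrisk, nrow = 1)

  ev <- which(d_t > 0)
  p1 <- atrisk[ev, , drop = FALSE] / n_t[ev]
  oe <- colSums(dth[ev, , drop = FALSE] - d_t[ev] * p1)
  vmult <- ifelse(n_t[ev] > 1, d_t[ev] * (n_t[ev] - d_t[ev]) / (n_t[ev] - 1), 0)
  v <- colSums(vmult * p1 * (1 - p1))
  list(oe = oe, var = v)
}

# Signed two-group log-rank statistic used as the Surv-MDR model score:
# chi-square statistic carrying the sign of (O - E) in the `high` group.
# Degenerate groupings (all subjects on one side, or zero variance) score 0.
signed_logrank_stat <- function(time, status, high) {
  n1 <- sum(high)
  if (n1 == 0 || n1 == length(high) || sum(status) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  res <- logrank_oe(time, status, cells = as.integer(high), ncell = 2L)
  oe <- res$oe[2]
  v <- res$var[2]
  if (v <= 0) return(structure(0, degenerate = TRUE))
  structure(sign(oe) * oe^2 / v, degenerate = FALSE)
}
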