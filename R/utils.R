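#' @importFrom rlang %||% .data
#' @importFrom stats pchisq qnorm rbinom rnorm runif setNames
NULL

# Derive a stream of child seeds from one user seed, all < 2^31.
child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Fold assignment stratified by event status: within events and within
# censored subjects separately, fold labels are dealt out as evenly as
# possible, so heavy censoring cannot produce event-free folds.
make_folds <- function(status, folds, repeats, seed) {
  n <- length(status)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (n < folds) stop("need at least as many subjects as folds", call. = FALSE)
  if (folds == n) {
    # leave-one-out: one subject per fold, no randomness involved
    return(matrix(rep(seq_len(n), repeats), n, repeats))
  }
  withr::with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      f <- integer(n)
      for (grp in unique(status)) {
        idx <- which(status == grp)
        lab <- rep_len(seq_len(folds), length(idx))
        f[idx] <- sample(lab)
      }
      f
    }, integer(n))
  })
}
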