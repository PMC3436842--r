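#' Simulation configuration for Cox-Weibull cohorts
#'
#' Defaults state the benchmark's world: 200 high-risk and 200 low-risk
#' subjects per dataset, a true risk-status log-hazard ratio `beta = 1`, a
#' covariate effect `gamma` in \{0, 1, 2\}, one normal covariate
#' `z ~ N(0, 0.5)` (variance 0.5), a Weibull baseline hazard with shape 5
#' and scale 2 (`Lambda0(t) = (t / scale)^shape`), uniform censoring on
#' (0, 4), and 8 null SNPs alongside the 2 causal ones.
#'
#' @param n_high,n_low Subjects drawn with high/low risk status.
#' @param beta Log hazard ratio of high-risk status.
#' @param gamma Covariate effect on the log hazard.
#' @param covariate_sd Standard deviation of the covariate z.
#' @param weibull_shape,weibull_scale Baseline-hazard Weibull parameters.
#' @param censor_upper Upper bound of the uniform censoring time.
#' @param n_null_snps Null SNPs added besides the two causal loci.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_high = 200L, n_low = 200L, beta = 1, gamma = 0,
                       covariate_sd = sqrt(0.5), weibull_shape = 5,
                       weibull_scale = 2, censor_upper = 4,
                       n_null_snps = 8L) {
  stopifnot(n_high >= 1, n_low >= 1, weibull_shape > 0, weibull_scale > 0,
            censor_upper > 0, covariate_sd >= 0, n_null_snps >= 0)
  structure(
    list(n_high = as.integer(n_high), n_low = as.integer(n_low), beta = beta,
         gamma = gamma, covariate_sd = covariate_sd,
         weibull_shape = weibull_shape, weibull_scale = weibull_scale,
         censor_upper = censor_upper, n_null_snps = as.integer(n_null_snps)),
    class = "sim_config"
  )
}

#' Simulate a survival cohort from a penetrance model
#'
#' Rejection-samples subjects until the high- and low-risk quotas are met:
#' each draw takes a two-locus genotype from HWE at the model's MAF and a
#' risk status `x ~ Bernoulli(f(g))`. Survival times come from the Cox model
#' `lambda(t) = lambda0(t) exp(beta x + gamma z)` with Weibull baseline by
#' inverse transform, `T = scale * (-log U / exp(beta x + gamma z))^(1/shape)`,
#' censored at `C ~ U(0, censor_upper)`. Null SNPs are i.i.d. HWE at the same
#' MAF, and the two causal loci are placed at seeded random positions among
#' the SNP columns to avoid index-order artifacts in the model search.
#'
#' @param model A [penetrance_model()].
#' @param config A [sim_config()].
#' @param seed Seed controlling the whole draw.
#' @param max_batches Cap on rejection-sampling batches before failing (a
#'   penetrance near 0 or 1 everywhere can make a quota unreachable).
#' @return A [cohort()] with covariate `z` and SNP columns `SNP1..SNPm`;
#'   [cohort_truth()] returns the hidden truth: `causal` (column positions of
#'   the two causal loci, in locus order), `x`, `model`, `config`.
#' @export
simulate_cohort <- function(model, config = sim_config(), seed = 1L,
                            max_batches = 200L) {
  stopifnot(inherits(model, "penetrance_model"), inherits(config, "sim_config"))
  w <- hwe_probs(model$maf)
  n_high <- config$n_high
  n_low <- config$n_low

  withr::with_seed(seed, {
    g1h <- integer(0); g2h <- integer(0)
    g1l <- integer(0); g2l <- integer(0)
    batch <- 4L * (n_high + n_low)
    tries <- 0L
    while ((length(g1h) < n_high || length(g1l) < n_low) &&
           tries < max_batches) {
      tries <- tries + 1L
      a <- sample.int(3, batch, replace = TRUE, prob = w) - 1L
      b <- sample.int(3, batch, replace = TRUE, prob = w) - 1L
      x <- stats::rbinom(batch, 1, model$f[cbind(a + 1L, b + 1L)])
      g1h <- c(g1h, a[x == 1]); g2h <- c(g2h, b[x == 1])
      g1l <- c(g1l, a[x == 0]); g2l <- c(g2l, b[x == 0])
    }
    if (length(g1h) < n_high || length(g1l) < n_low) {
      stop("risk-status quota unreachable after ", max_batches,
           " batches: penetrance too close to 0 or 1", call. = FALSE)
    }
    g1 <- c(g1h[seq_len(n_high)], g1l[seq_len(n_low)])
    g2 <- c(g2h[seq_len(n_high)], g2l[seq_len(n_low)])
    x <- rep(c(1L, 0L), c(n_high, n_low))
    n <- n_high + n_low

    nulls <- matrix(sample.int(3, n * config$n_null_snps, replace = TRUE,
                               prob = w) - 1L,
                    n, config$n_null_snps)
    z <- stats::rnorm(n, 0, config$covariate_sd)
    eta <- config$beta * x + config$gamma * z
    u <- stats::runif(n)
    t_event <- config$weibull_scale * (-log(u) / exp(eta))^(1 / config$weibull_shape)
    c_time <- stats::runif(n, 0, config$censor_upper)

    m <- config$n_null_snps + 2L
    causal_pos <- sort(sample.int(m, 2L))
    geno <- matrix(0L, n, m)
    geno[, causal_pos[1]] <- g1
    geno[, causal_pos[2]] <- g2
    geno[, -causal_pos] <- nulls
    colnames(geno) <- paste0("SNP", seq_len(m))

    d <- tibble::tibble(
      id = paste0("s", seq_len(n)),
      time = pmin(t_event, c_time),
      status = as.integer(t_event <= c_time),
      z = z
    )
    d <- cbind(d, tibble::as_tibble(geno))
    new_cohort(d, snp_cols = colnames(geno), covariate_cols = "z",
               truth = list(causal = causal_pos, x = x, model = model,
                            config = config, seed = seed))
  })
}
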