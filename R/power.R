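#' Power of an interaction-detection method over simulated cohorts
#'
#' Estimates, for one MAF-heritability combination, the probability that a
#' method recovers the two causal loci: for the MDR methods, that the causal
#' pair ranks first among all `choose(M, 2)` two-way models; for the
#' univariate Cox screen, that *both* causal SNPs reach a Wald p-value below
#' `alpha`. Following the benchmark design, `n_models` independent
#' penetrance realisations are drawn per combination and the per-model powers
#' over `n_datasets` simulated cohorts are averaged.
#'
#' @param maf,h2 Penetrance-model grid point.
#' @param method `"coxmdr"`, `"survmdr"` or `"coxreg"`.
#' @param gamma Covariate effect in the data-generating hazard.
#' @param adjust Adjust for the covariate z (ignored by `"survmdr"`, which
#'   cannot adjust).
#' @param n_models Penetrance realisations per combination.
#' @param n_datasets Simulated cohorts per model.
#' @param folds,repeats Cross-validation geometry for the MDR searches.
#' @param alpha Significance level of the univariate screen.
#' @param config Optional [sim_config()] overriding defaults other than
#'   `gamma`.
#' @param seed Master seed.
#' @return A one-row tibble: setting, `power` (averaged over models), its
#'   binomial `se` over all pooled datasets, per-model powers in a
#'   list-column, and the count of excluded dataset-level `failures`.
#' @export
estimate_power <- function(maf, h2, method = c("coxmdr", "survmdr", "coxreg"),
                           gamma = 0, adjust = FALSE, n_models = 5,
                           n_datasets = 100, folds = 10, repeats = 10,
                           alpha = 0.05, config = NULL, seed = 1L) {
  method <- match.arg(method)
  config <- config %||% sim_config(gamma = gamma)
  config$gamma <- gamma
  seeds <- child_seeds(seed, n_models * (n_datasets + 1))
  sidx <- 0L
  next_seed <- function() {
    sidx <<- sidx + 1L
    seeds[sidx]
  }

  failures <- 0L
  per_model <- numeric(n_models)
  succ_total <- 0L
  n_total <- 0L
  for (mi in seq_len(n_models)) {
    model <- penetrance_model(maf, h2, seed = next_seed())
    succ <- 0L
    n_ok <- 0L
    for (di in seq_len(n_datasets)) {
      s <- next_seed()
      res <- tryCatch(
        run_method_once(model, config, method, adjust, folds, repeats,
                        alpha, seed = s),
        error = function(e) NA
      )
      if (is.na(res)) {
        failures <- failures + 1L
      } else {
        n_ok <- n_ok + 1L
        succ <- succ + res
      }
    }
    per_model[mi] <- if (n_ok > 0) succ / n_ok else NA_real_
    succ_total <- succ_total + succ
    n_total <- n_total + n_ok
  }
  if (failures > 0) {
    warning(failures, " dataset-level method failure(s) excluded",
            call. = FALSE)
  }
  p <- mean(per_model, na.rm = TRUE)
  tibble::tibble(
    maf = maf, h2 = h2, method = method, gamma = gamma, adjust = adjust,
    n_models = n_models, n_datasets = n_datasets,
    power = p,
    se = sqrt(p * (1 - p) / max(n_total, 1)),
    per_model = list(per_model),
    failures = failures
  )
}

# One simulated dataset -> did the method recover the causal pair?
run_method_once <- function(model, config, method, adjust, folds, repeats,
                            alpha, seed) {
  ch <- simulate_cohort(model, config, seed = seed)
  truth <- sort(cohort_truth(ch)$causal)
  covs <- if (adjust) "z" else character(0)
  if (method == "coxreg") {
    p1 <- cox_snp_test(ch, truth[1], covariates = covs)$p.value
    p2 <- cox_snp_test(ch, truth[2], covariates = covs)$p.value
    return(as.integer(p1 < alpha && p2 < alpha))
  }
  search <- mdr_search(ch, k = 2, folds = folds, repeats = repeats,
                       covariates = covs, seed = seed,
                       method = if (method == "coxmdr") "coxmdr" else "survmdr")
  as.integer(identical(sort(search$snp_idx[[1]]), truth))
}

#' Type-I error of the Cox-MDR search under the global null
#'
#' Generates null datasets in which no SNP carries information about
#' survival: cohorts are simulated as in [estimate_power()] (survival still
#' depends on the latent risk status drawn from the penetrance model), but
#' the two causal genotype columns are removed. The type-I error is the
#' fraction of datasets in which one fixed, pre-designated null pair is
#' returned as the best two-way model. Under exchangeability of the null
#' SNPs this rate is `1 / choose(M, 2)` — about 0.022 in the 10-SNP
#' (45-pair) geometry and 0.036 in the 8-SNP one.
#'
#' @param n_null_datasets Total null datasets, spread evenly over the
#'   MAF-by-heritability model grid (default 800 = 40 models x 20).
#' @param geometry `"10snp"` replaces the two causal columns by fresh null
#'   SNPs, preserving the 45-pair search geometry; `"8snp"` drops them.
#' @param gamma,adjust,folds,repeats,mafs,h2s,n_models As in
#'   [estimate_power()] / [penetrance_grid()].
#' @param seed Master seed.
#' @return One-row tibble with the `type1` estimate, its binomial `se`, the
#'   number of datasets and the geometry.
#' @export
estimate_type1 <- function(n_null_datasets = 800, geometry = c("10snp", "8snp"),
                           gamma = 0, adjust = FALSE, folds = 10, repeats = 10,
                           mafs = c(0.2, 0.4), h2s = c(0.1, 0.2, 0.3, 0.4),
                           n_models = 5, seed = 1L) {
  geometry <- match.arg(geometry)
  grid <- penetrance_grid(mafs, h2s, n_models, seed = seed)
  per_model <- ceiling(n_null_datasets / nrow(grid))
  config <- sim_config(gamma = gamma)
  seeds <- child_seeds(seed + 1L, nrow(grid) * per_model)
  covs <- if (adjust) "z" else character(0)

  hits <- 0L
  n_done <- 0L
  failures <- 0L
  for (gi in seq_len(nrow(grid))) {
    model <- grid$model[[gi]]
    for (di in seq_len(per_model)) {
      if (n_done + failures >= n_null_datasets) break
      s <- seeds[(gi - 1L) * per_model + di]
      res <- tryCatch({
        ch <- simulate_cohort(model, config, seed = s)
        ch <- nullify_causal(ch, geometry, seed = s)
        designated <- cohort_truth(ch)$designated
        search <- mdr_search(ch, k = 2, folds = folds, repeats = repeats,
                             covariates = covs, seed = s)
        as.integer(identical(sort(search$snp_idx[[1]]), designated))
      }, error = function(e) NA_integer_)
      if (is.na(res)) failures <- failures + 1L else {
        hits <- hits + res
        n_done <- n_done + 1L
      }
    }
  }
  if (failures > 0) {
    warning(failures, " null dataset(s) failed and were excluded", call. = FALSE)
  }
  p <- hits / n_done
  tibble::tibble(
    type1 = p, se = sqrt(p * (1 - p) / n_done), n_datasets = n_done,
    geometry = geometry, n_pairs = choose(
      if (geometry == "10snp") 10 else 8, 2),
    failures = failures
  )
}

# Remove the survival signal carried by the causal columns: replace them by
# fresh HWE null SNPs (10-SNP geometry) or drop them (8-SNP geometry). The
# pre-designated pair for the type-I criterion is the causal columns'
# positions (10snp) or the first two remaining columns (8snp); under
# exchangeability any fixed choice is equivalent.
nullify_causal <- function(ch, geometry, seed) {
  truth <- cohort_truth(ch)
  covn <- covariate_cols(ch)
  snps <- snp_cols(ch)
  w <- hwe_probs(truth$model$maf)
  causal <- sort(truth$causal)
  d <- tibble::as_tibble(ch)
  if (geometry == "10snp") {
    fresh <- withr::with_seed(seed + 1L, matrix(
      sample.int(3, nrow(d) * 2, replace = TRUE, prob = w) - 1L,
      nrow(d), 2))
    d[[snps[causal[1]]]] <- fresh[, 1]
    d[[snps[causal[2]]]] <- fresh[, 2]
    designated <- causal
    keep <- snps
  } else {
    keep <- snps[-causal]
    d <- d[, c("id", "time", "status", covn, keep)]
    designated <- c(1L, 2L)
  }
  new_cohort(d, snp_cols = keep, covariate_cols = covn,
             truth = list(designated = designated, model = truth$model,
                          config = truth$config))
}
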