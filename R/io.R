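#' Read a cohort from phenotype and genotype files
#'
#' The phenotype file is a tab-delimited table with header columns
#' `id`, `time`, `status` and any number of numeric covariates. The genotype
#' file is either (a) a tab-delimited table with header `id` followed by SNP
#' columns coded as minor-allele counts 0/1/2 with `NA` for missing, or (b) a
#' PLINK `.raw` additive-coding export (`FID IID PAT MAT SEX PHENOTYPE` then
#' one dosage column per SNP; detected by the `.raw` extension or the
#' `FID IID` header). Subjects are matched by id and returned in phenotype
#' order; unmatched ids on either side are reported. SNP columns that are
#' entirely missing are excluded with a warning. Validation failures (times,
#' status codes, genotype codes, duplicated ids) are hard errors naming the
#' offending subject or column.
#'
#' @param phenotype_path,genotype_path File paths.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(phenotype_path, genotype_path) {
  # parse via character + strtod: correctly rounded, so text round-trips
  pheno <- readr::read_tsv(phenotype_path, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  num <- setdiff(names(pheno), "id")
  pheno[num] <- lapply(pheno[num], as.numeric)
  need <- c("id", "time", "status")
  if (!all(need %in% names(pheno))) {
    stop("phenotype file must have columns id, time, status", call. = FALSE)
  }
  pheno$id <- as.character(pheno$id)
  geno <- read_genotypes(genotype_path)

  unmatched_p <- setdiff(pheno$id, geno$id)
  unmatched_g <- setdiff(geno$id, pheno$id)
  if (length(unmatched_p) || length(unmatched_g)) {
    warning(length(unmatched_p), " phenotype and ", length(unmatched_g),
            " genotype subject(s) unmatched and dropped", call. = FALSE)
  }
  keep <- intersect(pheno$id, geno$id)
  if (length(keep) == 0) stop("no subjects shared between the two files",
                              call. = FALSE)
  pheno <- pheno[match(keep, pheno$id), , drop = FALSE]
  geno <- geno[match(keep, geno$id), , drop = FALSE]

  snps <- setdiff(names(geno), "id")
  all_na <- vapply(geno[snps], function(v) all(is.na(v)), logical(1))
  if (any(all_na)) {
    warning(sum(all_na), " SNP column(s) entirely missing excluded: ",
            paste(utils::head(snps[all_na], 5), collapse = ", "),
            call. = FALSE)
    snps <- snps[!all_na]
  }
  covariates <- setdiff(names(pheno), need)
  d <- dplyr::bind_cols(pheno, geno[snps])
  ch <- cohort(d, snps = snps, covariates = covariates)
  validate_cohort(ch)
  ch
}

read_genotypes <- function(path) {
  header <- readLines(path, n = 1)
  is_raw <- grepl("\\.raw$", path) ||
    grepl("^FID[ \t]+IID", header)
  if (is_raw) {
    g <- readr::read_table(path, show_col_types = FALSE, progress = FALSE,
                           na = c("NA", "-9", ""))
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(g))) {
      stop("PLINK .raw file lacks the standard FID..PHENOTYPE columns",
           call. = FALSE)
    }
    out <- g[, setdiff(names(g), meta), drop = FALSE]
    out <- dplyr::bind_cols(tibble::tibble(id = as.character(g$IID)), out)
    out
  } else {
    g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
    if (!"id" %in% names(g)) {
      stop("genotype file must have an id column", call. = FALSE)
    }
    num <- setdiff(names(g), "id")
    g[num] <- lapply(g[num], as.numeric)
    g
  }
}

#' Write a cohort to phenotype and genotype files
#'
#' Inverse of [read_cohort()]: tab-delimited, UTF-8, `NA` for missing. The
#' written pair re-reads to an identical cohort.
#'
#' @param data A [cohort()].
#' @param phenotype_path,genotype_path Output paths.
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, phenotype_path, genotype_path) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  pheno <- tibble::as_tibble(data)[, c("id", "time", "status",
                                       covariate_cols(data))]
  geno <- tibble::as_tibble(data)[, c("id", snp_cols(data))]
  # %.17g preserves doubles exactly, making write -> read -> write a fixed
  # point on the text
  fmt <- function(d) {
    dbl <- vapply(d, is.double, logical(1))
    d[dbl] <- lapply(d[dbl], function(x)
      ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
    d
  }
  readr::write_tsv(fmt(pheno), phenotype_path, na = "NA", progress = FALSE)
  readr::write_tsv(fmt(geno), genotype_path, na = "NA", progress = FALSE)
  invisible(data)
}

#' Kaplan-Meier coordinates for the high/low-risk attribute
#'
#' Computes the Kaplan-Meier survival curves of the predicted high- and
#' low-risk groups of an attribute (e.g. the best model of a search) along
#' with the two-group log-rank p-value — the coordinates behind the
#' survival-curve figures that accompany an MDR analysis. Exported as data,
#' not images; see [autoplot.coxmdr_km()] for plotting.
#'
#' @param data A [cohort()].
#' @param attribute A `coxmdr_attribute` from [mdr_attribute()], or a logical
#'   vector of per-subject high/low predictions.
#' @return A `coxmdr_km` tibble with columns `group` ("high"/"low"), `time`,
#'   `survival`, `n_risk`, `n_event`; attribute `logrank_p`.
#' @export
km_curves <- function(data, attribute) {
  stopifnot(inherits(data, "coxmdr_cohort"))
  high <- if (inherits(attribute, "coxmdr_attribute")) {
    attribute$subject_high
  } else {
    attribute
  }
  stopifnot(length(high) == nrow(data))
  keep <- !is.na(high)
  grp <- factor(ifelse(high[keep], "high", "low"), levels = c("high", "low"))
  fit <- survival::survfit(
    survival::Surv(data$time[keep], data$status[keep]) ~ grp)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  out <- tibble::tibble(
    group = sub("^grp=", "", strata),
    time = fit$time,
    survival = fit$surv,
    n_risk = fit$n.risk,
    n_event = fit$n.event
  )
  p <- if (length(unique(grp)) == 2 && sum(data$status[keep]) > 0) {
    logrank_test(data$time[keep], data$status[keep], grp == "high")$p_value
  } else {
    NA_real_
  }
  structure(out, logrank_p = p,
            class = c("coxmdr_km", class(out)))
}
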