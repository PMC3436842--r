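#' Assemble a survival cohort with genotypes
#'
#' A cohort is a tibble holding one row per subject: an identifier, the
#' observed time `T = min(T*, C*)`, the event indicator `status` (1 = event
#' observed, 0 = censored), optional numeric covariates, and SNP genotypes
#' coded as minor-allele counts 0/1/2 (`NA` allowed). Which columns are
#' covariates and which are SNPs is recorded in attributes so downstream
#' functions need no repeated column selection.
#'
#' @param data A data frame with one row per subject.
#' @param time,status,id Names of the time, event-indicator and subject-id
#'   columns. If `id` is absent a sequential id is created.
#' @param snps Character vector of SNP column names. Defaults to every column
#'   (other than id/time/status/covariates) whose non-missing values all lie
#'   in `{0, 1, 2}`.
#' @param covariates Character vector of covariate column names
#'   (default none).
#' @return A tibble of class `coxmdr_cohort` with attributes `snp_cols` and
#'   `covariate_cols`.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), status = c(1, 1, 0),
#'                 age = c(50, 61, 47), snp1 = c(0, 1, 2))
#' ch <- cohort(d, covariates = "age")
#' snp_cols(ch)
#' @export
cohort <- function(data, time = "time", status = "status", id = "id",
                   snps = NULL, covariates = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  for (col in c(time, status)) {
    if (!col %in% names(data)) stop("column '", col, "' not found", call. = FALSE)
  }
  if (!id %in% names(data)) {
    data[[id]] <- paste0("s", seq_len(nrow(data)))
  }
  out <- dplyr::rename(data, id = !!id, time = !!time, status = !!status)
  covariates <- covariates %||% character(0)
  missing_cov <- setdiff(covariates, names(out))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(snps)) {
    candidates <- setdiff(names(out), c("id", "time", "status", covariates))
    looks_geno <- vapply(candidates, function(cl) {
      v <- out[[cl]]
      is.numeric(v) && all(v %in% c(0, 1, 2) | is.na(v))
    }, logical(1))
    snps <- candidates[looks_geno]
  }
  out <- dplyr::relocate(out, "id", "time", "status",
                         dplyr::all_of(covariates), dplyr::all_of(snps))
  new_cohort(out, snp_cols = snps, covariate_cols = covariates)
}

new_cohort <- function(data, snp_cols, covariate_cols, truth = NULL) {
  structure(
    tibble::as_tibble(data),
    snp_cols = snp_cols,
    covariate_cols = covariate_cols,
    truth = truth,
    class = c("coxmdr_cohort", class(tibble::tibble()))
  )
}

#' @rdname cohort
#' @param x A `coxmdr_cohort`.
#' @export
snp_cols <- function(x) attr(x, "snp_cols")

#' @rdname cohort
#' @export
covariate_cols <- function(x) attr(x, "covariate_cols")

#' @rdname cohort
#' @export
cohort_truth <- function(x) attr(x, "truth")

#' Extract the genotype matrix of a cohort
#'
#' @param x A `coxmdr_cohort`.
#' @return Numeric matrix (subjects x SNPs) of minor-allele counts, with SNP
#'   names as column names.
#' @export
snp_matrix <- function(x) {
  cols <- snp_cols(x)
  m <- as.matrix(x[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Extract the covariate matrix of a cohort
#'
#' @param x A `coxmdr_cohort`.
#' @param covariates Optional subset of covariate column names; defaults to
#'   all covariates recorded in the cohort.
#' @return Numeric matrix (subjects x covariates); zero columns when none.
#' @export
covariate_matrix <- function(x, covariates = NULL) {
  cols <- covariates %||% covariate_cols(x)
  missing_cov <- setdiff(cols, names(x))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(x[, cols, drop = FALSE])
  if (length(cols)) storage.mode(m) <- "double"
  m
}

#' Validate cohort invariants
#'
#' Checks that times are positive, the event indicator is binary, genotypes
#' lie in `{0, 1, 2, NA}` and subject ids are unique. Violations are hard
#' errors naming the offending subject or column.
#'
#' @param x A `coxmdr_cohort`.
#' @return `x`, invisibly, when valid.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "coxmdr_cohort"))
  bad_time <- which(!is.finite(x$time) | x$time <= 0)
  if (length(bad_time)) {
    stop("non-positive or missing time for subject(s): ",
         paste(x$id[utils::head(bad_time, 5)], collapse = ", "), call. = FALSE)
  }
  bad_status <- which(!x$status %in% c(0, 1))
  if (length(bad_status)) {
    stop("status must be 0/1; offending subject(s): ",
         paste(x$id[utils::head(bad_status, 5)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$id)) {
    stop("duplicated subject id(s): ",
         paste(unique(x$id[duplicated(x$id)])[1:1], collapse = ", "),
         call. = FALSE)
  }
  for (cl in snp_cols(x)) {
    v <- x[[cl]]
    bad <- which(!(v %in% c(0, 1, 2) | is.na(v)))
    if (length(bad)) {
      stop("genotype not in {0,1,2,NA} at column '", cl, "', subject ",
           x$id[bad[1]], call. = FALSE)
    }
  }
  for (cl in covariate_cols(x)) {
    if (!is.numeric(x[[cl]])) {
      stop("covariate column '", cl, "' is not numeric", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.coxmdr_cohort <- function(x, ...) {
  cat(sprintf("<coxmdr_cohort> %d subjects, %d SNPs, %d covariate(s), %d events\n",
              nrow(x), length(snp_cols(x)), length(covariate_cols(x)),
              sum(x$status == 1)))
  NextMethod()
}
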