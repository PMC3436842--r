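#' Plot Kaplan-Meier curves of the high/low-risk groups
#'
#' @param object A `coxmdr_km` from [km_curves()].
#' @param ... Unused.
#' @return A ggplot with one step curve per risk group; the log-rank p-value
#'   is shown in the subtitle.
#' @export
autoplot.coxmdr_km <- function(object, ...) {
  start <- dplyr::distinct(
    dplyr::mutate(object, time = 0, survival = 1, n_risk = NA, n_event = NA),
    .data$group, .keep_all = TRUE)
  dat <- dplyr::bind_rows(start, tibble::as_tibble(object))
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "survival probability", colour = "risk group",
      subtitle = sprintf("log-rank p = %.4g", attr(object, "logrank_p"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the top models of a combination search
#'
#' @param object A `coxmdr_search`.
#' @param top Number of top-ranked combinations to show.
#' @param ... Unused.
#' @return A ggplot of mean testing score (balanced accuracy or signed
#'   log-rank statistic) with CV-consistency shading.
#' @export
autoplot.coxmdr_search <- function(object, top = 10, ...) {
  dat <- utils::head(tidy(object), top)
  dat$snps <- factor(dat$snps, levels = rev(dat$snps))
  ggplot2::ggplot(dat, ggplot2::aes(.data$mean_test, .data$snps,
                                    fill = .data$cv_consistency)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = if (attr(object, "score") == "balanced_accuracy")
        "mean testing balanced accuracy" else "mean testing log-rank score",
      y = NULL, fill = "CV consistency"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a penetrance function
#'
#' @param object A `penetrance_model`.
#' @param ... Unused.
#' @return A ggplot tile map of the 3x3 penetrance table.
#' @export
autoplot.penetrance_model <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(factor(.data$g1), factor(.data$g2),
                                    fill = .data$f)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$f))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(
      x = "locus 1 minor-allele count", y = "locus 2 minor-allele count",
      fill = "penetrance",
      subtitle = sprintf("MAF %.2f, h² %.2f, K %.3f",
                         object$maf, object$h2, object$prevalence)
    ) +
    ggplot2::theme_minimal()
}
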