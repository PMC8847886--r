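#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a variance-explained profile
#'
#' Observed per-mode variance explained (percent) in the connectome and SM
#' matrices, with the 5th-95th percentile band and mean of the permutation
#' null, faceted by view.
#'
#' @param object a [variance_profile()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pn_variance_profile <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(mode = object$mode, view = "connectome",
                   ve = 100 * object$ve_conn, p5 = 100 * object$p5_conn,
                   p95 = 100 * object$p95_conn),
    tibble::tibble(mode = object$mode, view = "subject measures",
                   ve = 100 * object$ve_sm, p5 = 100 * object$p5_sm,
                   p95 = 100 * object$p95_sm)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ve), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$ve), colour = "steelblue") +
    ggplot2::facet_wrap(~view, scales = "free_y") +
    ggplot2::labs(x = "CCA mode", y = "variance explained (%)",
                  title = "Variance explained vs. permutation null (5th-95th pct)") +
    ggplot2::theme_minimal()
}

#' Plot a positive-negative axis
#'
#' SMs ordered by their correlation with the primary-mode variate;
#' held-out SMs (not in the CCA) are shown in grey. A display threshold
#' can blank out weak correlations.
#'
#' @param object a `pn_axis` tibble from [positive_negative_axis()].
#' @param threshold display threshold on `|r|` (default 0.2; use 0 for the
#'   unthresholded axis).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pn_axis <- function(object, threshold = 0.2, ...) {
  df <- dplyr::filter(object, abs(.data$r) >= threshold)
  df$sm_name <- factor(df$sm_name, levels = rev(df$sm_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$sm_name,
                                   colour = .data$included_in_cca,
                                   size = .data$pct_variance)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey50"),
                                 name = "in CCA") +
    ggplot2::scale_size_continuous(name = "% variance") +
    ggplot2::labs(x = "correlation with primary-mode SM variate", y = NULL,
                  title = "Positive-negative axis") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation report
#'
#' Per-repetition held-out correlations with the across-repetition mean.
#'
#' @param object a `pn_cv` tibble from [repeated_cv()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pn_cv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$rep), y = .data$r_test)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "mean_r"), linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "repetition", y = "held-out r(U_test, V_test)",
                  title = "Family-respecting train/test cross-validation") +
    ggplot2::theme_minimal()
}
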