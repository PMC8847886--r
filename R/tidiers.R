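#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CCA fit
#'
#' One row per canonical mode with its canonical correlation; if a
#' permutation null is supplied, familywise-error p-values are added.
#'
#' @param x a [fit_cca()] result.
#' @param null optional [permutation_null()] result.
#' @param ... unused.
#' @return a tibble with columns `mode`, `r` (and `p_fwe`).
#' @export
tidy.cca_fit <- function(x, null = NULL, ...) {
  mode_weight_correlations(x, null = null)
}

#' Glance at a CCA fit
#'
#' @param x a [fit_cca()] result.
#' @param ... unused.
#' @return a one-row tibble with `n`, `d`, `r_first`.
#' @export
glance.cca_fit <- function(x, ...) {
  tibble::tibble(n = x$n, d = x$d, r_first = x$r[1])
}

#' Tidy a pipeline result
#'
#' The per-mode variance/significance table of a [run_pipeline()] result.
#'
#' @param x a `pn_result`.
#' @param ... unused.
#' @return the `pn_variance_profile` tibble.
#' @export
tidy.pn_result <- function(x, ...) {
  x$variance
}

#' Glance at a pipeline result
#'
#' @param x a `pn_result`.
#' @param ... unused.
#' @return one-row tibble with subject count, dimensionality, primary mode,
#'   its canonical correlation and FWE p, and the CV mean test r (if run).
#' @export
glance.pn_result <- function(x, ...) {
  pm <- x$primary_mode
  tibble::tibble(
    n = x$fit$n, d = x$fit$d, primary_mode = pm,
    r_primary = x$variance$r[pm], p_fwe_primary = x$variance$p_fwe[pm],
    cv_mean_r = if (!is.null(x$cv)) attr(x$cv, "mean_r") else NA_real_
  )
}
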