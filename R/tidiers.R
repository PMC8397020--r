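#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Mann-Whitney U test
#'
#' @param x An `mwu_test` from [mann_whitney_u()].
#' @param ... Unused.
#' @return A one-row tibble with `U`, `U1`, `n1`, `n2`, `p_value` and
#'   `method`.
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble::tibble(U = x$U, U1 = x$U1, n1 = x$n1, n2 = x$n2,
                 p_value = x$p_two_sided, method = x$method_used)
}

#' @rdname tidy.mwu_test
#' @export
glance.mwu_test <- function(x, ...) {
  tibble::tibble(n1 = x$n1, n2 = x$n2, mean1 = x$mean1, sd1 = x$sd1,
                 mean2 = x$mean2, sd2 = x$sd2, U = x$U,
                 p_value = x$p_two_sided, method = x$method_used)
}

#' Tidy a Spearman correlation
#'
#' @param x A `spearman_cor` from [spearman_rho()].
#' @param ... Unused.
#' @return A one-row tibble with `rho`, `n`, `p_value` and `band`.
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble::tibble(rho = x$rho, n = x$n, p_value = x$p_two_sided,
                 band = x$band)
}

#' Tidy a cohort report
#'
#' @param x A `cohort_report` from [summarize_cohort()].
#' @param ... Unused.
#' @return `tidy()`: the per-ROI, per-feature comparisons tibble.
#'   `glance()`: the per-ROI TTP-vs-ABI correlation tibble.
#' @export
tidy.cohort_report <- function(x, ...) x$comparisons

#' @rdname tidy.cohort_report
#' @export
glance.cohort_report <- function(x, ...) x$correlations
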