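#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the variance components of a mixed-model fit
#'
#' @param x An `lmm_fit` from [fit_null_lmm()].
#' @param ... Unused.
#' @return A tibble with one row per variance-component term.
#' @exportS3Method generics::tidy
tidy.lmm_fit <- function(x, ...) {
  tibble(term = c("lambda", "h2", "sigma2"),
         estimate = c(x$lambda, x$h2, x$sigma2))
}

#' One-row summary of a mixed-model fit
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.lmm_fit <- function(x, ...) {
  tibble(lambda = x$lambda, h2 = x$h2, sigma2 = x$sigma2,
         log_reml = x$log_reml, nobs = x$n)
}

#' Tidy a significance plan
#'
#' @param x A `significance_plan` from [significance_threshold()].
#' @param ... Unused.
#' @return A tibble of terms and estimates.
#' @exportS3Method generics::tidy
tidy.significance_plan <- function(x, ...) {
  tibble(term = c("n_eff", "m_eff", "m_eff_reported", "alpha", "threshold"),
         estimate = c(x$n_eff, x$m_eff, x$m_eff_reported, x$alpha,
                      x$threshold))
}

#' One-row summary of a significance plan
#'
#' @param x A `significance_plan`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.significance_plan <- function(x, ...) {
  tibble(n_eff = x$n_eff, m_eff = x$m_eff,
         m_eff_reported = x$m_eff_reported, alpha = x$alpha,
         threshold = x$threshold)
}
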