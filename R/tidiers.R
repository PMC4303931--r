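#' Tidy a hierarchical Bayes meta-regression fit
#'
#' @param x A `"psf_hblm"` object from [fit_hblm()] or [fit_fixed()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`.
#' @export
tidy.psf_hblm <- function(x, ...) x$beta

#' One-row model summary
#'
#' @inheritParams tidy.psf_hblm
#' @return A tibble with `model`, `N`, `k`, `df`, `level` and (for the
#'   hierarchical model) the posterior mean of tau^2.
#' @export
glance.psf_hblm <- function(x, ...) {
  tibble::tibble(model = x$model_tag, N = x$N, k = x$k, df = x$df,
                 level = x$level,
                 tau2 = if (x$model_tag == "hierarchical")
                   x$tau2_posterior_mean else 0)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
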