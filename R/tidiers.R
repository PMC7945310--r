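#' Tidy a Gaussian mixture fit
#'
#' One row per component: weight, mean, variance and role.
#'
#' @param x A `be_mixture`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy be_mixture
#' @export
tidy.be_mixture <- function(x, ...) {
  x$components
}

#' Glance at a Gaussian mixture fit
#'
#' @param x A `be_mixture`.
#' @param ... Unused.
#' @return One-row tibble with fit summaries.
#' @method glance be_mixture
#' @export
glance.be_mixture <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, logLik = x$loglik, AIC = x$AIC, BIC = x$BIC,
    converged = x$converged, negative_fallback = x$negative_fallback
  )
}

#' Tidy a LOF classification
#'
#' @param x A `be_classification`.
#' @param ... Unused.
#' @return The calls tibble.
#' @method tidy be_classification
#' @export
tidy.be_classification <- function(x, ...) {
  x$calls
}

#' Glance at a LOF classification
#' @param x A `be_classification`.
#' @param ... Unused.
#' @return One-row tibble: counts, threshold and equivalent beta cutoff.
#' @method glance be_classification
#' @export
glance.be_classification <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$calls),
    n_lof = sum(x$calls$lof_call),
    threshold = x$threshold,
    beta_cutoff = x$beta_cutoff
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
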