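#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted spacing model
#'
#' One row per mixture component with its mean gap, rate and weight.
#'
#' @param x a `spacing_model`.
#' @param ... unused.
#' @return A tibble with columns `component`, `mean_gap`, `rate`, `weight`.
#' @export
tidy.spacing_model <- function(x, ...) {
  tibble::tibble(component = c("target", "background"),
                 mean_gap = c(x$mean_target, x$mean_background),
                 rate = c(x$rate_target, x$rate_background),
                 weight = c(x$mixing_weight, 1 - x$mixing_weight))
}

#' @rdname tidy.spacing_model
#' @export
glance.spacing_model <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood,
                 iterations = x$iterations,
                 converged = x$converged,
                 mean_ratio = x$mean_ratio,
                 no_signal = x$no_signal,
                 n_gaps = x$n_gaps)
}

#' Glance at a concordance report
#'
#' @param x a `concordance` object.
#' @param ... unused.
#' @return One-row tibble: `n_matched`, `median_breakpoint_diff`,
#'   `region_recovery`, `n_only_regions`, `n_only_segments`.
#' @export
glance.concordance <- function(x, ...) {
  tibble::tibble(n_matched = nrow(x$matches),
                 median_breakpoint_diff = x$median_breakpoint_diff,
                 region_recovery = x$region_recovery,
                 n_only_regions = nrow(x$only_regions),
                 n_only_segments = nrow(x$only_segments))
}

#' @rdname glance.concordance
#' @export
tidy.concordance <- function(x, ...) x$matches
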