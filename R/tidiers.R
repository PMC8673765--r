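# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a zone-production fit
#'
#' @param x A `zone_fit` from [fit_production()].
#' @param ... Unused.
#' @return A tibble with one row per zone: `zone`, `top`, `bottom`, `rate`
#'   (umol L-1 hr-1).
#' @export
tidy.zone_fit <- function(x, ...) {
  dplyr::mutate(x$zones, zone = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.zone_fit
#' @return For `glance`: a one-row tibble with `k`, `sse`, `flux_top`,
#'   `flux_bottom`, `n_obs`, `alpha`.
#' @export
glance.zone_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, sse = x$sse, flux_top = x$flux_top,
    flux_bottom = x$flux_bottom, n_obs = nrow(x$data), alpha = x$alpha
  )
}

#' Tidy a Keeling fit
#'
#' @param x A `keeling_fit` from [keeling_intercept()].
#' @param ... Unused.
#' @return A tibble with rows for intercept and slope; the intercept row
#'   carries the bootstrap confidence bounds.
#' @export
tidy.keeling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(x$ci[1], NA_real_),
    conf.high = c(x$ci[2], NA_real_)
  )
}

#' @rdname tidy.keeling_fit
#' @return For `glance`: a one-row tibble with `intercept`, `conf.low`,
#'   `conf.high`, `n`, `n_boot`.
#' @export
glance.keeling_fit <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept, conf.low = x$ci[1], conf.high = x$ci[2],
    n = x$n, n_boot = x$n_boot
  )
}
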