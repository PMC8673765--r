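# Continuous-flow core-incubation flux arithmetic, delta-notation handling,
# Keeling-plot endmember regression and two-endmember mixing.

#' Sediment-water fluxes from continuous-flow core incubations
#'
#' For a core incubated under continuous flow, the solute flux across the
#' sediment-water interface is the inflow-outflow concentration difference
#' times the flow rate, divided by the core's surface area:
#' `flux = (c_out - c_in) * flow / area`, converted to umol m-2 hr-1.
#' Positive fluxes are a release from the sediment to the overlying water;
#' negative fluxes are uptake.
#'
#' @param records Data frame with columns `c_in`, `c_out` (umol L-1),
#'   `flow_ml_min` (mL min-1) and `diameter_cm` (inner core diameter, cm).
#'   Any other columns (core id, site, treatment, analyte, time) are carried
#'   through.
#' @return The input as a tibble with a `flux` column, umol m-2 hr-1.
#' @export
#' @examples
#' core_flux(data.frame(
#'   c_in = 10, c_out = 12, flow_ml_min = 1.5, diameter_cm = 6.4
#' ))
core_flux <- function(records) {
  stopifnot(
    all(c("c_in", "c_out", "flow_ml_min", "diameter_cm") %in% names(records))
  )
  if (any(records$flow_ml_min <= 0)) {
    stop("flow rate must be positive", call. = FALSE)
  }
  if (any(records$diameter_cm <= 0)) {
    stop("core diameter must be positive", call. = FALSE)
  }
  records |>
    tibble::as_tibble() |>
    dplyr::mutate(
      flux = (.data$c_out - .data$c_in) *
        (.data$flow_ml_min * 1e-3 * 60) / # L hr-1
        (pi * (.data$diameter_cm / 200)^2) # m2
    )
}

#' Summarise replicate fluxes with a zero-mean test
#'
#' Groups fluxes, reports mean and standard deviation, and tests the group
#' mean against zero with a two-sided one-sample Wilcoxon signed-rank test
#' (the nonparametric choice used for the site's flux comparisons).
#'
#' @param data Data frame containing a flux column.
#' @param flux Column name holding the fluxes (default `flux`).
#' @param ... Grouping columns (tidy-select), e.g. `site, treatment`.
#' @return A tibble with `n`, `mean`, `sd`, `p_zero` per group, plus a
#'   formatted `label` ("mean +/- sd").
#' @export
replicate_summary <- function(data, ..., flux = "flux") {
  stopifnot(flux %in% names(data))
  grouped <- dplyr::group_by(tibble::as_tibble(data), ...)
  out <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    mean = mean(.data[[flux]]),
    sd = stats::sd(.data[[flux]]),
    p_zero = if (dplyr::n() >= 2) {
      tryCatch(
        suppressWarnings(
          stats::wilcox.test(.data[[flux]], mu = 0, exact = FALSE)$p.value
        ),
        error = function(e) NA_real_
      )
    } else {
      NA_real_
    },
    .groups = "drop"
  )
  if (any(out$n < 2)) {
    stop("replicate_summary needs at least 2 replicates per group",
      call. = FALSE
    )
  }
  dplyr::mutate(
    out,
    label = sprintf("%.0f ± %.0f", .data$mean, .data$sd)
  )
}

#' Keeling-plot endmember regression
#'
#' Regresses the isotope ratio of a mixed pool against its inverse
#' concentration. Under two-endmember mixing of a background pool with an
#' added source, delta is exactly linear in 1/concentration and the
#' intercept is the isotopic signature of the added source. The intercept's
#' confidence interval is estimated by a seeded nonparametric bootstrap
#' (resampling sample pairs).
#'
#' @param samples Data frame with columns `delta` (permil vs VPDB) and
#'   `conc` (umol kg-1); an optional logical `include` column masks samples
#'   out of the fit (e.g. a separately treated DIC-maximum zone).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level of the percentile interval.
#' @param seed Integer seed for the bootstrap; `NULL` uses the current RNG
#'   state.
#' @return An object of class `keeling_fit`: list with `intercept`, `slope`,
#'   `ci` (length-2), `n`, `fitted`, `data`, `n_boot`, `conf`.
#' @export
keeling_intercept <- function(samples, n_boot = 1000, conf = 0.95,
                              seed = NULL) {
  stopifnot(all(c("delta", "conc") %in% names(samples)))
  s <- tibble::as_tibble(samples)
  if ("include" %in% names(s)) s <- s[as.logical(s$include), ]
  if (nrow(s) < 3) {
    stop("a Keeling fit needs at least 3 included samples", call. = FALSE)
  }
  x <- 1 / s$conc
  y <- s$delta
  if (max(x) - min(x) < .Machine$double.eps * max(abs(x), 1)) {
    stop("degenerate Keeling plot: all concentrations equal", call. = FALSE)
  }
  ols <- function(x, y) {
    mx <- mean(x)
    my <- mean(y)
    slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
    c(intercept = my - slope * mx, slope = slope)
  }
  est <- ols(x, y)

  boot_fun <- function() {
    n <- length(x)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n)
    yb <- matrix(y[idx], nrow = n)
    mx <- colMeans(xb)
    my <- colMeans(yb)
    dx <- sweep(xb, 2, mx)
    sl <- colSums(dx * sweep(yb, 2, my)) / colSums(dx^2)
    my - sl * mx
  }
  boots <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())
  boots <- boots[is.finite(boots)]
  ci <- stats::quantile(
    boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
    names = FALSE
  )

  structure(
    list(
      intercept = unname(est["intercept"]),
      slope = unname(est["slope"]),
      ci = ci,
      n = length(x),
      fitted = est["intercept"] + est["slope"] * x,
      data = s,
      n_boot = n_boot,
      conf = conf
    ),
    class = "keeling_fit"
  )
}

#' @export
print.keeling_fit <- function(x, ...) {
  cat(sprintf(
    "Keeling endmember: %.2f permil (%d%% CI %.2f to %.2f, n = %d)\n",
    x$intercept, round(100 * x$conf), x$ci[1], x$ci[2], x$n
  ))
  invisible(x)
}

#' Two-endmember isotope mixing fraction
#'
#' Fraction of endmember `a` in a mixture:
#' `f = (delta_mix - delta_b) / (delta_a - delta_b)`. Values outside [0, 1]
#' indicate the mixture is not explicable by the two endmembers; they are
#' returned as computed with a warning.
#'
#' @param delta_mix,delta_a,delta_b Isotope values, permil.
#' @return Fraction of endmember `a` (dimensionless).
#' @export
#' @examples
#' mixing_fraction(0, 1.9, -18) # carbonate-dissolution share of ~0 permil DIC
mixing_fraction <- function(delta_mix, delta_a, delta_b) {
  if (any(delta_a == delta_b)) {
    stop("mixing endmembers must differ", call. = FALSE)
  }
  f <- (delta_mix - delta_b) / (delta_a - delta_b)
  if (any(f < 0 | f > 1)) {
    warning("mixing fraction outside [0, 1]: endmembers do not bracket the mixture")
  }
  f
}
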