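#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.calibration_fit <- function(x, ...) {
  cf <- summary(x$lm)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1],
    std.error = cf[, 2],
    statistic = cf[, 3],
    p.value = cf[, 4]
  )
}

#' Glance at a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One-row tibble: `slope`, `intercept`, `r.squared`, `sigma`,
#'   `nobs`, `weighting`.
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
    sigma = x$residual_sd, nobs = x$n, weighting = x$weighting
  )
}

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The per-level accuracy/precision tibble.
#' @export
tidy.validation_report <- function(x, ...) x$levels

#' Glance at a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return One-row tibble with the three verdicts and the curve summary.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    pass_accuracy = x$pass_accuracy,
    pass_precision = x$pass_precision,
    pass_linearity = x$pass_linearity,
    r.squared = x$model$r_squared,
    slope = x$model$slope,
    intercept = x$model$intercept,
    n_levels = nrow(x$levels)
  )
}
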