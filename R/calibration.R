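#' Build a calibration series
#'
#' A calibration series is the graded-concentration design used to validate
#' the assay: several nominal concentrations of a reference reducing agent
#' (e.g. sodium thiosulfate or ascorbic acid over 0.01-0.1 M), each spotted
#' several times, with the integrated density of every replicate.
#'
#' @param data A data frame with at least columns `nominal` (mol/L) and
#'   `integrated_density`; any other columns are carried through.
#' @return The data as a tibble with class `calibration_series`, ordered by
#'   `nominal`.
#' @export
calibration_series <- function(data) {
  if (!all(c("nominal", "integrated_density") %in% names(data))) {
    stop("need columns `nominal` and `integrated_density`", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (anyNA(data$nominal) || any(data$nominal <= 0)) {
    stop("nominal concentrations must be positive and known", call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$nominal)
  class(data) <- c("calibration_series", class(data))
  data
}

n_levels <- function(series) length(unique(series$nominal))

#' Fit a linear calibration model
#'
#' Ordinary least squares of integrated density on nominal concentration over
#' all replicates. Unweighted fitting is the default; `weighting = "1/x2"`
#' weights each replicate by the inverse squared concentration, which
#' downweights the upper levels when variance grows with signal.
#'
#' @param series A [calibration_series()] (or a data frame with `nominal`
#'   and `integrated_density`) with at least 3 distinct levels.
#' @param weighting `"none"` (default) or `"1/x2"`.
#' @return A `calibration_fit`: list with `slope` (intensity.px per mol/L),
#'   `intercept`, `r_squared`, `residual_sd`, `n`, `weighting` and the
#'   underlying `lm` fit. Has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @examples
#' s <- calibration_series(data.frame(nominal = rep(c(.01, .05, .1), each = 2),
#'                                    integrated_density = rep(c(1, 5, 10), each = 2)))
#' fit_calibration(s)$slope
#' @export
fit_calibration <- function(series, weighting = c("none", "1/x2")) {
  weighting <- match.arg(weighting)
  if (!inherits(series, "calibration_series")) series <- calibration_series(series)
  if (n_levels(series) < 3L) {
    stop("insufficient data: need at least 3 distinct nominal levels", call. = FALSE)
  }
  w <- if (weighting == "1/x2") 1 / series$nominal^2 else NULL
  fit <- stats::lm(integrated_density ~ nominal, data = series, weights = w)
  sm <- suppressWarnings(summary(fit))
  y <- series$integrated_density
  flat <- stats::sd(y) <= 1e-10 * (abs(mean(y)) + 1)
  slope <- if (flat) 0 else unname(stats::coef(fit)[2])
  r2 <- if (flat) 0 else sm$r.squared
  if (!is.finite(r2)) r2 <- 0   # constant response carries no explained variance
  structure(
    list(
      slope = slope,
      intercept = if (flat) mean(y) else unname(stats::coef(fit)[1]),
      r_squared = r2,
      residual_sd = if (flat) 0 else sm$sigma,
      n = nrow(series),
      weighting = weighting,
      lm = fit
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> density = %.4g + %.4g * c   (R^2 = %.4f, s = %.3g, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$residual_sd, x$n
  ))
  invisible(x)
}

#' Back-calculate concentration from integrated density
#'
#' Inverts the calibration line: `(density - intercept) / slope`. The
#' back-calculated concentration of a level mean, divided by the nominal
#' concentration, is the accuracy measure of bioanalytical validation.
#'
#' @param model A `calibration_fit`.
#' @param density Numeric vector of integrated densities.
#' @return Concentrations in mol/L.
#' @export
back_calculate <- function(model, density) {
  if (!inherits(model, "calibration_fit")) stop("`model` must be a calibration_fit",
                                                call. = FALSE)
  if (abs(model$slope) <= .Machine$double.eps) {
    stop("degenerate model: zero slope cannot be inverted", call. = FALSE)
  }
  (density - model$intercept) / model$slope
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` with the n-1 sample standard deviation — the choice of
#' denominator is material at the 5-6 replicates typical of a membrane
#' series. Scale-invariant: rescaling all replicates leaves it unchanged.
#'
#' @param replicates Numeric vector, length >= 2, with nonzero mean.
#' @return CV as a percentage.
#' @examples
#' cv_percent(c(8, 12)) # 100 * 2*sqrt(2) / 10
#' @export
cv_percent <- function(replicates) {
  if (length(replicates) < 2L) stop("need at least 2 replicates for a CV",
                                    call. = FALSE)
  m <- mean(replicates)
  if (abs(m) <= .Machine$double.eps) stop("CV undefined: zero mean", call. = FALSE)
  100 * stats::sd(replicates) / m
}

#' Validate a calibration series against bioanalytical acceptance rules
#'
#' Computes, per nominal level, the accuracy (back-calculated concentration
#' of the level mean over nominal, x100) and the replicate CV, then applies
#' the acceptance rules of bioanalytical method validation: every level must
#' be accurate to +-15% of nominal and precise to CV <= 15%, relaxed to
#' +-20% / 20% at the lowest level (the LLOQ); the curve must be linear with
#' R^2 at or above `r2_threshold`. All thresholds are overridable.
#'
#' @param series A [calibration_series()].
#' @param accuracy_tol,accuracy_tol_lloq Allowed deviation of accuracy from
#'   100%, in percentage points (default 15 / 20).
#' @param cv_tol,cv_tol_lloq Maximum CV percent (default 15 / 20).
#' @param r2_threshold Minimum R^2 for the linearity verdict (default 0.98).
#' @param weighting Passed to [fit_calibration()].
#' @return A `validation_report`: list with the fitted model, a per-level
#'   tibble (`nominal`, `n`, `mean_density`, `accuracy_percent`,
#'   `cv_percent`, `accuracy_ok`, `cv_ok`, `flags`), the verdicts
#'   `pass_accuracy`, `pass_precision`, `pass_linearity`, and the thresholds
#'   used. Levels with a single replicate have `cv_percent = NA`, are flagged
#'   `single_replicate`, and are excluded from the precision verdict.
#' @export
validate_method <- function(series,
                            accuracy_tol = 15, accuracy_tol_lloq = 20,
                            cv_tol = 15, cv_tol_lloq = 20,
                            r2_threshold = 0.98,
                            weighting = c("none", "1/x2")) {
  if (!inherits(series, "calibration_series")) series <- calibration_series(series)
  model <- fit_calibration(series, weighting = weighting)
  lloq <- min(series$nominal)
  levels <- series |>
    dplyr::group_by(.data$nominal) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_density = mean(.data$integrated_density),
      cv_percent = if (dplyr::n() >= 2) cv_percent(.data$integrated_density)
                   else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      accuracy_percent = 100 * back_calculate(model, .data$mean_density) /
        .data$nominal,
      acc_tol = ifelse(.data$nominal == lloq, accuracy_tol_lloq, accuracy_tol),
      cv_lim = ifelse(.data$nominal == lloq, cv_tol_lloq, cv_tol),
      accuracy_ok = abs(.data$accuracy_percent - 100) <= .data$acc_tol,
      cv_ok = ifelse(is.na(.data$cv_percent), NA, .data$cv_percent <= .data$cv_lim),
      flags = ifelse(.data$n < 2, "single_replicate", "")
    ) |>
    dplyr::select("nominal", "n", "mean_density", "accuracy_percent",
                  "cv_percent", "accuracy_ok", "cv_ok", "flags")
  structure(
    list(
      model = model,
      levels = levels,
      pass_accuracy = all(levels$accuracy_ok),
      pass_precision = all(levels$cv_ok[!is.na(levels$cv_ok)]) &&
        any(!is.na(levels$cv_ok)),
      pass_linearity = model$r_squared >= r2_threshold,
      thresholds = list(accuracy_tol = accuracy_tol,
                        accuracy_tol_lloq = accuracy_tol_lloq,
                        cv_tol = cv_tol, cv_tol_lloq = cv_tol_lloq,
                        r2_threshold = r2_threshold)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$model)
  print(as.data.frame(x$levels), digits = 4)
  cat(sprintf("accuracy: %s   precision: %s   linearity: %s (R^2 >= %.2f)\n",
              ifelse(x$pass_accuracy, "PASS", "FAIL"),
              ifelse(x$pass_precision, "PASS", "FAIL"),
              ifelse(x$pass_linearity, "PASS", "FAIL"),
              x$thresholds$r2_threshold))
  invisible(x)
}

#' Compare two measurement methods by linear regression
#'
#' Regresses one method's readings on the other's (e.g. membrane integrated
#' density against direct electrode redox potential of the same graded
#' samples) and reports the coefficient of determination together with the
#' two-sided p value for zero slope.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite.
#' @return Tibble with one row: `r_squared`, `p_value`, `slope`,
#'   `intercept`, `n`.
#' @export
compare_methods <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite",
                                                     call. = FALSE)
  if (stats::sd(x) <= .Machine$double.eps) {
    stop("degenerate input: x has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless phantoms fit perfectly
  tibble::tibble(
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(x)
  )
}
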