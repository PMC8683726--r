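#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dose-response fit
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(
    term = c("ic50", "amplitude"),
    estimate = c(x$ic50, x$amplitude)
  )
}

#' @rdname tidy.dose_response_fit
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(
    ic50 = x$ic50, amplitude = x$amplitude,
    residual_sse = x$residual_sse, converged = x$converged,
    n_points = x$n_points
  )
}

#' Tidy an elongation-rate fit
#' @param x An `elongation_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy elongation_fit
#' @export
tidy.elongation_fit <- function(x, ...) {
  tibble(
    term = c("rate", "intercept"),
    estimate = c(x$rate, x$intercept)
  )
}

#' @rdname tidy.elongation_fit
#' @method glance elongation_fit
#' @export
glance.elongation_fit <- function(x, ...) {
  tibble(
    rate = x$rate, intercept = x$intercept,
    r_squared = x$r_squared, n_points = x$n_points
  )
}

#' Tidy a ladder calibration
#' @param x A `ladder_calibration`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy ladder_calibration
#' @export
tidy.ladder_calibration <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @rdname tidy.ladder_calibration
#' @method glance ladder_calibration
#' @export
glance.ladder_calibration <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n_rungs = x$n_rungs
  )
}
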