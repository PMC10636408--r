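#' A regularly sampled BOLD time series
#'
#' Lightweight container pairing signal values with their sampling interval.
#' All estimators in the package take a `bold_series`; the sampling interval
#' `dt` is the repetition time (TR) of the acquisition, in seconds.
#'
#' @param values Numeric vector of signal amplitudes (arbitrary units).
#' @param dt Sampling interval in seconds (> 0).
#' @return An object of class `bold_series` with elements `values` and `dt`.
#' @examples
#' x <- bold_series(rnorm(250), dt = 2.13)
#' x$dt
#' @export
bold_series <- function(values, dt) {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite and non-missing")
  structure(list(values = values, dt = dt), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> n = %d, dt = %g s (Nyquist %.4f Hz)\n",
              length(x$values), x$dt, 1 / (2 * x$dt)))
  invisible(x)
}

#' @export
length.bold_series <- function(x) length(x$values)

# Coerce numeric input to bold_series, defaulting dt when given a plain vector.
as_bold_series <- function(x, dt = NULL) {
  if (inherits(x, "bold_series")) return(x)
  if (is.null(dt)) stop("numeric input needs an explicit 'dt'")
  bold_series(x, dt)
}
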