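#' Regularly sampled time series
#'
#' A minimal container pairing a numeric vector with its sampling interval.
#' Most functions in the package accept either a `hant_ts` or a plain numeric
#' vector (in which case the sampling interval is taken from the companion
#' kernel or argument).
#'
#' @param values Numeric vector of samples.
#' @param dt Sampling interval in seconds (strictly positive).
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `hant_ts` with fields `values`, `dt`, `t0`.
#' @examples
#' y <- hant_ts(sin(seq(0, 10, by = 0.5)), dt = 0.5)
#' length(y$values)
#' @export
hant_ts <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("time series must have length >= 1")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  structure(list(values = values, dt = dt, t0 = t0), class = "hant_ts")
}

#' @export
print.hant_ts <- function(x, ...) {
  cat(sprintf("<hant_ts> %d samples, dt = %g s, t0 = %g s\n",
              length(x$values), x$dt, x$t0))
  invisible(x)
}

#' @export
length.hant_ts <- function(x) length(x$values)

# Extract values + dt from either a hant_ts or a plain vector with fallback dt
#' @noRd
ts_values <- function(x) if (inherits(x, "hant_ts")) x$values else as.numeric(x)

#' @noRd
ts_dt <- function(x, default = NULL) {
  if (inherits(x, "hant_ts")) return(x$dt)
  if (is.null(default)) stop("a sampling interval is required for a plain vector")
  default
}
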