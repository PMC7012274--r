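#' Canonical haemodynamic response function parameters
#'
#' Parameters of the canonical Glover double-gamma-style HRF
#' \deqn{h(t) = (t/\tau_1)^{\delta_1} e^{-(\delta_1/\tau_1)(t-\tau_1)}
#'  - c\,(t/\tau_2)^{\delta_2} e^{-(\delta_2/\tau_2)(t-\tau_2)},}
#' the positive lobe peaking near \eqn{\tau_1} seconds and the undershoot
#' (weight `c`) near \eqn{\tau_2} seconds.
#'
#' @param tau1,tau2 Peak times of the response and undershoot lobes (seconds).
#' @param delta1,delta2 Shape exponents of the two lobes (dimensionless).
#' @param c Undershoot weight (dimensionless).
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(tau1 = 5.4, tau2 = 10.8, delta1 = 6, delta2 = 12,
                       c = 0.35) {
  p <- list(tau1 = tau1, tau2 = tau2, delta1 = delta1, delta2 = delta2, c = c)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v > 0, logical(1))))
    stop("all HRF parameters must be single positive numbers")
  structure(p, class = "hrf_params")
}

#' Evaluate the canonical HRF at given times
#'
#' @param t Nonnegative times in seconds (vectorized).
#' @param params An [hrf_params()] object.
#' @return Numeric vector of HRF amplitudes; `h(0) = 0` exactly.
#' @examples
#' evaluate_hrf(c(0, 5.4, 60))
#' @export
evaluate_hrf <- function(t, params = hrf_params()) {
  stopifnot(inherits(params, "hrf_params"))
  if (any(t < 0)) stop("HRF is causal: t must be nonnegative")
  with(params,
    (t / tau1)^delta1 * exp(-(delta1 / tau1) * (t - tau1)) -
      c * (t / tau2)^delta2 * exp(-(delta2 / tau2) * (t - tau2)))
}

#' Sample the HRF onto a discrete kernel
#'
#' Evaluates the HRF on the grid `0, dt, 2*dt, ...` up to `duration`, then
#' trims the trailing run of samples whose magnitude falls below
#' `truncation_tol` (the response is numerically zero beyond roughly 30 s).
#'
#' @param params An [hrf_params()] object.
#' @param dt Sampling interval in seconds.
#' @param duration Kernel support in seconds (default 32).
#' @param truncation_tol Trailing samples with `|h|` below this are dropped.
#' @return An object of class `hrf_kernel` with fields `samples` and `dt`.
#' @examples
#' k <- sample_hrf(dt = 0.5)
#' k$samples[1]  # exactly zero
#' @export
sample_hrf <- function(params = hrf_params(), dt, duration = 32,
                       truncation_tol = 1e-8) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  tt <- seq(0, by = dt, length.out = floor(duration / dt) + 1L)
  h <- evaluate_hrf(tt, params)
  keep <- which(abs(h) >= truncation_tol)
  n <- if (length(keep)) max(keep) else 1L
  structure(list(samples = h[seq_len(n)], dt = dt), class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> %d samples, dt = %g s, peak %.4f at %.2f s\n",
              length(x$samples), x$dt, max(x$samples),
              (which.max(x$samples) - 1) * x$dt))
  invisible(x)
}

#' Forward LTI model: convolve neural events with the HRF
#'
#' The BOLD response is modelled as the output of a linear time-invariant
#' system whose impulse response is the HRF. The causal discrete convolution
#' is truncated to the length of `events`.
#'
#' @param events Neural event series: a [hant_ts()] or numeric vector sampled
#'   at the kernel's `dt`.
#' @param kernel An `hrf_kernel` from [sample_hrf()].
#' @return BOLD series of the same length and sampling as `events`
#'   (a `hant_ts` in, a `hant_ts` out; numeric in, numeric out).
#' @export
convolve_events <- function(events, kernel) {
  stopifnot(inherits(kernel, "hrf_kernel"))
  if (inherits(events, "hant_ts") && abs(events$dt - kernel$dt) > 1e-12)
    stop(sprintf("sampling mismatch: events dt = %g, kernel dt = %g",
                 events$dt, kernel$dt))
  e <- ts_values(events)
  y <- convolve_causal(e, kernel$samples)
  if (inherits(events, "hant_ts")) hant_ts(y, events$dt, events$t0) else y
}

# Causal convolution truncated to length(e): y[t] = sum_k h[k] e[t-k]
#' @noRd
convolve_causal <- function(e, h) {
  n <- length(e)
  full <- stats::convolve(e, rev(h), type = "open")
  full[seq_len(n)]
}

#' Recover neural events from BOLD by Tikhonov-regularized deconvolution
#'
#' Solves \eqn{\hat e = \arg\min_e \|He - y\|^2 + \lambda \|e\|^2}, where
#' \eqn{H} is the causal Toeplitz convolution operator of the HRF kernel.
#' The event series is estimated on the same sampling grid as the BOLD input
#' (square \eqn{H}). Because `h(0) = 0`, \eqn{H} is strictly lower triangular
#' and singular, so a strictly positive ridge is required; the last few event
#' samples (within one kernel rise time of the end of the record) are weakly
#' identified and shrink towards zero.
#'
#' @param bold BOLD series (a [hant_ts()] or numeric vector, or a matrix with
#'   series in columns for batch deconvolution).
#' @param kernel An `hrf_kernel` sampled at the same interval.
#' @param ridge Nonnegative Tikhonov penalty \eqn{\lambda} (default 0.1).
#' @return Estimated event series matching the input's shape and class.
#' @examples
#' k <- sample_hrf(dt = 1)
#' e <- numeric(80); e[c(10, 35, 60)] <- 1
#' y <- convolve_events(e, k)
#' ehat <- deconvolve_events(y, k, ridge = 1e-6)
#' cor(e, ehat)
#' @export
deconvolve_events <- function(bold, kernel, ridge = 0.1) {
  stopifnot(inherits(kernel, "hrf_kernel"))
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0)
    stop("ridge must be a single nonnegative number")
  if (inherits(bold, "hant_ts") && abs(bold$dt - kernel$dt) > 1e-12)
    stop(sprintf("sampling mismatch: bold dt = %g, kernel dt = %g",
                 bold$dt, kernel$dt))
  Y <- if (is.matrix(bold)) bold else cbind(ts_values(bold))
  Ti <- nrow(Y)
  solver <- deconvolution_operator(kernel, Ti, ridge)
  E <- solver(Y)
  if (is.matrix(bold)) return(E)
  e <- drop(E)
  if (inherits(bold, "hant_ts")) hant_ts(e, bold$dt, bold$t0) else e
}

# Factorized ridge solver for repeated deconvolution at fixed length/penalty.
# Returns a function mapping a T x n matrix of BOLD columns to events.
#' @noRd
deconvolution_operator <- function(kernel, n_time, ridge) {
  h <- kernel$samples
  H <- matrix(0, n_time, n_time)
  for (k in seq_along(h)) {
    if (h[k] == 0) next
    idx <- seq_len(n_time - k + 1L)
    H[cbind(idx + k - 1L, idx)] <- h[k]
  }
  A <- crossprod(H) + diag(ridge, n_time)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R))
    stop("deconvolution is ill-posed: the convolution operator is rank ",
         "deficient; use ridge > 0", call. = FALSE)
  if (ridge == 0 && kappa(R, exact = FALSE) > 1e12)
    stop("deconvolution is ill-posed at ridge = 0; use ridge > 0",
         call. = FALSE)
  function(Y) backsolve(R, backsolve(R, crossprod(H, Y), transpose = TRUE))
}
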