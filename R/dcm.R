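#' Dynamic causal model specification
#'
#' A DCM describes the neural dynamics of a network of `m` coupled nodes,
#' \deqn{\dot x = A x + \sum_j x_j B^{(j)} x + C u,}
#' where `A` is the intrinsic connectivity (its diagonal, fixed at -1, sets
#' each node's temporal decay and its positive off-diagonal entries the
#' directed connections), the `B` matrices encode bilinear modulatory
#' coupling between nodes, and `C` maps external binary stimuli `u` into the
#' network (the identity by default, one independent stimulus per node).
#'
#' @param A `m x m` intrinsic connectivity matrix; every diagonal entry must
#'   equal -1.
#' @param B List of `m` modulatory `m x m` matrices, or `NULL` for no
#'   bilinear coupling.
#' @param C `m x m` input weight matrix (default identity).
#' @param x0 Initial neural state (default zeros).
#' @return A list of class `dcm_spec`.
#' @examples
#' dcm_spec(A = diag(-1, 3))
#' @export
dcm_spec <- function(A, B = NULL, C = diag(nrow(A)), x0 = rep(0, nrow(A))) {
  A <- as.matrix(A)
  m <- nrow(A)
  if (ncol(A) != m) stop("A must be square")
  if (any(diag(A) != -1))
    stop("all diagonal entries of A must equal -1 (node temporal decay)")
  if (is.null(B)) B <- replicate(m, matrix(0, m, m), simplify = FALSE)
  if (!is.list(B) || length(B) != m)
    stop("B must be a list of m matrices (one per node)")
  B <- lapply(B, function(b) {
    b <- as.matrix(b)
    if (!all(dim(b) == c(m, m))) stop("each B matrix must be m x m")
    b
  })
  C <- as.matrix(C)
  if (!all(dim(C) == c(m, m))) stop("C must be m x m")
  if (length(x0) != m) stop("x0 must have length m")
  structure(list(A = A, B = B, C = C, x0 = as.numeric(x0), m = m),
            class = "dcm_spec")
}

#' Five-node example network
#'
#' The default validation network: five nodes, no bilinear coupling, a weak
#' chain of positive couplings `1 -> 2 -> ... -> 5` so node dynamics are
#' related but distinguishable, identity `C`.
#'
#' @param m Number of nodes (default 5).
#' @param coupling Off-diagonal chain weight (default 0.2).
#' @return A [dcm_spec()].
#' @export
dcm_example_network <- function(m = 5, coupling = 0.2) {
  A <- diag(-1, m)
  if (m > 1) for (j in seq_len(m - 1)) A[j + 1, j] <- coupling
  dcm_spec(A = A)
}

#' Stimulus specification for the DCM simulator
#'
#' Each node receives an independent random binary on/off stimulus train.
#' Pulse onsets are spaced far enough apart for the BOLD response to return
#' to baseline between stimuli.
#'
#' @param n_nodes Number of nodes / independent stimulus channels.
#' @param duration Total duration in seconds.
#' @param dt Integration step in seconds.
#' @param onset_spacing Minimum spacing between consecutive onsets on one
#'   channel (seconds); must exceed `pulse_duration`.
#' @param pulse_duration Length of each on-pulse (seconds).
#' @param seed Integer seed; the stimuli are a pure function of these
#'   settings.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(n_nodes = 5, duration = 300, dt = 0.01,
                          onset_spacing = 30, pulse_duration = 2, seed = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (pulse_duration >= onset_spacing)
    stop("pulse_duration must be smaller than onset_spacing ",
         "(the BOLD response must return to baseline between stimuli)")
  structure(list(n_nodes = n_nodes, duration = duration, dt = dt,
                 onset_spacing = onset_spacing,
                 pulse_duration = pulse_duration, seed = seed),
            class = "stimulus_spec")
}

#' Generate independent random binary stimulus trains
#'
#' @param spec A [stimulus_spec()].
#' @return A list of class `stimulus_set`: `u` is a `n_time x n_nodes` 0/1
#'   matrix at resolution `dt`, `onsets` the per-node onset times.
#' @examples
#' s <- generate_stimuli(stimulus_spec(n_nodes = 2, duration = 120))
#' colSums(s$u) * s$dt  # seconds "on" per node
#' @export
generate_stimuli <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n_time <- floor(spec$duration / spec$dt)
  u <- matrix(0, n_time, spec$n_nodes)
  onsets <- vector("list", spec$n_nodes)
  with_seed(spec$seed, {
    for (j in seq_len(spec$n_nodes)) {
      on_j <- numeric(0)
      # first onset jittered inside the first spacing window, then each
      # subsequent onset at spacing plus up to half a window of jitter
      t_on <- runif(1, 0, spec$onset_spacing)
      while (t_on + spec$pulse_duration < spec$duration) {
        on_j <- c(on_j, t_on)
        i0 <- floor(t_on / spec$dt) + 1L
        i1 <- min(n_time, floor((t_on + spec$pulse_duration) / spec$dt))
        if (i1 >= i0) u[i0:i1, j] <- 1
        t_on <- t_on + spec$onset_spacing + runif(1, 0, spec$onset_spacing / 2)
      }
      onsets[[j]] <- on_j
    }
  })
  if (spec$pulse_duration == 0) u[] <- 0
  structure(list(u = u, dt = spec$dt, onsets = onsets), class = "stimulus_set")
}

#' Integrate the DCM neural dynamics
#'
#' Forward-Euler integration of the bilinear DCM ODE from `x0`. With all `B`
#' zero the system is linear and the integrator matches the matrix
#' exponential solution to first order in `dt`.
#'
#' @param spec A [dcm_spec()].
#' @param stimuli A `stimulus_set` from [generate_stimuli()], or a
#'   `n_time x m` input matrix.
#' @param dt Integration step in seconds; must satisfy the heuristic
#'   stability bound `dt * max |eig(A)| < 1`.
#' @param duration Total integration time; defaults to the stimulus length.
#' @return `n_time x m` matrix of node states, with attribute `dt`.
#' @export
integrate_dcm <- function(spec, stimuli, dt = NULL, duration = NULL) {
  stopifnot(inherits(spec, "dcm_spec"))
  if (inherits(stimuli, "stimulus_set")) {
    u <- stimuli$u
    dt <- dt %||% stimuli$dt
  } else {
    u <- as.matrix(stimuli)
    if (is.null(dt)) stop("dt is required when stimuli is a plain matrix")
  }
  if (ncol(u) != spec$m) stop("stimulus matrix must have one column per node")
  n_time <- if (is.null(duration)) nrow(u) else min(nrow(u), floor(duration / dt))
  lam <- max(abs(eigen(spec$A, only.values = TRUE)$values))
  if (dt * lam >= 1)
    stop(sprintf("dt = %g too large for stability (dt * max|eig(A)| = %.3f >= 1)",
                 dt, dt * lam))
  nonlinear <- any(vapply(spec$B, function(b) any(b != 0), logical(1)))
  X <- matrix(0, n_time, spec$m)
  x <- spec$x0
  for (t in seq_len(n_time)) {
    dx <- spec$A %*% x + spec$C %*% u[t, ]
    if (nonlinear)
      for (j in seq_len(spec$m)) dx <- dx + x[j] * (spec$B[[j]] %*% x)
    x <- x + dt * drop(dx)
    if (!all(is.finite(x)) || sqrt(sum(x^2)) > 1e8)
      stop(sprintf("DCM integration diverged at t = %.2f s; reduce dt = %g",
                   t * dt, dt))
    X[t, ] <- x
  }
  attr(X, "dt") <- dt
  X
}

#' Map neural states to BOLD via the HRF and decimate to the scanner TR
#'
#' Convolves each node's neural state with the HRF at the integration
#' resolution, then keeps every `tr/dt`-th sample.
#'
#' @param states `n_time x m` neural state matrix with attribute `dt`
#'   (from [integrate_dcm()]), or a numeric vector.
#' @param kernel An `hrf_kernel` sampled at the states' `dt`.
#' @param tr Repetition time in seconds; must be an integer multiple of `dt`.
#' @return Matrix (or vector) of BOLD samples at TR resolution, attribute
#'   `dt` set to `tr`.
#' @export
neural_to_bold <- function(states, kernel, tr) {
  X <- if (is.matrix(states)) states else cbind(as.numeric(states))
  dt <- attr(states, "dt") %||% kernel$dt
  if (abs(dt - kernel$dt) > 1e-12)
    stop(sprintf("sampling mismatch: states dt = %g, kernel dt = %g", dt, kernel$dt))
  step <- tr / dt
  if (abs(step - round(step)) > 1e-8)
    stop(sprintf("tr = %g is not an integer multiple of dt = %g", tr, dt))
  step <- as.integer(round(step))
  Y <- apply(X, 2, convolve_causal, h = kernel$samples)
  Y <- Y[seq(step, nrow(Y), by = step), , drop = FALSE]
  attr(Y, "dt") <- tr
  if (is.matrix(states)) Y else drop(Y)
}

#' Standardized stationary AR(1) Gaussian noise
#'
#' A synthetic fMRI-like noise model: a first-order autoregressive Gaussian
#' process (default `phi = 0.4`) reproducing the temporal autocorrelation
#' character of resting BOLD noise, standardized to zero mean and unit
#' standard deviation.
#'
#' @param n Number of samples.
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` with mean 0 and sd 1.
#' @export
ar1_noise <- function(n, phi = 0.4, seed = NULL) {
  if (abs(phi) >= 1) stop("phi must satisfy |phi| < 1 (stationarity)")
  x <- with_seed(seed, {
    if (phi == 0) rnorm(n)
    else as.numeric(arima.sim(model = list(ar = phi), n = n))
  })
  standardize(x)
}

#' Mix a signal and a noise realization at a prescribed SNR
#'
#' Both inputs are standardized, then combined as
#' `snr * standardize(signal) + standardize(noise)`, so the ratio of the
#' signal-part to noise-part standard deviations equals `snr` exactly
#' (SNR = sigma_signal / sigma_noise).
#'
#' @param signal,noise Numeric vectors of equal length, each with nonzero
#'   variance.
#' @param snr Positive signal-to-noise ratio.
#' @return Numeric vector; attributes `signal_part` and `noise_part` hold the
#'   two standardized components.
#' @export
mix_at_snr <- function(signal, noise, snr) {
  if (length(signal) != length(noise))
    stop("signal and noise must have equal length")
  if (!is.numeric(snr) || snr < 0) stop("snr must be nonnegative")
  s <- standardize(as.numeric(signal))
  e <- standardize(as.numeric(noise))
  out <- snr * s + e
  attr(out, "signal_part") <- snr * s
  attr(out, "noise_part") <- e
  out
}

#' Generate a synthetic benchmark dataset with ground-truth labels
#'
#' Runs the full simulation protocol: independent binary stimuli drive the
#' DCM, neural states are mapped to noiseless BOLD at the scanner TR, each
#' node's course is replicated `n_replicates` times, and an independent
#' standardized AR(1) noise realization is mixed into every replicate at the
#' requested SNR. Every signal is tagged with its source node.
#'
#' @param spec A [dcm_spec()] (default [dcm_example_network()] with 5 nodes).
#' @param stim A [stimulus_spec()] (its `n_nodes` must match `spec`).
#' @param n_replicates Replicates per node (the reference protocol uses 1000).
#' @param snr Signal-to-noise ratio, `sigma_signal / sigma_noise`.
#' @param tr Repetition time in seconds (default 2).
#' @param seed Integer seed controlling stimuli and every noise draw.
#' @param noise_phi AR(1) coefficient of the noise model.
#' @details The default network has five uncoupled nodes (`A = -I`), each
#'   driven by its own independent stimulus train, so the ground-truth
#'   cluster structure is unambiguous; pass [dcm_example_network()] for a
#'   network with chained positive couplings.
#' @return A list of class `synthetic_dataset`: `signals` is a
#'   `T x (m * n_replicates)` matrix, `truth` the source node of each column,
#'   plus `noiseless` (`T x m`), `snr`, `tr`, `seed`.
#' @examples
#' d <- make_benchmark_dataset(n_replicates = 3, snr = 4, seed = 1)
#' dim(d$signals); table(d$truth)
#' @export
make_benchmark_dataset <- function(spec = dcm_spec(A = diag(-1, 5)),
                                   stim = stimulus_spec(n_nodes = spec$m,
                                                        seed = seed),
                                   n_replicates = 1000, snr = 1, tr = 2,
                                   seed = 1, noise_phi = 0.4) {
  stopifnot(inherits(spec, "dcm_spec"), n_replicates >= 1)
  if (stim$n_nodes != spec$m)
    stop("stimulus spec must have one channel per DCM node")
  stimuli <- generate_stimuli(stim)
  states <- integrate_dcm(spec, stimuli)
  kernel <- sample_hrf(dt = stim$dt)
  bold <- neural_to_bold(states, kernel, tr)
  m <- spec$m
  n_time <- nrow(bold)
  signals <- matrix(0, n_time, m * n_replicates)
  truth <- rep(seq_len(m), each = n_replicates)
  with_seed(seed, {
    for (i in seq_len(m * n_replicates)) {
      noise <- standardize(as.numeric(
        arima.sim(model = if (noise_phi == 0) list(order = c(0, 0, 0))
                  else list(ar = noise_phi), n = n_time)))
      signals[, i] <- mix_at_snr(bold[, truth[i]], noise, snr)
    }
  })
  structure(list(signals = signals, truth = truth, noiseless = bold,
                 snr = snr, tr = tr, seed = seed, n_replicates = n_replicates),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d signals (%d nodes x %d replicates), T = %d, SNR = %g\n",
    ncol(x$signals), length(unique(x$truth)), x$n_replicates,
    nrow(x$signals), x$snr))
  invisible(x)
}
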