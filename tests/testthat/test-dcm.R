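test_that("dcm_spec validates its fields", {
  expect_error(dcm_spec(diag(-2, 3)), "diagonal")
  expect_error(dcm_spec(matrix(-1, 2, 3)), "square")
  s <- dcm_spec(diag(-1, 4))
  expect_equal(s$m, 4)
  expect_equal(s$C, diag(4))
  expect_true(all(vapply(s$B, function(b) all(b == 0), logical(1))))
  expect_error(dcm_spec(diag(-1, 3), B = list(matrix(0, 3, 3))), "list of m")
})

test_that("stimuli are binary, spaced, and reproducible", {
  sp <- stimulus_spec(n_nodes = 3, duration = 300, dt = 0.1,
                      onset_spacing = 30, pulse_duration = 2, seed = 5)
  s <- generate_stimuli(sp)
  expect_true(all(s$u %in% c(0, 1)))
  for (j in 1:3) {
    gaps <- diff(s$onsets[[j]])
    expect_true(all(gaps >= 30))
  }
  s2 <- generate_stimuli(sp)
  expect_identical(s$u, s2$u)
  # zero-length pulses produce silence
  s0 <- generate_stimuli(stimulus_spec(n_nodes = 2, duration = 100,
                                       pulse_duration = 0,
                                       onset_spacing = 30, seed = 1))
  expect_true(all(s0$u == 0))
  expect_error(stimulus_spec(pulse_duration = 30, onset_spacing = 30),
               "smaller")
})

test_that("integrator reproduces linear decay and brute-force bilinear oracle", {
  # A = -I, no input: x1(t) = exp(-t)
  spec <- dcm_spec(diag(-1, 3), x0 = c(1, 0, 0))
  u <- matrix(0, 1000, 3)
  X <- integrate_dcm(spec, u, dt = 1e-3)
  expect_equal(X[1000, 1], exp(-1), tolerance = 1e-3)
  # zero state, zero input: stays at zero
  spec0 <- dcm_spec(diag(-1, 2))
  expect_true(all(integrate_dcm(spec0, matrix(0, 50, 2), dt = 0.01) == 0))

  # bilinear case against an independently coded naive Euler loop
  set.seed(11)
  m <- 3
  A <- diag(-1, m); A[2, 1] <- 0.4; A[3, 2] <- 0.3
  B <- lapply(1:m, function(j) matrix(rnorm(m * m, sd = 0.05), m, m))
  C <- diag(m)
  u <- matrix(rbinom(200 * m, 1, 0.1), 200, m)
  dt <- 0.01
  x <- c(0.1, -0.2, 0.05)
  Xo <- matrix(0, 200, m)
  for (t in 1:200) {
    dx <- numeric(m)
    for (i in 1:m) {
      for (kk in 1:m) dx[i] <- dx[i] + A[i, kk] * x[kk] + C[i, kk] * u[t, kk]
      for (j in 1:m) for (kk in 1:m)
        dx[i] <- dx[i] + x[j] * B[[j]][i, kk] * x[kk]
    }
    x <- x + dt * dx
    Xo[t, ] <- x
  }
  spec_b <- dcm_spec(A, B = B, C = C, x0 = c(0.1, -0.2, 0.05))
  X <- integrate_dcm(spec_b, u, dt = dt)
  expect_equal(X, Xo, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(integrate_dcm(spec0, matrix(0, 10, 2), dt = 1.5), "stability")
})

test_that("linear integrator matches the matrix-exponential solution to O(dt)", {
  set.seed(12)
  A <- diag(-1, 3); A[lower.tri(A)] <- runif(3, 0, 0.3)
  spec <- dcm_spec(A, x0 = c(1, 0.5, -0.2))
  err <- vapply(c(1e-2, 1e-3), function(dt) {
    n <- round(1 / dt)
    X <- integrate_dcm(spec, matrix(0, n, 3), dt = dt)
    xt <- as.numeric(Matrix::expm(A) %*% spec$x0)
    max(abs(X[n, ] - xt))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 5e-3)
})

test_that("neural_to_bold convolves at fine resolution and decimates to TR", {
  k <- sample_hrf(dt = 0.1)
  states <- matrix(0, 500, 2); attr(states, "dt") <- 0.1
  expect_true(all(neural_to_bold(states, k, tr = 2) == 0))
  # tr = dt keeps every sample
  s1 <- matrix(rnorm(100), 100, 1); attr(s1, "dt") <- 0.1
  y <- neural_to_bold(s1, k, tr = 0.1)
  expect_equal(nrow(y), 100)
  expect_error(neural_to_bold(s1, k, tr = 0.25), "multiple")
  # linearity through the LTI map
  s2 <- matrix(rnorm(100), 100, 1); attr(s2, "dt") <- 0.1
  s12 <- s1 + s2; attr(s12, "dt") <- 0.1
  expect_equal(neural_to_bold(s12, k, tr = 0.5),
               neural_to_bold(s1, k, tr = 0.5) +
                 neural_to_bold(s2, k, tr = 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("AR(1) noise is standardized with the requested autocorrelation", {
  x <- ar1_noise(5000, phi = 0.4, seed = 3)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  r0 <- acf(ar1_noise(10000, phi = 0, seed = 4), plot = FALSE)$acf[2]
  expect_lt(abs(r0), 0.1)
  r8 <- acf(ar1_noise(10000, phi = 0.8, seed = 5), plot = FALSE)$acf[2]
  expect_gt(r8, 0.7); expect_lt(r8, 0.9)
  expect_error(ar1_noise(100, phi = 1), "stationarity")
})

test_that("SNR mixing satisfies the exact component-sd contract", {
  set.seed(6)
  sig <- cumsum(rnorm(400)); noi <- rnorm(400)
  for (snr in c(0.1, 0.8, 4)) {
    out <- mix_at_snr(sig, noi, snr)
    expect_equal(sd(attr(out, "signal_part")) / sd(attr(out, "noise_part")),
                 snr, tolerance = 1e-12)
  }
  # snr -> 0 limit leaves pure standardized noise; doubling snr doubles the
  # signal part exactly
  expect_equal(mix_at_snr(sig, noi, 0), (noi - mean(noi)) / sd(noi),
               tolerance = 1e-12, ignore_attr = TRUE)
  m1 <- attr(mix_at_snr(sig, noi, 1), "signal_part")
  m2 <- attr(mix_at_snr(sig, noi, 2), "signal_part")
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  expect_error(mix_at_snr(rep(1, 10), rnorm(10), 1), "zero-variance")
})

test_that("benchmark datasets carry ground truth and are reproducible", {
  d <- make_benchmark_dataset(n_replicates = 1, snr = 1, seed = 2)
  expect_equal(ncol(d$signals), 5)
  expect_equal(sort(unique(d$truth)), 1:5)
  d2 <- make_benchmark_dataset(n_replicates = 4, snr = 1, seed = 2)
  expect_equal(ncol(d2$signals), 20)
  d3 <- make_benchmark_dataset(n_replicates = 4, snr = 1, seed = 2)
  expect_identical(d2$signals, d3$signals)

  # at very high SNR, nearest-centroid classification is near perfect
  dh <- make_benchmark_dataset(n_replicates = 20, snr = 100, seed = 3)
  cent <- sapply(1:5, function(k)
    rowMeans(dh$signals[, dh$truth == k, drop = FALSE]))
  pred <- apply(dh$signals, 2, function(v)
    which.min(colSums((cent - v)^2)))
  expect_gte(mean(pred == dh$truth), 0.99)
})
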