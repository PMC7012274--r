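test_that("HRF evaluates to the canonical shape", {
  expect_identical(evaluate_hrf(0), 0)
  # direct substitution: first lobe is exactly 1 at t = tau1, minus the
  # undershoot 0.35 * 0.5^12 * exp(6)
  expect_equal(evaluate_hrf(5.4), 1 - 0.35 * 0.5^12 * exp(6),
               tolerance = 1e-12)
  expect_equal(evaluate_hrf(5.4), 0.96553, tolerance = 1e-4)
  expect_lt(abs(evaluate_hrf(60)), 1e-12)
  expect_error(evaluate_hrf(-1), "causal")
  # h(0) = 0 exactly for any positive parameters
  for (p in list(hrf_params(tau1 = 2, tau2 = 7, delta1 = 3, delta2 = 5,
                            c = 0.1),
                 hrf_params(tau1 = 8, tau2 = 16, delta1 = 9, delta2 = 14,
                            c = 0.9)))
    expect_identical(evaluate_hrf(0, p), 0)
})

test_that("sampled kernel matches pointwise evaluation and peaks in (4, 7) s", {
  k <- sample_hrf(dt = 1, duration = 3)
  expect_length(k$samples, 4)
  expect_identical(k$samples[1], 0)

  k1 <- sample_hrf(dt = 0.1, duration = 30)
  peak_t <- (which.max(k1$samples) - 1) * 0.1
  expect_gt(peak_t, 4)
  expect_lt(peak_t, 7)
  # pointwise function: values at shared times agree across resolutions
  k2 <- sample_hrf(dt = 0.05, duration = 30)
  expect_equal(k1$samples[1:200], k2$samples[seq(1, 399, by = 2)],
               tolerance = 1e-15)
  expect_error(sample_hrf(dt = 0), "positive")
  expect_error(sample_hrf(dt = 1, duration = -2), "positive")
})

test_that("forward convolution is causal, linear, and reproduces the kernel", {
  k <- sample_hrf(dt = 0.5)
  imp <- numeric(80); imp[1] <- 1
  out <- convolve_events(imp, k)
  expect_equal(out, c(k$samples, numeric(80 - length(k$samples)))[1:80],
               tolerance = 1e-12)
  expect_equal(convolve_events(numeric(40), k), numeric(40))
  set.seed(4)
  e1 <- rnorm(60); e2 <- rnorm(60)
  expect_equal(convolve_events(e1 + e2, k),
               convolve_events(e1, k) + convolve_events(e2, k),
               tolerance = 1e-12)
  expect_error(convolve_events(hant_ts(rnorm(10), dt = 1), k), "mismatch")
})

test_that("deconvolution inverts the forward model on noiseless data", {
  k <- sample_hrf(dt = 1)
  set.seed(7)
  e <- rbinom(120, 1, 0.08)
  e[(120 - 15):120] <- 0  # the trailing samples are unidentifiable (h(0)=0)
  if (sum(e) == 0) e[10] <- 1
  y <- convolve_events(e, k)
  ehat <- deconvolve_events(y, k, ridge = 1e-6)
  expect_gte(cor(e, ehat), 0.99)
  # zero input, minimizer of a nonnegative quadratic
  expect_equal(deconvolve_events(numeric(50), k, ridge = 0.1), numeric(50),
               tolerance = 1e-12)
  # ridge shrinkage is monotone in the norm
  norms <- vapply(c(0.01, 0.1, 1, 10, 100),
                  function(r) sqrt(sum(deconvolve_events(y, k, r)^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
  # H is strictly lower triangular (h(0) = 0), so ridge = 0 is ill-posed
  expect_error(deconvolve_events(y, k, ridge = 0), "ridge > 0")
})

test_that("deconvolution is linear in the data", {
  k <- sample_hrf(dt = 1)
  set.seed(8)
  y1 <- rnorm(70); y2 <- rnorm(70)
  a <- 2.5; b <- -1.25
  lhs <- deconvolve_events(a * y1 + b * y2, k, ridge = 0.1)
  rhs <- a * deconvolve_events(y1, k, ridge = 0.1) +
    b * deconvolve_events(y2, k, ridge = 0.1)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("batch deconvolution matches per-column deconvolution", {
  k <- sample_hrf(dt = 2)
  set.seed(9)
  Y <- matrix(rnorm(100 * 3), 100, 3)
  E <- deconvolve_events(Y, k, ridge = 0.1)
  for (j in 1:3)
    expect_equal(E[, j], deconvolve_events(Y[, j], k, ridge = 0.1),
                 tolerance = 1e-12)
})
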