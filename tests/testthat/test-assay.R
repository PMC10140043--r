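# TX-TL analysis: endpoints, ratio corrections, dose-response and beta.

flat_trace <- function(level, n = 40, well = "F1", role = "riboswitch") {
  kinetic_trace(well, seq(0, by = 10, length.out = n), rep(level, n),
                role = role)
}

test_that("kinetic_trace validates input", {
  expect_error(kinetic_trace("w", c(0, 10, 10), c(1, 2, 3)), "increasing")
  expect_error(kinetic_trace("w", c(0, 10), c(1, NaN)), "non-finite")
  expect_error(kinetic_trace("w", c(0, 10), 1), "equal length")
})

test_that("endpoint cancels constant traces and enforces window room", {
  nd <- flat_trace(80, role = "no_dna_control")
  expect_equal(endpoint(flat_trace(120), nd)$corrected_endpoint, 0)
  # trace equal to the no-DNA trace self-cancels even with drift
  drifting <- generate_trace(trace_params(plateau = 0, drift_slope = 0.3,
                                          noise_sd = 0, seed = 1))
  expect_equal(endpoint(drifting, drifting)$corrected_endpoint, 0)
  expect_error(endpoint(flat_trace(1, n = 20), nd), "F1")
})

test_that("endpoint recovers the logistic plateau and ignores offsets", {
  p <- trace_params(plateau = 2000, drift_slope = 0.05, noise_sd = 0, seed = 1)
  tr <- generate_trace(p)
  nd <- generate_trace(trace_params(plateau = 0, drift_slope = 0.05,
                                    noise_sd = 0, seed = 2),
                       role = "no_dna_control")
  r <- endpoint(tr, nd)
  expect_equal(r$corrected_endpoint, 2000)
  # invariant to adding a constant offset to both traces
  shift <- function(t, k) { t$fluorescence <- t$fluorescence + k; t }
  r2 <- endpoint(shift(tr, 500), shift(nd, 500))
  expect_equal(r2$corrected_endpoint, r$corrected_endpoint, tolerance = 1e-12)
  # with reader noise, the plateau is recovered within 3 sd / sqrt(window)
  sigma <- 30
  noisy <- generate_trace(trace_params(plateau = 2000, noise_sd = sigma, seed = 7))
  rn <- endpoint(noisy, nd)
  expect_lt(abs(rn$corrected_endpoint - 2000), 3 * sigma * sqrt(2 / 15))
})

test_that("replicate summaries report t-based confidence intervals", {
  nd <- flat_trace(0, role = "no_dna_control")
  reps <- lapply(c(100, 110, 90, 105), function(a) {
    tr <- flat_trace(0)
    tr$fluorescence[26:40] <- a
    endpoint(tr, nd)
  })
  s <- summarize_endpoints(reps)
  expect_equal(s$n_replicates, 4L)
  expect_equal(s$mean, 101.25)
  expect_true(s$ci_lo < s$mean && s$mean < s$ci_hi)
})

test_that("regulation ratios are mode-oriented and guard degeneracy", {
  expect_equal(regulation_ratio(50, 50, "ON"), 1)
  expect_equal(regulation_ratio(50, 100, "OFF"), 2)
  expect_equal(regulation_ratio(100, 50, "ON"), 2)
  expect_error(regulation_ratio(-5, 50, "OFF"), "degenerate")
  expect_error(regulation_ratio(5, 0, "ON"), "degenerate")
})

test_that("non-specific correction reproduces the control arithmetic", {
  # control moving opposite to an OFF switch multiplies the raw ratio
  expect_equal(correct_nonspecific(1.74, regulation_ratio(2.37, 1, "OFF")),
               1.74 * 2.37)
  # control moving with the switch divides it
  expect_equal(correct_nonspecific(237, 11), 237 / 11)
  # identity and two-step multiplicativity
  expect_equal(correct_nonspecific(3.7, 1), 3.7)
  expect_equal(correct_nonspecific(correct_nonspecific(10, 2), 2.5),
               correct_nonspecific(10, 5))
  expect_error(correct_nonspecific(2, 0), "> 0")
})

test_that("dose-response fitting recovers Hill parameters within 10%", {
  set.seed(21)
  concs <- rep(c(0, 50, 100, 200, 400, 800, 1600, 3200) * 1e-9, each = 3)
  truth <- 1000 - 800 * concs^2 / (concs^2 + (400e-9)^2)
  y <- truth * stats::rlnorm(length(truth), 0, 0.05)
  f <- fit_dose_response(concs, y)
  expect_true(f$converged)
  expect_equal(f$direction, "repression")
  expect_lt(abs(f$half_max_conc - 400e-9) / 400e-9, 0.10)
  # definitional: the curve at the fitted half-max is baseline + amplitude/2
  expect_equal(predict(f, f$half_max_conc), f$baseline + f$amplitude / 2,
               tolerance = 1e-9)
  # monotone fitted curve
  curve <- predict(f, seq(0, 3200e-9, length.out = 50))
  expect_true(all(diff(curve) <= 1e-12))
})

test_that("flat dose-response data is flagged degenerate, not fit", {
  concs <- c(0, 1e-8, 1e-7, 1e-6)
  f <- fit_dose_response(concs, rep(500, 4))
  expect_true(f$degenerate)
  expect_equal(f$amplitude, 0)
  expect_error(fit_dose_response(c(1e-8, 1e-7, 1e-6), rep(1, 3)), "including 0")
})

test_that("fit_beta recovers the slope of the log-linear relation", {
  dg <- seq(-10, 2, length.out = 12)
  ep <- exp(3.1 - 0.23 * dg)
  b <- suppressWarnings(fit_beta(dg, ep))
  expect_equal(b$beta_hat, 0.23, tolerance = 1e-9)
  expect_equal(b$ln_k_hat, 3.1, tolerance = 1e-9)
  expect_equal(b$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_beta(rep(-5, 4), c(1, 2, 3, 4)), "singular")
  expect_error(fit_beta(dg, -ep), "> 0")
  expect_error(fit_beta(c(-1, 0), c(1, 2)), ">= 3")
})
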