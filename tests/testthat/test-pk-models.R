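test_that("Tofts models reproduce constant-input closed forms", {
  tt <- seq(0, 600, by = 1)
  c0 <- 2
  aifc <- flat_aif(c0)
  kep <- (0.4 / 60) / 0.39
  closed <- 0.39 * c0 * (1 - exp(-kep * tt))
  expect_equal(standard_tofts(0.4, 0.39, aifc, tt), closed, tolerance = 1e-4)
  expect_equal(extended_tofts(0.4, 0.39, 0.03, aifc, tt), closed + 0.03 * c0,
               tolerance = 1e-4)
  expect_equal(standard_tofts(0, 0.39, aifc, tt), rep(0, length(tt)))
  expect_equal(extended_tofts(0, 0.39, 0.03, aifc, tt), 0.03 * rep(c0,
               length(tt)))
  expect_identical(extended_tofts(0.4, 0.39, 0, aifc, tt),
                   standard_tofts(0.4, 0.39, aifc, tt))
})

test_that("convolution quadrature is second order in the grid spacing", {
  aif <- fixture_aif()
  tref <- seq(0, 660, by = 0.25)
  ref <- standard_tofts(0.4, 0.39, aif, tref)
  err <- sapply(c(4, 2, 1), function(dt) {
    tt <- seq(0, 660, by = dt)
    max(abs(standard_tofts(0.4, 0.39, aif, tt) -
            ref[match(tt, tref)]))
  })
  orders <- diff(-log2(err))
  expect_gt(mean(orders), 1.6)
  expect_lt(mean(orders), 2.4)
})

test_that("high-D limit equals the standard model scaled by ve", {
  aif <- fixture_aif()
  tt <- seq(0, 660, by = 1.6)
  expect_equal(high_d_limit(0.4, 0.39, aif, tt),
               standard_tofts(0.4, 0.39, aif, tt) / 0.39, tolerance = 1e-12)
  expect_equal(high_d_limit(0, 0.39, aif, tt), rep(0, length(tt)))
  c0 <- 1.5
  kep <- (0.4 / 60) / 0.39
  expect_equal(high_d_limit(0.4, 0.39, flat_aif(c0), tt),
               c0 * (1 - exp(-kep * tt)), tolerance = 1e-4)
})

test_that("signal-to-concentration conversion inverts the forward model", {
  sc <- scan_parameters()
  C <- c(0, 0.05, 0.3, 1, 2.5)
  R1 <- 0.5 + sc$r1 * C
  stc <- structure(list(time = seq_along(C), SI = spgr_signal(R1, sc),
                        temporal_resolution = 1, scan = sc),
                   class = "signal_time_course")
  expect_equal(si_to_concentration(stc), C, tolerance = 1e-9)
  expect_equal(si_to_concentration(stc)[1], 0, tolerance = 1e-12)
  stc$SI <- rep(0.0110, length(C))
  expect_lt(max(abs(si_to_concentration(stc))), 0.01)
})

test_that("noiseless self-consistency: the fitter recovers its own model", {
  aif <- fixture_aif()
  tt <- seq(0, 660, by = 1.6)
  ct <- extended_tofts(0.4, 0.39, 0.03, aif, tt)
  fit <- fit_extended_tofts(tt, ct, aif, truth = c(0.4, 0.39, 0.03))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$percent_errors)), 1)
  # chi2 equals an independently recomputed residual norm (same fine
  # convolution grid as the fitter's default)
  tf <- sort(unique(c(tt, seq(min(tt), max(tt),
                              length.out = 10L * (length(tt) - 1) + 1))))
  r <- ct - extended_tofts(fit$Ktrans_est, fit$ve_est, fit$vp_est, aif,
                           tf)[match(tt, tf)]
  expect_equal(fit$chi2, sum(r^2), tolerance = 1e-12)
  # and the sample-grid variant is exactly self-consistent
  f1 <- fit_extended_tofts(tt, ct, aif, supersample = 1L)
  r1 <- ct - extended_tofts(f1$Ktrans_est, f1$ve_est, f1$vp_est, aif, tt)
  expect_equal(f1$chi2, sum(r1^2), tolerance = 1e-12)
})

test_that("degenerate curves fit to the expected corners", {
  aif <- fixture_aif()
  tt <- seq(0, 660, by = 3.2)
  f0 <- fit_extended_tofts(tt, rep(0, length(tt)), aif)
  expect_lt(f0$Ktrans_est, 1e-4)
  expect_lt(f0$vp_est, 1e-5)
  cp <- evaluate_aif(aif, tt)
  fp <- fit_extended_tofts(tt, 0.03 * cp, aif)
  expect_equal(fp$vp_est, 0.03, tolerance = 1e-3)
  expect_lt(fp$Ktrans_est, 1e-3)
})

test_that("percent error is the standard signed relative difference", {
  expect_equal(percent_error(0.2, 0.4), -50)
  expect_equal(percent_error(0.4, 0.4), 0)
  expect_equal(percent_error(0.0636, 0.03), 112, tolerance = 1e-3)
  expect_error(percent_error(1, 0), "nonzero")
  for (cc in c(0.5, 1.3, 2)) expect_equal(percent_error(cc * 0.37, 0.37),
                                          100 * (cc - 1), tolerance = 1e-10)
})
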