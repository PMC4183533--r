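test_that("default AIF peaks at 0.88 min, starts at zero, stays nonnegative", {
  aif <- fixture_aif()
  expect_equal(aif_peak_time(aif, 0.01), 52.8, tolerance = 0.5 / 52.8)
  expect_equal(evaluate_aif(aif, 0), 0)
  tt <- seq(0, aif$duration, by = 0.1)
  cp <- evaluate_aif(aif, tt)
  expect_true(all(cp >= 0))
  expect_equal(max(cp), 3.0, tolerance = 1e-3)
  # unique interior maximum: strictly rising then falling about the peak
  pk <- which.max(cp)
  expect_gt(pk, 1)
  expect_lt(pk, length(cp))
  d <- diff(cp)
  expect_true(all(d[seq_len(pk - 1)] > 0))
  expect_true(all(d[pk:length(d)] < 0))
})

test_that("AIF peak time is invariant to the simulated duration", {
  a1 <- aif_parametric(duration_s = 660)
  a2 <- aif_parametric(duration_s = 1320)
  expect_equal(aif_peak_time(a1, 0.01), aif_peak_time(a2, 0.01),
               tolerance = 0.02 / 52.8)
})

test_that("AIF evaluation rejects out-of-range times", {
  aif <- fixture_aif()
  expect_error(evaluate_aif(aif, -1), "duration")
  expect_error(evaluate_aif(aif, aif$duration + 5), "duration")
})

test_that("tabulated AIF round-trips through CSV exactly", {
  tt <- seq(0, 600, by = 2)
  cp <- pmax(0, sin(tt / 80)) * 2
  a <- aif_tabulated(tt, cp)
  f <- tempfile(fileext = ".csv")
  write_aif(a, f)
  a2 <- load_aif(f)
  expect_equal(a2$time, tt)
  expect_equal(a2$cp, cp)
  expect_equal(evaluate_aif(a2, c(1, 3.5, 599)), evaluate_aif(a, c(1, 3.5, 599)))
  unlink(f)
})

test_that("AIF file validation catches malformed inputs", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("t_min,cp_mM", "0,0", "11,0"), f)
  a <- load_aif(f)
  expect_equal(evaluate_aif(a, c(0, 300, 660)), c(0, 0, 0))
  writeLines(c("t_min,cp_mM", "0,0", "5,1", "3,2"), f)
  expect_error(load_aif(f), "increasing")
  writeLines(c("t_min,cp_mM", "0,0", "5,-1"), f)
  expect_error(load_aif(f), "negative")
  unlink(f)
})

test_that("sampling the parametric AIF to a table preserves its values", {
  aif <- fixture_aif()
  f <- tempfile(fileext = ".csv")
  write_aif(aif, f, dt_s = 1)
  tab <- load_aif(f)
  tt <- seq(0, 660, by = 0.25)
  # linear-interpolation error bound for a curve of this smoothness
  expect_lt(max(abs(evaluate_aif(tab, tt) - evaluate_aif(aif, tt))), 0.01)
  unlink(f)
})

test_that("the AIF integral is finite", {
  aif <- fixture_aif()
  tt <- seq(0, aif$duration, by = 0.1)
  expect_true(is.finite(sum(evaluate_aif(aif, tt)) * 0.1))
})
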