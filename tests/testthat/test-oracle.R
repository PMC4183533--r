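test_that("masked grid reproduces the domain fractions at 1 um pixels", {
  d <- fixture_domain()
  g <- masked_grid(d, pixel = 0.001)
  expect_lt(abs(g$fractions[["ve"]] - d$ve_achieved), 0.02)
  expect_lt(abs(g$fractions[["vp"]] - d$vp_achieved), 0.02)
  expect_lt(abs(g$fractions[["veis"]] - d$veis_achieved), 0.02)
})

test_that("finite-difference solver is quiescent with P = 0", {
  d <- fixture_domain()
  g <- masked_grid(d, pixel = 0.002)
  fd <- fd_solve(g, 2e-4, 0, fixture_aif(), dt = 1, duration = 30)
  expect_equal(max(abs(fd$voxel_mean)), 0)
})

test_that("finite-difference cosine-mode decay matches the analytic rate", {
  side <- 0.1; D <- 1e-4; Tend <- 5
  g <- masked_grid(empty_domain(side), pixel = 0.002)
  fd <- fd_solve(g, D, 0, flat_aif(0), dt = 0.05, duration = Tend,
                 C0 = function(x, y) cos(pi * x / side))
  decay <- exp(-D * pi^2 * Tend / side^2)
  # compare final field against the decayed initial mode
  nx <- ((seq_len(g$n^2) - 1) %% g$n + 0.5) * g$pixel
  expect_lt(max(abs(fd$C_final - decay * cos(pi * nx[g$mask == 0] / side))),
            0.01 * decay)
})
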