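test_that("a single-cell configuration yields one row per resolution", {
  cfg <- experiment_config(Ktrans = 0.4, ve = 0.39, vp = 0.03, D = 3e-3,
                           temporal_resolutions = 6.4, voxel_side = 0.06,
                           target_edge = 0.008, duration = 300, seed = 5L)
  f <- tempfile(fileext = ".csv")
  tab <- run_grid(cfg, out_csv = f)
  expect_equal(nrow(tab), 1)
  expect_named(tab, c("Ktrans_true_min", "ve_true", "vp_true", "D_mm2_s",
                      "dt_sample_s", "Ktrans_est_min", "ve_est", "vp_est",
                      "err_Ktrans_pct", "err_ve_pct", "err_vp_pct", "chi2",
                      "converged"))
  expect_true(tab$converged)
  disk <- read.csv(f)
  expect_equal(disk$Ktrans_est_min, tab$Ktrans_est_min, tolerance = 1e-12)
  unlink(f)
})

test_that("error summaries restrict to the requested diffusion range", {
  tab <- data.frame(D_mm2_s = c(1e-4, 2e-4, 3e-3),
                    err_Ktrans_pct = c(-5, -10, -1),
                    err_ve_pct = c(2, 3, 0.5),
                    err_vp_pct = c(10, 50, 2))
  s <- summarize_errors(tab, c(1e-4, 4e-4))
  expect_equal(s$min_pct, c(-10, 2, 10))
  expect_equal(s$max_pct, c(-5, 3, 50))
  s1 <- summarize_errors(tab, c(2e-4, 2e-4))
  expect_equal(s1$min_pct, s1$max_pct)
  expect_equal(s1$min_pct, c(-10, 3, 50))
  expect_error(summarize_errors(tab, c(1e-2, 2e-2)), "no rows")
})

test_that("single-row tables summarize to degenerate ranges", {
  tab <- data.frame(D_mm2_s = 2e-4, err_Ktrans_pct = -5, err_ve_pct = 2,
                    err_vp_pct = 10)
  s <- summarize_errors(tab, c(1e-4, 4e-4))
  expect_equal(s$min_pct, c(-5, 2, 10))
  expect_equal(s$max_pct, c(-5, 2, 10))
})
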