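test_that("elemental, blood and composite R1 follow the FXL arithmetic", {
  sc <- scan_parameters()
  # element of relative area 3.2e-5 at 1 mM
  expect_equal(elemental_r1(1, 2.0e-6, 0.0625, sc), (0.5 + 4.7) * 3.2e-5,
               tolerance = 1e-9)
  expect_equal(elemental_r1(0, 2.0e-6, 0.0625, sc), 0.5 * 3.2e-5,
               tolerance = 1e-9)
  sc0 <- scan_parameters(r1 = 0)
  expect_equal(elemental_r1(5, 2e-6, 0.0625, sc0),
               elemental_r1(0, 2e-6, 0.0625, sc0))
  expect_equal(blood_r1(0, sc), 0.5)
  expect_equal(blood_r1(1, sc), 5.2)
  expect_equal(blood_r1(3, sc) - blood_r1(1, sc), 2 * 4.7)  # linear in Cp
  # ve = 0.39 at uniform 1 mM, vp = 0.03 at 2 mM, veis = 0.58 at baseline
  elm <- elemental_r1(1, 0.39 * 0.0625, 0.0625, sc)
  expect_equal(composite_r1(elm, 0.03, blood_r1(2, sc), 0.58, sc, ve = 0.39),
               2.615, tolerance = 1e-12)
  # splitting an element leaves the composite unchanged (linearity)
  elm2 <- elemental_r1(c(1, 1), c(0.19, 0.20) * 0.0625, 0.0625, sc)
  expect_equal(composite_r1(elm2, 0.03, blood_r1(2, sc), 0.58, sc, ve = 0.39),
               2.615, tolerance = 1e-12)
  expect_error(composite_r1(elm, 0.5, blood_r1(2, sc), 0.58, sc, ve = 0.39),
               "sum to 1")
  # all compartments at baseline partition unity
  expect_equal(composite_r1(elemental_r1(0, 0.39 * 0.0625, 0.0625, sc),
                            0.03, blood_r1(0, sc), 0.58, sc, ve = 0.39), 0.5)
})

test_that("SPGR signal equation and its inverse agree", {
  sc <- scan_parameters()
  expect_equal(spgr_signal(0.5, sc), 0.01100, tolerance = 1e-3)
  expect_equal(spgr_signal(1e9, sc), sin(25 * pi / 180), tolerance = 1e-6)
  R1 <- c(0.3, 0.5, 2, 10)
  expect_equal(invert_spgr(spgr_signal(R1, sc), sc), R1, tolerance = 1e-10)
  # monotone in R1 over the operating range
  R1g <- seq(0.3, 30, by = 0.1)
  expect_true(all(diff(spgr_signal(R1g, sc)) > 0))
  expect_error(invert_spgr(sin(25 * pi / 180), sc), "saturation")
})

test_that("voxel R1 baseline is exactly the common R10 for any domain", {
  tc <- structure(list(time = c(0, 1, 2), voxel_mean = c(0, 0, 0),
                       domain_fractions = c(ve = 0.3898, vp = 0.0302,
                                            veis = 0.58)),
                  class = "conc_time_course")
  r1 <- voxel_r1_trajectory(tc, flat_aif(0))
  expect_equal(r1$R1, rep(0.5, 3))
})

test_that("element area weights tie to the achieved EES fraction", {
  d <- fixture_domain()
  m <- fixture_mesh()
  expect_equal(sum(m$element_areas) / d$voxel_side^2, d$ve_achieved,
               tolerance = 5e-3)
})

test_that("temporal sampling produces the expected number of points", {
  tr <- list(time = seq(0, 660, by = 0.1), R1 = rep(0.7, 6601))
  s <- sample_time_course(tr, 1.6)
  expect_equal(length(s$time), floor(660 / 1.6) + 1)
  expect_equal(length(s$time), 413)
  s2 <- sample_time_course(tr, 660)
  expect_equal(length(s2$time), 2)
  expect_true(all(s$SI == s$SI[1]))   # constant R1 -> constant SI
  expect_error(sample_time_course(tr, 0.01), "finer")
})
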