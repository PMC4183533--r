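test_that("generated domain meets target fractions and partitions unity", {
  d <- fixture_domain()
  expect_gte(d$ve_achieved, 0.38)
  expect_lte(d$ve_achieved, 0.40)
  expect_gte(d$vp_achieved, 0.025)
  expect_lte(d$vp_achieved, 0.035)
  expect_equal(d$ve_achieved + d$vp_achieved + d$veis_achieved, 1,
               tolerance = 1e-12)
  # stored fractions agree with the stored geometry
  geo <- (sum(pi * d$cells$a * d$cells$b) + sum(pi * d$vessels$r^2)) /
    d$voxel_side^2
  expect_equal(geo, 1 - d$ve_achieved, tolerance = 1e-9)
})

test_that("packing is deterministic given the seed and shapes never overlap", {
  d1 <- generate_domain(0.07, 0.39, 0.03, seed = 42)
  d2 <- generate_domain(0.07, 0.39, 0.03, seed = 42)
  expect_identical(d1$cells, d2$cells)
  expect_identical(d1$vessels, d2$vessels)
  d3 <- generate_domain(0.07, 0.39, 0.03, seed = 43)
  expect_false(isTRUE(all.equal(d1$cells$cx, d3$cells$cx)))
  expect_gt(min_shape_gap(d1), 0)
  expect_gt(min_shape_gap(fixture_domain()), 0)
})

test_that("vessels are spread across the tile", {
  d <- fixture_domain()
  dm <- as.matrix(dist(d$vessels[, c("cx", "cy")]))
  diag(dm) <- Inf
  expect_gte(min(dm), 2 * 0.008)
})

test_that("degenerate and impossible fraction requests are handled", {
  expect_error(generate_domain(0.1, 0.6, 0.5, seed = 1), "fractions")
  # ve + vp = 1 leaves no intracellular space: a cell-free domain
  d <- generate_domain(0.1, 1 - 0.03015929, 0.03, seed = 1)
  expect_equal(nrow(d$cells), 0)
  expect_gt(d$ve_achieved, 0.95)
})

test_that("3x3 tiling preserves fractions and clips back to the input", {
  d <- fixture_domain()
  ext <- tile_extended_domain(d)
  expect_equal(ext$side, 3 * d$voxel_side)
  expect_equal(nrow(ext$cells), 9 * nrow(d$cells))
  expect_equal(nrow(ext$vessels), 9 * nrow(d$vessels))
  expect_equal(ext$ve_achieved, d$ve_achieved, tolerance = 1e-12)
  expect_equal(ext$vp_achieved, d$vp_achieved, tolerance = 1e-12)
  ctr <- central_tile(ext)
  expect_equal(nrow(ctr$cells), nrow(d$cells))
  o <- order(ctr$cells$cx, ctr$cells$cy)
  oo <- order(d$cells$cx, d$cells$cy)
  expect_equal(ctr$cells[o, ], d$cells[oo, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(tile_extended_domain(ext), "already extended")
})

test_that("JSON serialization round-trips a domain", {
  d <- fixture_domain()
  f <- tempfile(fileext = ".json")
  domain_to_json(d, f)
  d2 <- domain_from_json(f)
  expect_equal(d2$cells, d$cells, tolerance = 1e-12)
  expect_equal(d2$vessels, d$vessels, tolerance = 1e-12)
  expect_equal(d2$ve_achieved, d$ve_achieved, tolerance = 1e-12)
  unlink(f)
})
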