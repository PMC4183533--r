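test_that("meshed area of a square with one circular hole is analytic", {
  side <- 0.1
  dom <- empty_domain(side)
  dom$vessels <- data.frame(cx = side / 2, cy = side / 2, r = 0.1 * side)
  m <- mesh_ees(dom, target_edge = 0.005)
  expect_equal(sum(m$element_areas), side^2 - pi * (0.1 * side)^2,
               tolerance = 5e-3)
  # refining leaves the area error tiny (area-preserving hole polygons)
  m2 <- mesh_ees(dom, target_edge = 0.0025)
  expect_equal(sum(m2$element_areas), side^2 - pi * (0.1 * side)^2,
               tolerance = 5e-3)
  expect_lt(abs(sum(m2$element_areas) / (side^2 - pi * (0.1 * side)^2) - 1),
            1e-6)
})

test_that("boundary edges are exhaustively and correctly tagged", {
  d <- fixture_domain()
  m <- fixture_mesh()
  be <- m$boundary_edges
  expect_true(all(be$tag %in% c("outer", "vessel", "cell")))
  # one vessel-tagged boundary loop per vessel, one cell loop per cell
  expect_equal(length(unique(be$shape_id[be$tag == "vessel"])),
               nrow(d$vessels))
  expect_equal(length(unique(be$shape_id[be$tag == "cell"])), nrow(d$cells))
  # the tagged set is exactly the set of edges adjacent to one triangle
  tri <- m$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- paste(pmin(be$node1, be$node2), pmax(be$node1, be$node2))
  expect_setequal(names(cnt[cnt == 1]), bkey)
})

test_that("mesh quality, area and topology invariants hold", {
  d <- fixture_domain()
  m <- fixture_mesh()
  expect_true(all(m$element_areas > 0))
  expect_gte(mesh_min_angle(m), 20 - 1e-6)
  expect_equal(sum(m$element_areas), m$ees_area_domain, tolerance = 5e-3)
  expect_equal(mesh_euler_characteristic(m),
               1 - nrow(d$cells) - nrow(d$vessels))
  # connectivity closed: all triangle indices valid, all nodes referenced
  expect_true(all(m$triangles >= 1 & m$triangles <= nrow(m$nodes)))
  expect_equal(sort(unique(as.vector(m$triangles))), seq_len(nrow(m$nodes)))
})

test_that("mean edge length tracks the target on hole-free meshes", {
  dom <- empty_domain(0.1)
  for (h in c(0.01, 0.005)) {
    m <- mesh_ees(dom, target_edge = h)
    expect_gt(mesh_mean_edge(m), 0.75 * h)
    expect_lt(mesh_mean_edge(m), 1.25 * h)
  }
})

test_that("mesh text IO round-trips nodes, elements and tags", {
  m <- fixture_mesh()
  stem <- tempfile()
  write_mesh(m, stem)
  m2 <- read_mesh(stem)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-12)
  expect_identical(m2$triangles, m$triangles)
  expect_equal(m2$boundary_edges$tag, m$boundary_edges$tag)
  expect_equal(m2$element_areas, m$element_areas, tolerance = 1e-9)
  unlink(paste0(stem, c(".node", ".ele", ".edge", ".meta.json")))
})
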