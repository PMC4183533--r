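# helper: wrap raw arrays as a tri_mesh
make_mesh <- function(nodes, tri, be, tile_side = 1, extended = FALSE) {
  x <- nodes[, 1]; y <- nodes[, 2]
  areas <- 0.5 * ((x[tri[, 2]] - x[tri[, 1]]) * (y[tri[, 3]] - y[tri[, 1]]) -
                  (y[tri[, 2]] - y[tri[, 1]]) * (x[tri[, 3]] - x[tri[, 1]]))
  structure(list(nodes = nodes, triangles = tri, boundary_edges = be,
                 element_areas = areas, target_edge = NA_real_,
                 ees_area_domain = sum(areas), min_angle_deg = NA_real_,
                 n_bad_quality = 0L, domain_side = max(nodes),
                 tile_side = tile_side, is_extended = extended),
            class = "tri_mesh")
}

test_that("transfer coefficient follows P = (Ktrans/60) V / S", {
  expect_equal(compute_transfer_coefficient(0.4, 0.93, 0.0625),
               (0.4 / 60) * 0.0625 / 0.93, tolerance = 1e-12)
  expect_equal(compute_transfer_coefficient(0.4, 0.93, 0.0625), 4.48e-4,
               tolerance = 1e-3)
  expect_equal(compute_transfer_coefficient(0, 0.93, 0.0625), 0)
  expect_equal(compute_transfer_coefficient(0.4, 2 * 0.93, 0.0625),
               compute_transfer_coefficient(0.4, 0.93, 0.0625) / 2)
  expect_error(compute_transfer_coefficient(0.4, 0, 0.0625), "positive")
})

test_that("P1 matrices on the reference triangle match hand assembly", {
  nodes <- rbind(c(0, 0), c(1, 0), c(0, 1))
  tri <- matrix(c(1, 2, 3), 1)
  be <- data.frame(node1 = c(1, 2, 3), node2 = c(2, 3, 1), tag = "outer",
                   shape_id = -1L)
  mats <- assemble(make_mesh(nodes, tri, be))
  Kexp <- 0.5 * rbind(c(2, -1, -1), c(-1, 1, 0), c(-1, 0, 1))
  Mexp <- (0.5 / 12) * rbind(c(2, 1, 1), c(1, 2, 1), c(1, 1, 2))
  expect_equal(as.matrix(mats$K), Kexp, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(as.matrix(mats$M), Mexp, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(sum(abs(mats$B)), 0)
  expect_equal(mats$b, rep(0, 3))
})

test_that("stiffness row sums vanish and vessel terms live on vessel nodes", {
  m <- fixture_mesh()
  mats <- assemble(m)
  expect_lt(max(abs(Matrix::rowSums(mats$K))), 1e-10)
  vn <- unique(c(m$boundary_edges$node1[m$boundary_edges$tag == "vessel"],
                 m$boundary_edges$node2[m$boundary_edges$tag == "vessel"]))
  nz <- which(Matrix::rowSums(abs(mats$B)) > 0)
  expect_setequal(nz, vn)
  expect_setequal(which(mats$b > 0), vn)
  # B row sums equal the load pattern (both integrate phi_i over vessel arcs)
  expect_equal(as.numeric(Matrix::rowSums(mats$B)), mats$b, tolerance = 1e-12)
})

test_that("trivial steps: zero state with zero input stays zero; matched
           plasma level keeps a uniform field uniform", {
  m <- fixture_mesh()
  mats <- assemble(m)
  cfg <- solver_config(D = 1e-4, P = 1e-4, dt = 0.1, duration = 1)
  z <- step(mats, cfg, numeric(mats$n_nodes), 0, flat_aif(0))
  expect_equal(z, numeric(mats$n_nodes))
  u <- step(mats, cfg, rep(2, mats$n_nodes), 0, flat_aif(2))
  expect_equal(u, rep(2, mats$n_nodes), tolerance = 1e-10)
})

test_that("cosine-mode decay matches the separable analytic solution", {
  dom <- empty_domain(0.1)
  m <- mesh_ees(dom, target_edge = 0.005)
  mats <- assemble(m)
  D <- 1e-4; L <- 0.1; Tend <- 5
  cfg <- solver_config(D = D, P = 0, dt = 0.05, duration = Tend)
  C0 <- cos(pi * m$nodes[, 1] / L)
  out <- run_theta_scheme(mats, cfg, flat_aif(0), C0 = C0)
  expected <- exp(-D * pi^2 * Tend / L^2) * C0
  expect_lt(max(abs(out$C_final - expected)), 0.01 * exp(-D * pi^2 * Tend / L^2))
})

test_that("spatial convergence of the cosine mode is second order", {
  dom <- empty_domain(0.1)
  D <- 1e-4; L <- 0.1; Tend <- 2
  err <- sapply(c(0.01, 0.005, 0.0025), function(h) {
    m <- mesh_ees(dom, target_edge = h)
    mats <- assemble(m)
    cfg <- solver_config(D = D, P = 0, dt = 0.01, duration = Tend)
    C0 <- cos(pi * m$nodes[, 1] / L)
    out <- run_theta_scheme(mats, cfg, flat_aif(0), C0 = C0)
    e <- out$C_final - exp(-D * pi^2 * Tend / L^2) * C0
    sqrt(sum((mats$M %*% e) * e))     # L2 (mass) norm
  })
  order1 <- log2(err[1] / err[2])
  order2 <- log2(err[2] / err[3])
  expect_gt(mean(c(order1, order2)), 1.7)
  expect_lt(mean(c(order1, order2)), 2.3)
})

test_that("temporal convergence at theta = 1/2 is second order", {
  m <- fixture_mesh()
  mats <- assemble(m)
  aif <- fixture_aif()
  P <- compute_transfer_coefficient(0.4, mats$vessel_length, 0.1^2)
  run_dt <- function(dt) {
    cfg <- solver_config(D = 2e-4, P = P, dt = dt, duration = 60)
    run_theta_scheme(mats, cfg, aif)$C_final
  }
  ref <- run_dt(0.05)
  errs <- sapply(c(0.8, 0.4, 0.2), function(dt) max(abs(run_dt(dt) - ref)))
  orders <- diff(-log2(errs))
  expect_gt(mean(orders), 1.8)
  expect_lt(mean(orders), 2.2)
})

test_that("influx is monotone at start-up and concentrations stay physical", {
  m <- fixture_mesh()
  mats <- assemble(m)
  aif <- fixture_aif()
  cfg <- solver_config(D = 2e-4, P = 2e-4, dt = 0.1, duration = 1)
  C1 <- step(mats, cfg, numeric(mats$n_nodes), 10, aif)  # Cp(10 s) > 0
  expect_gt(total_mass(m, C1), 0)
  expect_gt(min(C1), -1e-6)
})

test_that("a 4-fold symmetric domain yields a 4-fold symmetric field", {
  # structured crisscross mesh of the unit square with a square vessel hole
  n <- 10; L <- 1; hole <- c(4, 6) / n   # hole [0.4,0.6]^2
  xs <- seq(0, L, length.out = n + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = xs))
  id <- function(i, j) (j - 1) * (n + 1) + i
  inhole <- function(i, j) {
    x0 <- xs[i]; y0 <- xs[j]
    x0 >= hole[1] - 1e-9 && x0 < hole[2] - 1e-9 &&
      y0 >= hole[1] - 1e-9 && y0 < hole[2] - 1e-9
  }
  tri <- NULL; ctr <- NULL
  for (i in 1:n) for (j in 1:n) {
    if (inhole(i, j)) next
    cid <- nrow(nodes) + 1
    nodes <- rbind(nodes, c((xs[i] + xs[i + 1]) / 2, (xs[j] + xs[j + 1]) / 2))
    a <- id(i, j); b <- id(i + 1, j); cc <- id(i + 1, j + 1); d <- id(i, j + 1)
    tri <- rbind(tri, c(a, b, cid), c(b, cc, cid), c(cc, d, cid), c(d, a, cid))
  }
  # vessel edges: the hole boundary
  hb <- NULL
  for (i in 1:n) for (j in 1:n) {
    if (!inhole(i, j)) next
    if (!inhole(i - 1, j)) hb <- rbind(hb, c(id(i, j), id(i, j + 1)))
    if (!inhole(i + 1, j)) hb <- rbind(hb, c(id(i + 1, j), id(i + 1, j + 1)))
    if (!inhole(i, j - 1)) hb <- rbind(hb, c(id(i, j), id(i + 1, j)))
    if (!inhole(i, j + 1)) hb <- rbind(hb, c(id(i, j + 1), id(i + 1, j + 1)))
  }
  # compact away nodes enclosed by the hole
  used <- sort(unique(as.vector(tri)))
  remap <- rep(NA_integer_, nrow(nodes))
  remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  hb <- matrix(remap[hb], ncol = 2)
  be <- data.frame(node1 = hb[, 1], node2 = hb[, 2], tag = "vessel",
                   shape_id = 1L)
  m <- make_mesh(nodes, tri, be, tile_side = 1)
  mats <- assemble(m)
  cfg <- solver_config(D = 0.02, P = 0.005, dt = 0.5, duration = 30)
  out <- run_theta_scheme(mats, cfg, fixture_aif())
  C <- out$C_final
  # rotate nodes by 90 degrees about the centre and match
  rot <- cbind(L - nodes[, 2], nodes[, 1])
  key <- function(M) paste(round(M[, 1], 9), round(M[, 2], 9))
  map <- match(key(rot), key(nodes))
  expect_false(anyNA(map))
  expect_lt(max(abs(C - C[map])), 1e-9 * max(abs(C)))
})

test_that("sealed-domain mass is conserved through a long run", {
  m <- fixture_mesh()
  mats <- assemble(m)
  cfg <- solver_config(D = 2e-4, P = 0, dt = 0.5, duration = 660)
  C0 <- 1 + m$nodes[, 1] / 0.1
  out <- run_theta_scheme(mats, cfg, flat_aif(0), C0 = C0)
  m0 <- total_mass(m, C0)
  expect_lt(abs(total_mass(m, out$C_final) - m0) / m0, 1e-8)
})

test_that("time step selection clamps sensibly", {
  m <- fixture_mesh()
  h <- mesh_mean_edge(m)
  D_mid <- h^2 / 0.05          # puts h^2/D at 0.05 s, inside the clamps
  expect_equal(choose_time_step(m, D_mid), 0.05, tolerance = 1e-12)
  expect_equal(choose_time_step(m, 1), 1e-3)     # very large D -> dt_min
  expect_equal(choose_time_step(m, 1e-12), 0.1)  # very small D -> dt_max cap
  expect_equal(choose_time_step(m, 1e-12, dt_max = 1), 0.25)  # bolus cap
})

test_that("simulation with P = 0 stays identically zero", {
  d <- fixture_domain()
  m <- fixture_mesh()
  cfg <- solver_config(D = 2e-4, P = 0, dt = 1, duration = 30)
  tc <- run_simulation(d, m, cfg, fixture_aif())
  expect_equal(max(abs(tc$voxel_mean)), 0)
  stem <- tempfile()
  write_time_course(tc, stem)
  tc2 <- read_time_course(stem)
  expect_equal(tc2$voxel_mean, tc$voxel_mean)
  disk <- read.csv(paste0(stem, ".csv"))
  expect_equal(disk$t_s, tc$time)
  unlink(paste0(stem, c(".rds", ".csv")))
})
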