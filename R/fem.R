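# Galerkin P1 finite elements for the diffusion equation on the EES mesh,
# with a Robin-type influx condition D dC/dn = P (Cp(t) - C) on vessel-tagged
# boundary edges and zero flux on cell and outer boundaries.  Time stepping
# is the theta scheme (theta = 0.5: Crank-Nicolson), with the constant
# left-hand matrix factorized once (sparse Cholesky) and reused.

#' Solver configuration
#'
#' @param D contrast-agent diffusion coefficient [mm^2/s]
#' @param Ktrans volume transfer constant [1/min]; converted internally to
#'   the vessel-wall transfer coefficient `P` via [compute_transfer_coefficient()]
#' @param P vessel transfer coefficient [mm/s]; overrides `Ktrans` when given
#' @param theta time weighting (0 explicit Euler, 1 implicit Euler,
#'   0.5 Crank-Nicolson)
#' @param dt time step [s]; when `NULL` it is chosen by [choose_time_step()]
#' @param duration simulated time [s]
#' @param output_stride_s spacing of stored full-field snapshots [s]; the
#'   voxel-mean summary is always kept at full step resolution
#' @return a `solver_config` list
#' @export
solver_config <- function(D, Ktrans = NULL, P = NULL, theta = 0.5, dt = NULL,
                          duration = 660, output_stride_s = 5) {
  stopifnot(D > 0, theta >= 0, theta <= 1, duration > 0)
  if (is.null(P) && is.null(Ktrans))
    stop("provide Ktrans [1/min] or P [mm/s]")
  if (!is.null(P)) stopifnot(P >= 0)
  if (!is.null(Ktrans)) stopifnot(Ktrans >= 0)
  if (!is.null(dt)) stopifnot(dt > 0)
  structure(list(D = D, Ktrans = Ktrans, P = P, theta = theta, dt = dt,
                 duration = duration, output_stride_s = output_stride_s),
            class = "solver_config")
}

#' Vessel transfer coefficient from Ktrans
#'
#' In the permeability-limited regime the wall transfer coefficient `P`
#' [mm/s] relates to the volume transfer constant via `P = Ktrans * V / S`,
#' where `S` is the total vessel boundary length of one voxel and `V` its
#' area (the 2-D analogues of vessel surface area and voxel volume).  This
#' scaling makes the well-mixed (high diffusion) limit of the simulation
#' reproduce the standard Tofts model at the nominal Ktrans.
#'
#' @param Ktrans volume transfer constant [1/min]
#' @param S vessel boundary length per voxel [mm]
#' @param V voxel area [mm^2]
#' @return transfer coefficient `P` [mm/s]
#' @export
#' @examples
#' compute_transfer_coefficient(0.4, 0.93, 0.0625)
compute_transfer_coefficient <- function(Ktrans, S, V) {
  stopifnot(Ktrans >= 0, V > 0)
  if (!(S > 0)) stop("vessel boundary length S must be positive")
  (Ktrans / 60) * V / S
}

#' Assemble the finite-element system matrices
#'
#' Builds the consistent mass matrix `M`, the unit-diffusivity stiffness
#' matrix `K`, the vessel boundary matrix `B` and the vessel load pattern `b`
#' for linear Lagrange (P1) elements on a tagged mesh.  At solve time the
#' spatial operator is `A = D*K + P*B` and the source is `P*Cp(t)*b`; cell-
#' and outer-tagged edges contribute nothing (zero flux).
#'
#' @param mesh a `tri_mesh` with fully tagged boundary edges
#' @param config optional `solver_config` (not required for assembly)
#' @return a `system_matrices` list with sparse `M`, `K`, `B`, vector `b`,
#'   `n_nodes` and `vessel_length` (total vessel-tagged boundary length, mm)
#' @export
assemble <- function(mesh, config = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!all(mesh$boundary_edges$tag %in% c("outer", "vessel", "cell")))
    stop("untagged boundary edge")
  p <- mesh$nodes
  tri <- mesh$triangles
  n <- nrow(p)
  i1 <- tri[, 1]; i2 <- tri[, 2]; i3 <- tri[, 3]
  x1 <- p[i1, 1]; y1 <- p[i1, 2]
  x2 <- p[i2, 1]; y2 <- p[i2, 2]
  x3 <- p[i3, 1]; y3 <- p[i3, 2]
  A <- mesh$element_areas
  # P1 gradient coefficients: grad(phi_k) = (b_k, c_k) / (2A)
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  bb <- cbind(b1, b2, b3); cc <- cbind(c1, c2, c3)
  idx <- cbind(i1, i2, i3)
  rowv <- colv <- integer(9 * nrow(tri))
  kv <- mv <- numeric(9 * nrow(tri))
  pos <- 0L
  for (a in 1:3) for (b in 1:3) {
    rng <- pos + seq_len(nrow(tri))
    rowv[rng] <- idx[, a]
    colv[rng] <- idx[, b]
    kv[rng] <- (bb[, a] * bb[, b] + cc[, a] * cc[, b]) / (4 * A)
    mv[rng] <- A / 12 * (1 + (a == b))
    pos <- pos + nrow(tri)
  }
  K <- Matrix::sparseMatrix(i = rowv, j = colv, x = kv, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = rowv, j = colv, x = mv, dims = c(n, n))
  ves <- mesh$boundary_edges[mesh$boundary_edges$tag == "vessel", ,
                             drop = FALSE]
  if (nrow(ves)) {
    e1 <- ves$node1; e2 <- ves$node2
    len <- sqrt((p[e1, 1] - p[e2, 1])^2 + (p[e1, 2] - p[e2, 2])^2)
    B <- Matrix::sparseMatrix(
      i = c(e1, e2, e1, e2), j = c(e1, e2, e2, e1),
      x = c(len / 3, len / 3, len / 6, len / 6), dims = c(n, n))
    bvec <- numeric(n)
    agg <- rowsum(c(len / 2, len / 2), c(e1, e2))
    bvec[as.integer(rownames(agg))] <- agg[, 1]
    vlen <- sum(len)
  } else {
    B <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
    bvec <- numeric(n)
    vlen <- 0
  }
  structure(list(M = M, K = K, B = B, b = bvec, n_nodes = n,
                 vessel_length = vlen), class = "system_matrices")
}

#' Choose the simulation time step
#'
#' Diffusion-scaled heuristic `dt = c * h^2 / D` (with `h` the mean mesh edge
#' length), clamped to `[dt_min, dt_max]` and additionally capped so the
#' bolus peak of the AIF is well resolved.
#'
#' @param mesh a `tri_mesh`
#' @param D diffusion coefficient [mm^2/s]
#' @param aif unused placeholder for AIF-aware refinements
#' @param c_factor scale factor on `h^2/D`
#' @param dt_min,dt_max clamp bounds [s]
#' @param bolus_cap upper cap preserving AIF features [s]
#' @return time step [s]
#' @export
choose_time_step <- function(mesh, D, aif = NULL, c_factor = 1,
                             dt_min = 1e-3, dt_max = 0.1, bolus_cap = 0.25) {
  h <- mesh_mean_edge(mesh)
  min(max(c_factor * h^2 / D, dt_min), dt_max, bolus_cap)
}

# Internal: cached theta-scheme stepper.  Returns an environment with
# lhs factorization and a step(C, t) closure.
.make_stepper <- function(matrices, config, aif, P) {
  theta <- config$theta
  dt <- config$dt
  A <- config$D * matrices$K + P * matrices$B
  lhs <- matrices$M + theta * dt * A
  rhsM <- matrices$M - (1 - theta) * dt * A
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(lhs), LDL = FALSE)
  b <- matrices$b
  dur <- aif$duration
  function(C, t_now) {
    f <- P * (theta * evaluate_aif(aif, min(t_now + dt, dur)) +
              (1 - theta) * evaluate_aif(aif, min(t_now, dur)))
    rhs <- rhsM %*% C + (dt * f) * b
    as.numeric(Matrix::solve(ch, rhs, system = "A"))
  }
}

#' Advance the concentration field by one time step
#'
#' Solves `(M + theta*dt*A) C_next = (M - (1-theta)*dt*A) C_now +
#' dt*[theta*f(t+dt) + (1-theta)*f(t)]` with `A = D*K + P*B` and vessel load
#' `f(t) = P*Cp(t)*b`.  Intended for diagnostics and small studies; full
#' trajectories should use [run_simulation()], which factorizes once.
#'
#' @param matrices a `system_matrices`
#' @param config a `solver_config` with non-`NULL` `dt` and `P`
#' @param C_now nodal concentration vector [mM]
#' @param t_now current time [s]
#' @param aif an `aif_model`
#' @return nodal concentrations at `t_now + dt`
#' @export
step <- function(matrices, config, C_now, t_now, aif) {
  stopifnot(inherits(matrices, "system_matrices"), !is.null(config$dt))
  if (!all(is.finite(C_now))) stop("non-finite concentration state")
  P <- if (!is.null(config$P)) config$P else
    stop("config$P must be set for step(); run_simulation() derives it")
  st <- .make_stepper(matrices, config, aif, P)
  st(C_now, t_now)
}

#' Run the theta-scheme over a full duration
#'
#' Lower-level loop used by [run_simulation()] and by convergence studies;
#' starts from an arbitrary initial field.
#'
#' @param matrices a `system_matrices`
#' @param config a `solver_config` with `dt` and `P` resolved
#' @param aif an `aif_model`
#' @param C0 initial nodal field [mM] (default zero)
#' @param weights optional node weights; when given, the weighted summary
#'   `sum(w*C)/sum(w)` is recorded at every step
#' @param snapshot_stride store full nodal fields every this many steps
#'   (0 = none)
#' @return list with `time`, `summary`, `snap_times`, `snapshots`, `C_final`
#' @export
run_theta_scheme <- function(matrices, config, aif, C0 = NULL, weights = NULL,
                             snapshot_stride = 0L) {
  dt <- config$dt
  stopifnot(!is.null(dt), !is.null(config$P))
  nsteps <- ceiling(config$duration / dt - 1e-9)
  dt <- config$duration / nsteps       # land exactly on the final time
  config$dt <- dt
  C <- if (is.null(C0)) numeric(matrices$n_nodes) else as.numeric(C0)
  st <- .make_stepper(matrices, config, aif, config$P)
  tgrid <- (0:nsteps) * dt
  summ <- if (is.null(weights)) NULL else numeric(nsteps + 1)
  wsum <- if (is.null(weights)) NULL else sum(weights)
  if (!is.null(weights)) summ[1] <- sum(weights * C) / wsum
  snaps <- NULL; snap_t <- NULL
  if (snapshot_stride > 0) {
    ks <- unique(c(seq(0, nsteps, by = snapshot_stride), nsteps))
    snaps <- matrix(0, matrices$n_nodes, length(ks))
    snap_t <- ks * dt
    snaps[, 1] <- C
    snap_i <- 2L
  }
  for (k in seq_len(nsteps)) {
    C <- st(C, (k - 1) * dt)
    if (!is.null(weights)) summ[k + 1] <- sum(weights * C) / wsum
    if (snapshot_stride > 0 && (k %% snapshot_stride == 0 || k == nsteps) &&
        snap_i <= ncol(snaps)) {
      if (snap_t[snap_i] == k * dt) { snaps[, snap_i] <- C; snap_i <- snap_i + 1L }
    }
  }
  list(time = tgrid, summary = summ, snap_times = snap_t, snapshots = snaps,
       C_final = C, dt = dt)
}

#' Total tracer mass on the mesh
#' @param mesh a `tri_mesh`
#' @param C nodal concentration vector [mM]
#' @return mass in mM*mm^2 units
#' @export
total_mass <- function(mesh, C) {
  tri <- mesh$triangles
  sum(mesh$element_areas * (C[tri[, 1]] + C[tri[, 2]] + C[tri[, 3]]) / 3)
}

# node weights that integrate C over the elements whose centroid lies in the
# central voxel; sum(w) equals the included EES area
.central_voxel_weights <- function(mesh) {
  tri <- mesh$triangles
  p <- mesh$nodes
  cx <- (p[tri[, 1], 1] + p[tri[, 2], 1] + p[tri[, 3], 1]) / 3
  cy <- (p[tri[, 1], 2] + p[tri[, 2], 2] + p[tri[, 3], 2]) / 3
  L <- mesh$tile_side
  sel <- if (mesh$is_extended)
    cx >= L & cx <= 2 * L & cy >= L & cy <= 2 * L else rep(TRUE, nrow(tri))
  w <- numeric(nrow(p))
  At <- mesh$element_areas[sel] / 3
  for (k in 1:3) {
    agg <- rowsum(At, tri[sel, k])
    id <- as.integer(rownames(agg))
    w[id] <- w[id] + agg[, 1]
  }
  w
}

#' Run a forward perfusion-diffusion simulation
#'
#' Time-steps the contrast-agent concentration in the EES from a zero initial
#' state, with influx across vessel walls driven by the AIF.  The voxel EES
#' mean concentration is recorded at every step, restricted to the central
#' voxel of interest when the mesh comes from the 3x3 extended domain.
#'
#' @param domain the `tissue_domain` the mesh was built from
#' @param mesh a `tri_mesh` of the domain's EES
#' @param config a `solver_config`; when `config$P` is `NULL` it is derived
#'   from `config$Ktrans` using the meshed vessel boundary length of one
#'   voxel and the voxel area
#' @param aif an `aif_model`
#' @return a `conc_time_course` with full-resolution `time` and `voxel_mean`
#'   [mM], decimated nodal `snapshots`, the solver settings used, and the
#'   central-voxel element index/areas
#' @export
run_simulation <- function(domain, mesh, config, aif) {
  stopifnot(inherits(domain, "tissue_domain"), inherits(mesh, "tri_mesh"),
            inherits(config, "solver_config"), inherits(aif, "aif_model"))
  mats <- assemble(mesh, config)
  ntiles <- if (mesh$is_extended) 9 else 1
  S_voxel <- mats$vessel_length / ntiles
  V_voxel <- mesh$tile_side^2
  P <- config$P
  if (is.null(P)) P <- compute_transfer_coefficient(config$Ktrans, S_voxel,
                                                    V_voxel)
  cfg <- config
  cfg$P <- P
  if (is.null(cfg$dt)) cfg$dt <- choose_time_step(mesh, cfg$D, aif)
  if (cfg$duration > aif$duration + 1e-9)
    stop("simulation duration exceeds the AIF duration")
  w <- .central_voxel_weights(mesh)
  stride <- max(1L, round(cfg$output_stride_s / cfg$dt))
  out <- run_theta_scheme(mats, cfg, aif, C0 = NULL, weights = w,
                          snapshot_stride = stride)
  undershoot <- min(0, min(out$summary))
  if (undershoot < -1e-6)
    warning(sprintf("voxel-mean undershoot %.3g mM below zero", -undershoot))
  structure(list(
    time = out$time, voxel_mean = out$summary,
    snap_times = out$snap_times, snapshots = out$snapshots,
    dt = out$dt, P = P, D = cfg$D,
    Ktrans_nominal = P * S_voxel / V_voxel * 60,
    S_voxel = S_voxel, V_voxel = V_voxel,
    central_weights = w, central_area = sum(w),
    domain_fractions = c(ve = domain$ve_achieved, vp = domain$vp_achieved,
                         veis = domain$veis_achieved)),
    class = "conc_time_course")
}

#' Write a concentration time course to disk
#'
#' Stores the full trajectory (an R serialization of the
#' `conc_time_course`, holding the decimated nodal snapshots) together with
#' a plain-CSV mirror of the full-resolution voxel summary (columns `t_s`,
#' `voxel_mean_mM`).
#'
#' @param tc a `conc_time_course`
#' @param stem output path stem; writes `<stem>.rds` and `<stem>.csv`
#' @return `stem`, invisibly
#' @export
write_time_course <- function(tc, stem) {
  stopifnot(inherits(tc, "conc_time_course"))
  saveRDS(tc, paste0(stem, ".rds"))
  write.csv(data.frame(t_s = tc$time, voxel_mean_mM = tc$voxel_mean),
            paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' Read a concentration time course written by [write_time_course()]
#' @param stem path stem used at write time
#' @return a `conc_time_course`
#' @export
read_time_course <- function(stem) {
  tc <- readRDS(paste0(stem, ".rds"))
  stopifnot(inherits(tc, "conc_time_course"))
  tc
}

#' Element-mean concentrations at a stored snapshot
#' @param tc a `conc_time_course`
#' @param mesh the mesh used for the simulation
#' @param snap snapshot index (into `tc$snap_times`)
#' @return vector of element mean concentrations [mM]
#' @export
element_means <- function(tc, mesh, snap) {
  C <- tc$snapshots[, snap]
  tri <- mesh$triangles
  (C[tri[, 1]] + C[tri[, 2]] + C[tri[, 3]]) / 3
}

#' @export
print.conc_time_course <- function(x, ...) {
  cat(sprintf(paste0("<conc_time_course> %d steps, dt %.3g s, D %.3g mm^2/s,",
                     " peak voxel mean %.4g mM\n"),
              length(x$time) - 1, x$dt, x$D, max(x$voxel_mean)))
  invisible(x)
}
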