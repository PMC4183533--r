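# Independent references used for verification: a masked-grid finite
# difference solver of the same continuous problem (5-point stencil, flux
# faces at vessel-adjacent pixels) and the closed-form well-mixed limit.

#' Rasterize a domain onto a masked pixel grid
#'
#' Classifies pixel centres as EES, cell, or vessel using the analytic shape
#' geometry (not the meshing polygons), for use by the finite-difference
#' reference solver.
#'
#' @param domain a single-tile `tissue_domain`
#' @param pixel pixel size [mm]
#' @return a `masked_grid` with the integer mask (0 EES, 1 cell, 2 vessel),
#'   per-vessel ids for flux-length correction, and achieved mask fractions
#' @export
masked_grid <- function(domain, pixel = 0.001) {
  stopifnot(inherits(domain, "tissue_domain"), !isTRUE(domain$is_extended))
  L <- domain$side
  n <- round(L / pixel)
  xc <- (seq_len(n) - 0.5) * pixel
  gx <- matrix(xc, n, n)
  gy <- matrix(xc, n, n, byrow = TRUE)
  mask <- matrix(0L, n, n)
  vid <- matrix(0L, n, n)
  cc <- domain$cells
  if (nrow(cc)) for (i in seq_len(nrow(cc))) {
    dx <- gx - cc$cx[i]; dy <- gy - cc$cy[i]
    ca <- cos(cc$angle[i]); sa <- sin(cc$angle[i])
    u <- (ca * dx + sa * dy) / cc$a[i]
    v <- (-sa * dx + ca * dy) / cc$b[i]
    mask[u^2 + v^2 <= 1] <- 1L
  }
  vv <- domain$vessels
  if (nrow(vv)) for (i in seq_len(nrow(vv))) {
    inside <- (gx - vv$cx[i])^2 + (gy - vv$cy[i])^2 <= vv$r[i]^2
    mask[inside] <- 2L
    vid[inside] <- i
  }
  fr <- c(ve = mean(mask == 0L), veis = mean(mask == 1L),
          vp = mean(mask == 2L))
  structure(list(pixel = pixel, n = n, mask = mask, vessel_id = vid,
                 side = L, fractions = fr,
                 vessel_perimeter = if (nrow(vv)) 2 * pi * vv$r else numeric(0)),
            class = "masked_grid")
}

#' Finite-difference reference solve on a masked grid
#'
#' Discretizes the same diffusion problem as the finite-element solver with a
#' 5-point stencil on EES pixels: no flux at cell faces and at the outer
#' (reflecting) boundary, and a Robin influx `P (Cp - C)` on faces adjacent
#' to vessel pixels.  The staircase vessel boundary is longer than the true
#' circular one, so each vessel's face flux is scaled by the ratio of its
#' analytic perimeter to its staircase perimeter; the theta scheme (default
#' Crank-Nicolson) advances in time with a factorized sparse solve.
#'
#' @param grid a `masked_grid`
#' @param D diffusion coefficient [mm^2/s]
#' @param P vessel transfer coefficient [mm/s]
#' @param aif an `aif_model`
#' @param dt time step [s]; default 0.05 s
#' @param duration simulated time [s]
#' @param theta time weighting
#' @param C0 optional initial EES-pixel concentration vector (or a function
#'   of pixel-centre coordinates), default zero
#' @return list with `time`, `voxel_mean` (mean over EES pixels, mM) and
#'   `C_final`
#' @export
fd_solve <- function(grid, D, P, aif, dt = 0.05, duration = 660,
                     theta = 0.5, C0 = NULL) {
  stopifnot(inherits(grid, "masked_grid"))
  n <- grid$n
  h <- grid$pixel
  ees <- which(grid$mask == 0L)
  ne <- length(ees)
  idx <- matrix(0L, n, n)
  idx[ees] <- seq_len(ne)
  ro <- ((ees - 1L) %% n) + 1L      # row (x index)
  co <- ((ees - 1L) %/% n) + 1L     # col (y index)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_lap <- numeric(ne)
  flux <- numeric(ne)   # per-pixel vessel face count, perimeter-corrected
  vcount <- matrix(0, ne, max(1L, length(grid$vessel_perimeter)))
  shift <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (s in shift) {
    r2 <- ro + s[1]; c2 <- co + s[2]
    inb <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= n
    lin <- rep(0L, ne)
    lin[inb] <- (c2[inb] - 1L) * n + r2[inb]
    m2 <- rep(-1L, ne)
    m2[inb] <- grid$mask[lin[inb]]
    isees <- m2 == 0L
    ii <- c(ii, which(isees)); jj <- c(jj, idx[lin[isees]])
    xx <- c(xx, rep(1, sum(isees)))
    diag_lap <- diag_lap - isees
    isv <- m2 == 2L
    if (any(isv)) {
      vv <- grid$vessel_id[lin[isv]]
      for (k in unique(vv)) {
        sel <- which(isv)[vv == k]
        vcount[sel, k] <- vcount[sel, k] + 1
      }
    }
  }
  # per-vessel staircase-length correction
  if (length(grid$vessel_perimeter)) {
    tot_faces <- colSums(vcount)
    for (k in seq_along(grid$vessel_perimeter)) {
      if (tot_faces[k] > 0) {
        corr <- grid$vessel_perimeter[k] / (tot_faces[k] * h)
        flux <- flux + vcount[, k] * corr
      }
    }
  }
  lap <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ne, ne)) +
    Matrix::Diagonal(ne, diag_lap)
  # dC/dt = (D/h^2) lap C + (P/h) flux (Cp - C)
  A <- -(D / h^2) * lap + Matrix::Diagonal(ne, (P / h) * flux)
  nsteps <- ceiling(duration / dt - 1e-9)
  lhs <- Matrix::Diagonal(ne) + theta * dt * A
  rhsM <- Matrix::Diagonal(ne) - (1 - theta) * dt * A
  ch <- Matrix::lu(lhs)
  C <- numeric(ne)
  if (!is.null(C0)) {
    C <- if (is.function(C0)) {
      C0((ro - 0.5) * h, (co - 0.5) * h)
    } else as.numeric(C0)
    stopifnot(length(C) == ne)
  }
  vm <- numeric(nsteps + 1)
  vm[1] <- mean(C)
  bvec <- (P / h) * flux
  for (k in seq_len(nsteps)) {
    f <- theta * evaluate_aif(aif, k * dt) +
      (1 - theta) * evaluate_aif(aif, (k - 1) * dt)
    C <- as.numeric(Matrix::solve(ch, rhsM %*% C + dt * f * bvec))
    vm[k + 1] <- mean(C)
  }
  list(time = (0:nsteps) * dt, voxel_mean = vm, C_final = C)
}

#' Well-mixed (high diffusion) EES concentration limit
#'
#' When diffusion is fast enough that the EES is effectively well mixed, the
#' EES concentration obeys `ve dCe/dt = Ktrans (Cp - Ce)`, whose solution is
#' the standard Tofts convolution divided by `ve`.
#'
#' @param Ktrans volume transfer constant [1/min]
#' @param ve EES fraction
#' @param aif an `aif_model` or Cp samples on `t`
#' @param t time grid [s]
#' @return EES concentration `Ce(t)` [mM]
#' @export
high_d_limit <- function(Ktrans, ve, aif, t) {
  standard_tofts(Ktrans, ve, aif, t) / ve
}
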