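# Voxel geometry: seeded packing of elliptical cells and circular vessels
# into a square tile with prescribed area fractions, and 3x3 periodic tiling.
# Internal units: lengths in mm, areas in mm^2.

#' Polygonize an ellipse
#'
#' Returns an `n`-gon approximating an ellipse.  With `area_match = TRUE` the
#' vertices are scaled radially outward so the polygon area equals the exact
#' ellipse area `pi*a*b`, which keeps mesh-based area sums consistent with the
#' analytic fractions independently of `n`.
#'
#' @param cx,cy centre [mm]
#' @param a,b semi-axes [mm]
#' @param angle rotation [rad]
#' @param n number of vertices
#' @param area_match scale so polygon area equals the ellipse area
#' @param wobble relative radial perturbation amplitude (deterministic); a
#'   tiny nonzero value breaks exact cocircularity of the vertices, which
#'   degenerate-position Delaunay predicates appreciate
#' @return an `n` x 2 matrix of vertices (counter-clockwise, not closed)
#' @keywords internal
ellipse_poly <- function(cx, cy, a, b, angle = 0, n = 32L,
                         area_match = TRUE, wobble = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  s <- if (area_match) sqrt(2 * pi / (n * sin(2 * pi / n))) else 1
  r <- 1 + wobble * cos(12.9898 * seq_len(n) + 78.233 * (cx * 1e3 + cy * 2e3))
  xs <- s * r * a * cos(th)
  ys <- s * r * b * sin(th)
  ca <- cos(angle); sa <- sin(angle)
  cbind(cx + ca * xs - sa * ys, cy + sa * xs + ca * ys)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a seeded 2-D voxel tissue domain
#'
#' Constructs a square voxel of side `voxel_side` containing non-overlapping
#' elliptical cells (the impermeable extravascular intracellular space, EIS),
#' circular vessels, and the extravascular extracellular space (EES) in
#' between, with area fractions matching `target_ve` (EES) and `target_vp`
#' (vessels).  Vessels are laid out by farthest-point sampling so perfusion
#' sources are spaced across the tile; cells are seeded at random and relaxed
#' by deterministic pairwise push-apart moves until no two shapes are closer
#' than `gap`.
#'
#' @param voxel_side tile side length [mm] (default 0.25 mm)
#' @param target_ve target EES area fraction
#' @param target_vp target vascular area fraction
#' @param cell_diameter_mean mean cell (area-equivalent) diameter [mm]
#' @param vessel_diameter_mean vessel diameter [mm]
#' @param seed integer RNG seed; the same seed reproduces the geometry exactly
#' @param gap minimum clearance kept between any two shapes and between a
#'   shape and the tile border [mm]; the border clearance is `gap/2` so that
#'   periodic copies of the tile also respect `gap`
#' @param cell_diameter_cv lognormal coefficient of variation of cell size
#' @param axis_ratio_range range of the ellipse minor/major axis ratio
#' @param max_restarts packing restarts before the clearance is relaxed
#' @param max_sweeps relaxation sweeps per attempt
#' @return a `tissue_domain` object with elements `cells` (data frame of
#'   `cx, cy, a, b, angle`), `vessels` (`cx, cy, r`), the achieved fractions
#'   `ve_achieved`, `vp_achieved`, `veis_achieved`, the `seed`, and tiling
#'   metadata
#' @export
#' @examples
#' d <- generate_domain(0.1, 0.39, 0.03, seed = 1)
#' d$ve_achieved
generate_domain <- function(voxel_side = 0.25, target_ve = 0.39,
                            target_vp = 0.03,
                            cell_diameter_mean = 0.014,
                            vessel_diameter_mean = 0.008,
                            seed = 1L, gap = 0.001,
                            cell_diameter_cv = 0.15,
                            axis_ratio_range = c(0.7, 1.0),
                            max_restarts = 6L, max_sweeps = 6000L) {
  L <- voxel_side
  if (!(L > 0)) stop("voxel_side must be positive")
  if (!(target_ve > 0) || !(target_vp > 0))
    stop("target_ve and target_vp must be positive")
  if (target_ve + target_vp > 1 + 1e-12)
    stop("impossible fractions: target_ve + target_vp exceeds 1")
  rv <- vessel_diameter_mean / 2
  with_seed(seed, {
    ## ---- vessels: count from the target fraction, farthest-point layout
    nv <- round(target_vp * L^2 / (pi * rv^2))
    if (nv < 1L) nv <- 1L
    vp_achieved <- nv * pi * rv^2 / L^2
    if (abs(vp_achieved - target_vp) > 0.005)
      stop("packing failure: vessel count granularity cannot meet target_vp ",
           "within 0.005 for this tile size")
    vmargin <- rv + gap / 2
    if (2 * vmargin >= L) stop("packing failure: vessel does not fit in tile")
    ncand <- max(12L, ceiling(L / vessel_diameter_mean))
    gx <- seq(vmargin, L - vmargin, length.out = ncand)
    cand <- as.matrix(expand.grid(x = gx, y = gx))
    cand <- cand + matrix(runif(length(cand), -0.2, 0.2) * (gx[2] - gx[1]),
                          ncol = 2)
    cand[, 1] <- pmin(pmax(cand[, 1], vmargin), L - vmargin)
    cand[, 2] <- pmin(pmax(cand[, 2], vmargin), L - vmargin)
    sel <- integer(nv)
    sel[1] <- sample.int(nrow(cand), 1L)
    if (nv > 1L) {
      d2 <- (cand[, 1] - cand[sel[1], 1])^2 + (cand[, 2] - cand[sel[1], 2])^2
      for (k in 2:nv) {
        sel[k] <- which.max(d2)
        d2 <- pmin(d2, (cand[, 1] - cand[sel[k], 1])^2 +
                       (cand[, 2] - cand[sel[k], 2])^2)
      }
    }
    vessels <- data.frame(cx = cand[sel, 1], cy = cand[sel, 2], r = rv)
    if (nv > 1L) {
      dm <- as.matrix(stats::dist(vessels[, c("cx", "cy")]))
      diag(dm) <- Inf
      if (min(dm) < 2 * vessel_diameter_mean)
        stop("packing failure: vessels cannot be spaced at twice their ",
             "diameter in this tile")
    }

    ## ---- cells: draw sizes to hit the EIS area exactly, then relax
    eis_area <- (1 - target_ve - target_vp) * L^2
    cells <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                        b = numeric(0), angle = numeric(0))
    g <- gap
    # an EIS sliver smaller than a fifth-of-mean-diameter cell is left empty
    # (the deficit is far inside the +/-0.01 fraction tolerance)
    if (eis_area > pi * (0.1 * cell_diameter_mean)^2) {
      sdlog <- sqrt(log(1 + cell_diameter_cv^2))
      meanlog <- log(cell_diameter_mean) - sdlog^2 / 2
      dia <- numeric(0)
      while (sum(pi * dia^2 / 4) < eis_area) {
        dd <- rlnorm(32L, meanlog, sdlog)
        dd <- pmin(pmax(dd, 0.4 * cell_diameter_mean), 1.8 * cell_diameter_mean)
        dia <- c(dia, dd)
        if (length(dia) > 1e5) stop("packing failure: cell size draw runaway")
      }
      csum <- cumsum(pi * dia^2 / 4)
      ncell <- which(csum >= eis_area)[1]
      dia <- dia[seq_len(ncell)]
      dia <- dia * sqrt(eis_area / sum(pi * dia^2 / 4))   # exact EIS area
      ratio <- runif(ncell, axis_ratio_range[1], axis_ratio_range[2])
      aa <- dia / 2 / sqrt(ratio)
      bb <- dia / 2 * sqrt(ratio)
      ang <- runif(ncell, 0, pi)
      placed <- FALSE
      for (attempt in seq_len(max_restarts)) {
        infl <- lapply(seq_len(ncell), function(i) {
          p <- ellipse_poly(0, 0, aa[i] + g / 2, bb[i] + g / 2, ang[i],
                            n = 20L, area_match = FALSE)
          p
        })
        vinfl <- lapply(seq_len(nv), function(i)
          ellipse_poly(0, 0, rv + g / 2, rv + g / 2, 0, n = 16L,
                       area_match = FALSE))
        extx <- vapply(infl, function(p) max(abs(p[, 1])), 0)
        exty <- vapply(infl, function(p) max(abs(p[, 2])), 0)
        if (any(2 * extx >= L) || any(2 * exty >= L))
          stop("packing failure: a cell does not fit in the tile")
        ## initial positions: randomly assigned jittered hex lattice sites
        ## (close to the final packed state, so relaxation converges quickly)
        sp <- min(sqrt(L^2 / ncell / 0.866), L / 2.5)
        sites <- NULL
        while (is.null(sites) || nrow(sites) < ncell) {
          ys <- seq(sp / 2, L - sp / 2, by = sp * 0.866)
          sites <- do.call(rbind, lapply(seq_along(ys), function(r) {
            xo <- if (r %% 2 == 0) sp / 2 else sp * 0.75
            xs <- seq(xo, L - sp / 4, by = sp)
            cbind(xs, ys[r])
          }))
          sp <- sp * 0.96
        }
        sites <- sites[sample.int(nrow(sites), ncell), , drop = FALSE]
        c0 <- sites + matrix(runif(2 * ncell, -0.15, 0.15) * sp, ncol = 2)
        c0[, 1] <- pmin(pmax(c0[, 1], extx), L - extx)
        c0[, 2] <- pmin(pmax(c0[, 2], exty), L - exty)
        res <- .cpp_relax_cells(c0, infl, as.matrix(vessels[, c("cx", "cy")]),
                                vinfl, L, as.integer(max_sweeps), 1e-7)
        if (isTRUE(res$converged)) {
          cells <- data.frame(cx = res$centers[, 1], cy = res$centers[, 2],
                              a = aa, b = bb, angle = ang)
          placed <- TRUE
          break
        }
        if (attempt == ceiling(max_restarts / 2) && g > 5e-4) g <- g / 2
      }
      if (!placed)
        stop("packing failure: could not place cells without overlap at the ",
             "requested fractions (EIS fraction too high for this clearance)")
    }
    ve_achieved <- 1 - vp_achieved - sum(pi * cells$a * cells$b) / L^2
    if (abs(ve_achieved - target_ve) > 0.01)
      stop("packing failure: achieved ve misses the target by more than 0.01")
    dom <- structure(list(
      voxel_side = L, side = L, is_extended = FALSE,
      cells = cells, vessels = vessels,
      ve_achieved = ve_achieved, vp_achieved = vp_achieved,
      veis_achieved = 1 - ve_achieved - vp_achieved,
      seed = as.integer(seed), gap = g), class = "tissue_domain")
    validate_domain(dom)
    dom
  })
}

#' Validate a tissue domain
#'
#' Checks the fraction partition and (for modest shape counts) the pairwise
#' separation of all shapes.
#' @param domain a `tissue_domain`
#' @param check_overlap also run the polygon separation test
#' @return the domain, invisibly; stops on violation
#' @export
validate_domain <- function(domain, check_overlap = TRUE) {
  stopifnot(inherits(domain, "tissue_domain"))
  fr <- c(domain$ve_achieved, domain$vp_achieved, domain$veis_achieved)
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions do not sum to 1")
  if (domain$ve_achieved <= 0 || domain$ve_achieved >= 1 ||
      domain$vp_achieved <= 0 || domain$vp_achieved >= 1)
    stop("fractions out of (0,1)")
  area_geo <- (sum(pi * domain$cells$a * domain$cells$b) +
               sum(pi * domain$vessels$r^2)) / domain$voxel_side^2
  if (abs(area_geo - (1 - domain$ve_achieved)) >
      1e-6 * max(1e-12, 1 - domain$ve_achieved))
    stop("stored fractions disagree with the stored geometry")
  if (check_overlap && nrow(domain$cells) + nrow(domain$vessels) <= 5000) {
    g <- min_shape_gap(domain)
    if (!is.infinite(g) && g <= 0) stop("overlapping shapes in domain")
  }
  invisible(domain)
}

#' Minimum clearance between any two shapes of a domain
#'
#' @param domain a `tissue_domain`
#' @param n polygonization resolution for the separation test
#' @return the smallest pairwise gap [mm] (negative if shapes overlap)
#' @export
min_shape_gap <- function(domain, n = 48L) {
  polys <- domain_shape_polys(domain, n = n, area_match = FALSE)
  if (length(polys) < 2) return(Inf)
  .cpp_min_pair_gap(polys)
}

# world-coordinate polygons of every shape (cells then vessels)
domain_shape_polys <- function(domain, n = 48L, area_match = FALSE) {
  c(lapply(seq_len(nrow(domain$cells)), function(i)
      with(domain$cells[i, ], ellipse_poly(cx, cy, a, b, angle, n, area_match))),
    lapply(seq_len(nrow(domain$vessels)), function(i)
      with(domain$vessels[i, ], ellipse_poly(cx, cy, r, r, 0, n, area_match))))
}

#' Tile a voxel domain into the 3x3 extended domain
#'
#' Surrounds the voxel with eight identical copies so that the central voxel
#' of interest, `[L, 2L] x [L, 2L]`, sees realistic (periodic-neighbour)
#' boundary conditions instead of artificial sealed walls.
#'
#' @param domain a single-tile `tissue_domain`
#' @return a `tissue_domain` of side `3 L` with `is_extended = TRUE`; the
#'   achieved fractions are unchanged
#' @export
tile_extended_domain <- function(domain) {
  stopifnot(inherits(domain, "tissue_domain"))
  if (isTRUE(domain$is_extended)) stop("domain is already extended")
  L <- domain$voxel_side
  off <- as.matrix(expand.grid(ox = c(0, L, 2 * L), oy = c(0, L, 2 * L)))
  cells <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
    cc <- domain$cells
    if (nrow(cc)) { cc$cx <- cc$cx + off[k, 1]; cc$cy <- cc$cy + off[k, 2] }
    cc
  }))
  vessels <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
    vv <- domain$vessels
    vv$cx <- vv$cx + off[k, 1]; vv$cy <- vv$cy + off[k, 2]
    vv
  }))
  structure(list(
    voxel_side = L, side = 3 * L, is_extended = TRUE,
    cells = cells, vessels = vessels,
    ve_achieved = domain$ve_achieved, vp_achieved = domain$vp_achieved,
    veis_achieved = domain$veis_achieved,
    seed = domain$seed, gap = domain$gap), class = "tissue_domain")
}

#' Extract the central tile of an extended domain
#'
#' Shapes whose centres lie in the central voxel `[L, 2L]^2` are shifted back
#' to `[0, L]^2`; for a tiling produced by [tile_extended_domain()] this
#' reproduces the input domain.
#'
#' @param domain an extended `tissue_domain`
#' @return a single-tile `tissue_domain`
#' @export
central_tile <- function(domain) {
  stopifnot(inherits(domain, "tissue_domain"), isTRUE(domain$is_extended))
  L <- domain$voxel_side
  inwin <- function(x, y) x >= L & x < 2 * L & y >= L & y < 2 * L
  cells <- domain$cells[inwin(domain$cells$cx, domain$cells$cy), , drop = FALSE]
  vessels <- domain$vessels[inwin(domain$vessels$cx, domain$vessels$cy), ,
                            drop = FALSE]
  cells$cx <- cells$cx - L; cells$cy <- cells$cy - L
  vessels$cx <- vessels$cx - L; vessels$cy <- vessels$cy - L
  rownames(cells) <- NULL; rownames(vessels) <- NULL
  structure(list(
    voxel_side = L, side = L, is_extended = FALSE,
    cells = cells, vessels = vessels,
    ve_achieved = domain$ve_achieved, vp_achieved = domain$vp_achieved,
    veis_achieved = domain$veis_achieved,
    seed = domain$seed, gap = domain$gap), class = "tissue_domain")
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf("<tissue_domain> side %.3g mm%s, %d cells, %d vessels\n",
              x$side, if (isTRUE(x$is_extended)) " (3x3 extended)" else "",
              nrow(x$cells), nrow(x$vessels)))
  cat(sprintf("  ve = %.4f  vp = %.4f  veis = %.4f  (seed %d)\n",
              x$ve_achieved, x$vp_achieved, x$veis_achieved, x$seed))
  invisible(x)
}

#' Serialize a tissue domain to JSON
#' @param domain a `tissue_domain`
#' @param path optional file path; when `NULL` the JSON string is returned
#' @return `path` invisibly, or the JSON string
#' @export
domain_to_json <- function(domain, path = NULL) {
  stopifnot(inherits(domain, "tissue_domain"))
  obj <- unclass(domain)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a tissue domain from JSON
#' @param path file path or JSON string produced by [domain_to_json()]
#' @return a `tissue_domain`
#' @export
domain_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  empty_cells <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                            b = numeric(0), angle = numeric(0))
  empty_vessels <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  obj$cells <- if (length(obj$cells)) as.data.frame(obj$cells) else empty_cells
  obj$vessels <- if (length(obj$vessels)) as.data.frame(obj$vessels) else
    empty_vessels
  obj$seed <- as.integer(obj$seed)
  dom <- structure(obj, class = "tissue_domain")
  validate_domain(dom, check_overlap = FALSE)
  dom
}
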