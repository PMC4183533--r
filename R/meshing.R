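# Triangulation of the EES: cells and vessels are holes, every boundary edge
# is tagged (vessel / cell / outer).  The triangulator is an unstructured
# Delaunay mesh refined to a minimum-angle criterion; see src/mesher.cpp.

# polygonization resolution for a hole of max radius r at edge target h:
# enough vertices that the chord error is <= h/4 and the edge length <= h
.hole_n <- function(r, perim, h, nmin) {
  max(nmin, ceiling(perim / h), ceiling(pi * sqrt(2 * r / h)))
}

# Ramanujan approximation to the ellipse perimeter
.ellipse_perim <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Triangulate the extravascular extracellular space of a domain
#'
#' Produces a conforming triangular mesh of the EES: the outer square minus
#' every cell and vessel, which are left as unmeshed holes.  Hole boundaries
#' are polygonized with chord error at most `target_edge/4` (and the polygon
#' scaled to preserve the analytic shape area), boundary edges are tagged by
#' the type of the shape that owns them, and the mesh is refined until all
#' triangles meet the minimum-angle quality criterion.
#'
#' @param domain a `tissue_domain` (single tile or 3x3 extended)
#' @param target_edge target triangle edge length [mm]; the study-fidelity
#'   value is 0.002 mm (2 um); coarser meshes are appropriate for quick runs
#' @param min_angle_deg quality threshold for Ruppert refinement [degrees]
#' @param max_verts safety cap on the number of mesh vertices
#' @return a `tri_mesh` with `nodes` (n x 2, mm), `triangles` (m x 3 indices),
#'   `boundary_edges` (data frame: `node1`, `node2`, `tag`, `shape_id`),
#'   `element_areas` [mm^2], `target_edge`, and summary fields
#' @export
mesh_ees <- function(domain, target_edge = 0.006, min_angle_deg = 20,
                     max_verts = 2e6) {
  stopifnot(inherits(domain, "tissue_domain"), target_edge > 0)
  h <- target_edge
  S <- domain$side
  ncell <- nrow(domain$cells)
  nves <- nrow(domain$vessels)
  holes <- vector("list", ncell + nves)
  tags <- integer(ncell + nves)
  if (ncell) for (i in seq_len(ncell)) {
    ci <- domain$cells[i, ]
    n <- .hole_n(ci$a, .ellipse_perim(ci$a, ci$b), h, 12L)
    holes[[i]] <- ellipse_poly(ci$cx, ci$cy, ci$a, ci$b, ci$angle, n,
                               area_match = TRUE, wobble = 1e-6)
    tags[i] <- 2L
  }
  if (nves) for (i in seq_len(nves)) {
    vi <- domain$vessels[i, ]
    n <- .hole_n(vi$r, 2 * pi * vi$r, h, 16L)
    holes[[ncell + i]] <- ellipse_poly(vi$cx, vi$cy, vi$r, vi$r, 0, n,
                                       area_match = TRUE, wobble = 1e-6)
    tags[ncell + i] <- 1L
  }
  ## boundary points: outer square then hole rings; segments are consecutive
  k <- ceiling(S / h)
  s1 <- seq(0, S, length.out = k + 1)[-(k + 1)]
  outer_pts <- rbind(cbind(s1, 0), cbind(S, s1), cbind(S - s1, S),
                     cbind(0, S - s1))
  no <- nrow(outer_pts)
  pts <- outer_pts
  seg <- cbind(seq_len(no), c(seq_len(no)[-1], 1L))
  seg_tag <- rep(0L, no)
  seg_sid <- rep(-1L, no)
  for (j in seq_along(holes)) {
    base <- nrow(pts)
    nh <- nrow(holes[[j]])
    pts <- rbind(pts, holes[[j]])
    seg <- rbind(seg, cbind(base + seq_len(nh), base + c(seq_len(nh)[-1], 1L)))
    seg_tag <- c(seg_tag, rep(tags[j], nh))
    seg_sid <- c(seg_sid, rep(j, nh))
  }
  res <- .cpp_mesh_ees(pts, seg, seg_tag, seg_sid, holes, S, h,
                       min_angle_deg = min_angle_deg,
                       max_verts = as.integer(max_verts))
  nodes <- res$nodes
  tri <- res$triangles
  x <- nodes[, 1]; y <- nodes[, 2]
  a1 <- tri[, 1]; a2 <- tri[, 2]; a3 <- tri[, 3]
  areas <- 0.5 * ((x[a2] - x[a1]) * (y[a3] - y[a1]) -
                  (y[a2] - y[a1]) * (x[a3] - x[a1]))
  if (any(areas <= 0)) stop("meshing failure: non-positive element area")
  tagname <- c("outer", "vessel", "cell")[res$seg_tag + 1L]
  be <- data.frame(node1 = res$segments[, 1], node2 = res$segments[, 2],
                   tag = tagname, shape_id = res$seg_sid)
  ees_area <- S^2 - sum(pi * domain$cells$a * domain$cells$b) -
    sum(pi * domain$vessels$r^2)
  m <- structure(list(
    nodes = nodes, triangles = tri, boundary_edges = be,
    element_areas = areas, target_edge = h,
    ees_area_domain = ees_area,
    min_angle_deg = res$min_angle_deg,
    n_bad_quality = res$n_bad_quality,
    domain_side = S, tile_side = domain$voxel_side,
    is_extended = isTRUE(domain$is_extended)), class = "tri_mesh")
  m
}

#' Mean edge length of a mesh
#' @param mesh a `tri_mesh`
#' @return mean length over unique edges [mm]
#' @export
mesh_mean_edge <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), , drop = FALSE]
  p <- mesh$nodes
  mean(sqrt((p[e[, 1], 1] - p[e[, 2], 1])^2 + (p[e[, 1], 2] - p[e[, 2], 2])^2))
}

#' Minimum interior angle over all mesh triangles
#' @param mesh a `tri_mesh`
#' @return smallest angle [degrees]
#' @export
mesh_min_angle <- function(mesh) {
  p <- mesh$nodes; tri <- mesh$triangles
  l2 <- function(i, j) (p[tri[, i], 1] - p[tri[, j], 1])^2 +
    (p[tri[, i], 2] - p[tri[, j], 2])^2
  A <- mesh$element_areas
  e12 <- l2(1, 2); e23 <- l2(2, 3); e31 <- l2(3, 1)
  ang <- function(opp2, s1, s2) atan2(2 * A / sqrt(s1 * s2),
                                      (s1 + s2 - opp2) / (2 * sqrt(s1 * s2)))
  m <- pmin(ang(e23, e12, e31), ang(e31, e12, e23), ang(e12, e23, e31))
  min(m) * 180 / pi
}

#' Euler characteristic of a mesh
#'
#' For a triangulated planar region with `k` holes the Euler characteristic
#' `V - E + F` (faces excluding the unbounded one) equals `1 - k`.
#' @param mesh a `tri_mesh`
#' @return integer Euler characteristic
#' @export
mesh_euler_characteristic <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nrow(mesh$nodes) - length(unique(key)) + nrow(tri)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(paste0("<tri_mesh> %d nodes, %d triangles, %d boundary edges\n",
                     "  mean edge %.3g mm (target %.3g), min angle %.1f deg,",
                     " EES area %.4g mm^2\n"),
              nrow(x$nodes), nrow(x$triangles), nrow(x$boundary_edges),
              mesh_mean_edge(x), x$target_edge, x$min_angle_deg,
              sum(x$element_areas)))
  invisible(x)
}

#' Write a mesh in Triangle-style text format
#'
#' Writes `<stem>.node`, `<stem>.ele` and `<stem>.edge` (the latter holds the
#' tagged boundary edges; tag codes: 0 outer, 1 vessel, 2 cell, followed by
#' the owning shape id).
#' @param mesh a `tri_mesh`
#' @param stem output path stem
#' @return `stem`, invisibly
#' @export
write_mesh <- function(mesh, stem) {
  nd <- mesh$nodes
  con <- file(paste0(stem, ".node"), "w")
  writeLines(sprintf("%d 2 0 0", nrow(nd)), con)
  writeLines(sprintf("%d %.17g %.17g", seq_len(nrow(nd)), nd[, 1], nd[, 2]), con)
  close(con)
  tr <- mesh$triangles
  con <- file(paste0(stem, ".ele"), "w")
  writeLines(sprintf("%d 3 0", nrow(tr)), con)
  writeLines(sprintf("%d %d %d %d", seq_len(nrow(tr)), tr[, 1], tr[, 2],
                     tr[, 3]), con)
  close(con)
  be <- mesh$boundary_edges
  code <- match(be$tag, c("outer", "vessel", "cell")) - 1L
  con <- file(paste0(stem, ".edge"), "w")
  writeLines(sprintf("%d 1", nrow(be)), con)
  writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(be)), be$node1, be$node2,
                     code, be$shape_id), con)
  close(con)
  ## metadata needed to rebuild summary fields
  writeLines(jsonlite::toJSON(list(target_edge = mesh$target_edge,
                                   ees_area_domain = mesh$ees_area_domain,
                                   domain_side = mesh$domain_side,
                                   tile_side = mesh$tile_side,
                                   is_extended = mesh$is_extended),
                              auto_unbox = TRUE, digits = NA),
             paste0(stem, ".meta.json"))
  invisible(stem)
}

#' Read a mesh written by [write_mesh()]
#' @param stem path stem used at write time
#' @return a `tri_mesh`
#' @export
read_mesh <- function(stem) {
  nd <- read.table(paste0(stem, ".node"), skip = 1)
  nodes <- as.matrix(nd[, 2:3])
  dimnames(nodes) <- NULL
  el <- read.table(paste0(stem, ".ele"), skip = 1)
  tri <- as.matrix(el[, 2:4])
  dimnames(tri) <- NULL
  ed <- read.table(paste0(stem, ".edge"), skip = 1)
  be <- data.frame(node1 = ed[, 2], node2 = ed[, 3],
                   tag = c("outer", "vessel", "cell")[ed[, 4] + 1L],
                   shape_id = ed[, 5])
  meta <- jsonlite::fromJSON(paste0(stem, ".meta.json"))
  x <- nodes[, 1]; y <- nodes[, 2]
  areas <- 0.5 * ((x[tri[, 2]] - x[tri[, 1]]) * (y[tri[, 3]] - y[tri[, 1]]) -
                  (y[tri[, 2]] - y[tri[, 1]]) * (x[tri[, 3]] - x[tri[, 1]]))
  structure(list(nodes = nodes, triangles = tri, boundary_edges = be,
                 element_areas = areas, target_edge = meta$target_edge,
                 ees_area_domain = meta$ees_area_domain,
                 min_angle_deg = NA_real_, n_bad_quality = NA_integer_,
                 domain_side = meta$domain_side, tile_side = meta$tile_side,
                 is_extended = meta$is_extended), class = "tri_mesh")
}
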