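## Triangle-mesh container and geometric queries (ray casting, closest point).
## The surface_mesh is the substrate for both the aortic root and all
## skirt-to-anatomy distance queries.

#' Construct a triangulated surface mesh
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @param region optional character vector, one label per triangle, one of
#'   `"LVOT"`, `"LEAFLET"`, `"INTERLEAFLET_TRIANGLE"`, `"ASCENDING_AORTA"`
#'   (or `"UNRESOLVED"` for meshes loaded without a label sidecar).
#' @param material optional character vector per triangle: `"WALL"`,
#'   `"LEAFLET_TISSUE"` or `"CALCIUM"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, region = NULL, material = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3) stop("triangles must have 3 columns")
  if (max(triangles) > nrow(vertices) || min(triangles) < 1)
    stop("triangle indices out of range")
  n_tri <- nrow(triangles)
  if (is.null(region)) region <- rep("UNRESOLVED", n_tri)
  if (is.null(material)) material <- rep("WALL", n_tri)
  stopifnot(length(region) == n_tri, length(material) == n_tri)
  structure(list(vertices = vertices, triangles = triangles,
                 region = as.character(region),
                 material = as.character(material)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  if (!all(x$region == "UNRESOLVED")) {
    tab <- table(x$region)
    cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-triangle areas of a surface mesh
#' @param mesh a `surface_mesh`.
#' @return numeric vector of areas in mm^2.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  t1 <- v[mesh$triangles[, 1], , drop = FALSE]
  t2 <- v[mesh$triangles[, 2], , drop = FALSE]
  t3 <- v[mesh$triangles[, 3], , drop = FALSE]
  e1 <- t2 - t1
  e2 <- t3 - t1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

## Precompute triangle vertex arrays + z bounds once per mesh for repeated
## ray queries. Stored in an environment keyed off the mesh object itself.
mesh_query_cache <- function(mesh) {
  if (!is.null(attr(mesh, "query_cache"))) return(attr(mesh, "query_cache"))
  v <- mesh$vertices
  a <- v[mesh$triangles[, 1], , drop = FALSE]
  b <- v[mesh$triangles[, 2], , drop = FALSE]
  c3 <- v[mesh$triangles[, 3], , drop = FALSE]
  list(a = a, b = b, c = c3,
       e1 = b - a, e2 = c3 - a,
       zmin = pmin(a[, 3], b[, 3], c3[, 3]),
       zmax = pmax(a[, 3], b[, 3], c3[, 3]))
}

#' Prepare a mesh for repeated geometric queries
#'
#' Attaches a precomputed edge/bounds cache so that batches of ray casts do
#' not rebuild per-triangle arrays.
#' @param mesh a `surface_mesh`.
#' @return The mesh with a `query_cache` attribute.
#' @export
prepare_mesh <- function(mesh) {
  attr(mesh, "query_cache") <- mesh_query_cache(mesh)
  mesh
}

#' First ray-triangle intersection (Moller-Trumbore, vectorised over triangles)
#'
#' Casts a single ray against all mesh triangles, pruned by the triangles'
#' z extent, and returns the nearest intersection.
#'
#' @param mesh a `surface_mesh`, ideally passed through [prepare_mesh()].
#' @param origin numeric length-3 ray origin (mm).
#' @param dir numeric length-3 unit direction.
#' @param tmax maximum ray parameter (mm) to accept.
#' @return list with `hit` (logical), `t` (distance along the ray),
#'   `triangle` (index) — `t = Inf`, `triangle = NA` when there is no hit.
#' @export
ray_first_hit <- function(mesh, origin, dir, tmax = Inf) {
  if (sqrt(sum(dir^2)) < 1e-12) stop("degenerate ray direction")
  q <- mesh_query_cache(mesh)
  ## z-window prune: a hit at parameter t <= tmax has z within this window
  if (is.finite(tmax)) {
    zlo <- origin[3] - abs(dir[3]) * tmax - 1e-9
    zhi <- origin[3] + abs(dir[3]) * tmax + 1e-9
    keep <- which(q$zmax >= zlo & q$zmin <= zhi)
  } else {
    keep <- seq_along(q$zmin)
  }
  if (length(keep) == 0)
    return(list(hit = FALSE, t = Inf, triangle = NA_integer_))
  e1 <- q$e1[keep, , drop = FALSE]
  e2 <- q$e2[keep, , drop = FALSE]
  a <- q$a[keep, , drop = FALSE]
  ## pvec = dir x e2
  px <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  py <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  pz <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  det <- e1[, 1] * px + e1[, 2] * py + e1[, 3] * pz
  ok <- abs(det) > 1e-12
  inv <- ifelse(ok, 1 / det, 0)
  tx <- origin[1] - a[, 1]; ty <- origin[2] - a[, 2]; tz <- origin[3] - a[, 3]
  u <- (tx * px + ty * py + tz * pz) * inv
  ## qvec = tvec x e1
  qx <- ty * e1[, 3] - tz * e1[, 2]
  qy <- tz * e1[, 1] - tx * e1[, 3]
  qz <- tx * e1[, 2] - ty * e1[, 1]
  v <- (dir[1] * qx + dir[2] * qy + dir[3] * qz) * inv
  tt <- (e2[, 1] * qx + e2[, 2] * qy + e2[, 3] * qz) * inv
  eps <- 1e-9
  valid <- ok & u >= -eps & v >= -eps & (u + v) <= 1 + eps &
    tt > eps & tt <= tmax
  if (!any(valid))
    return(list(hit = FALSE, t = Inf, triangle = NA_integer_))
  i <- which(valid)[which.min(tt[valid])]
  list(hit = TRUE, t = tt[i], triangle = keep[i])
}

#' Closest point on a triangle mesh to a query point
#'
#' Vectorised point-to-triangle distance (Ericson's region classification)
#' over all triangles; used as the no-hit fallback for skirt elements.
#'
#' @param mesh a `surface_mesh`.
#' @param p numeric length-3 query point.
#' @return list with `distance` (mm) and `triangle` (index of nearest
#'   triangle).
#' @export
mesh_closest_point <- function(mesh, p) {
  q <- mesh_query_cache(mesh)
  a <- q$a; b <- q$b; c3 <- q$c
  ab <- q$e1; ac <- q$e2
  apx <- p[1] - a[, 1]; apy <- p[2] - a[, 2]; apz <- p[3] - a[, 3]
  d1 <- ab[, 1] * apx + ab[, 2] * apy + ab[, 3] * apz
  d2 <- ac[, 1] * apx + ac[, 2] * apy + ac[, 3] * apz
  bpx <- p[1] - b[, 1]; bpy <- p[2] - b[, 2]; bpz <- p[3] - b[, 3]
  d3 <- ab[, 1] * bpx + ab[, 2] * bpy + ab[, 3] * bpz
  d4 <- ac[, 1] * bpx + ac[, 2] * bpy + ac[, 3] * bpz
  cpx <- p[1] - c3[, 1]; cpy <- p[2] - c3[, 2]; cpz <- p[3] - c3[, 3]
  d5 <- ab[, 1] * cpx + ab[, 2] * cpy + ab[, 3] * cpz
  d6 <- ac[, 1] * cpx + ac[, 2] * cpy + ac[, 3] * cpz
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  ## default: interior barycentric projection
  v <- ifelse(abs(denom) > 0, vb / denom, 0)
  w <- ifelse(abs(denom) > 0, vc / denom, 0)
  ## vertex regions
  v <- ifelse(d1 <= 0 & d2 <= 0, 0, v)
  w <- ifelse(d1 <= 0 & d2 <= 0, 0, w)
  v <- ifelse(d3 >= 0 & d4 <= d3, 1, v)
  w <- ifelse(d3 >= 0 & d4 <= d3, 0, w)
  v <- ifelse(d6 >= 0 & d5 <= d6, 0, v)
  w <- ifelse(d6 >= 0 & d5 <= d6, 1, w)
  ## edge AB
  onAB <- vc <= 0 & d1 >= 0 & d3 <= 0 & (d1 - d3) != 0
  v <- ifelse(onAB, d1 / (d1 - d3), v)
  w <- ifelse(onAB, 0, w)
  ## edge AC
  onAC <- vb <= 0 & d2 >= 0 & d6 <= 0 & (d2 - d6) != 0
  v <- ifelse(onAC, 0, v)
  w <- ifelse(onAC, d2 / (d2 - d6), w)
  ## edge BC
  num <- d4 - d3
  den <- (d4 - d3) + (d5 - d6)
  onBC <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0 & den != 0
  tbc <- ifelse(onBC, num / den, 0)
  v <- ifelse(onBC, 1 - tbc, v)
  w <- ifelse(onBC, tbc, w)
  v <- pmin(pmax(v, 0), 1)
  w <- pmin(pmax(w, 0), 1 - v)
  qx <- a[, 1] + ab[, 1] * v + ac[, 1] * w
  qy <- a[, 2] + ab[, 2] * v + ac[, 2] * w
  qz <- a[, 3] + ab[, 3] * v + ac[, 3] * w
  d2all <- (qx - p[1])^2 + (qy - p[2])^2 + (qz - p[3])^2
  i <- which.min(d2all)
  list(distance = sqrt(d2all[i]), triangle = i)
}
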