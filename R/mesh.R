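## Structured triangular mesh of a disk, built from concentric rings of
## nodes.  Deterministic (no randomized Delaunay), conforming, and sized by a
## target edge length.

#' Build a triangular finite-element mesh of a disk
#'
#' Nodes are placed on concentric rings (ring k carries 8k nodes, so the
#' mesh shares the full symmetry group of the square raster: 90-degree
#' rotations and axis reflections map it onto itself).  With \code{n} rings
#' the mesh has \eqn{1 + 4n(n+1)} nodes and \eqn{8n^2} triangles;
#' \code{target_edge_length = radius / 36} reproduces a mesh of about
#' 5.3e3 nodes / 1.0e4 elements on a 50 mm domain.
#'
#' @param domain_radius disk radius (mm).
#' @param target_edge_length requested edge length (mm).
#' @return an object of class \code{fem_mesh}: list with \code{nodes}
#'   (n x 2), \code{elements} (m x 3 integer, 1-based, counterclockwise),
#'   \code{boundary_nodes}, \code{boundary_edges} (consecutive boundary node
#'   pairs), \code{radius}, \code{h}, and precomputed element areas.
#' @export
build_mesh <- function(domain_radius = 50, target_edge_length = 2.5) {
  stopifnot(domain_radius > 0, target_edge_length > 0)
  n <- max(1L, as.integer(round(domain_radius / target_edge_length)))
  ring_n <- c(1L, 8L * seq_len(n))            # nodes per ring (ring 0 = center)
  ring_start <- cumsum(c(1L, ring_n))[seq_along(ring_n)]  # first index per ring
  nodes <- matrix(0, nrow = 1 + 4 * n * (n + 1), ncol = 2)
  for (k in seq_len(n)) {
    m <- 8L * k
    th <- 2 * pi * (seq_len(m) - 1) / m
    r <- domain_radius * k / n
    nodes[ring_start[k + 1] + seq_len(m) - 1L, ] <- cbind(r * cos(th),
                                                          r * sin(th))
  }

  tri <- vector("list", n)
  # center fan
  tri[[1]] <- cbind(1L, 1L + seq_len(8L), 1L + c(seq_len(7L) + 1L, 1L))
  for (k in seq_len(n)[-1]) {
    m1 <- 8L * (k - 1L); m2 <- 8L * k
    s1 <- ring_start[k]; s2 <- ring_start[k + 1]
    inner <- function(i) s1 + (i %% m1)
    outer <- function(j) s2 + (j %% m2)
    tt <- matrix(0L, nrow = m1 + m2, ncol = 3)
    i <- 0L; j <- 0L; t <- 0L
    while (i < m1 || j < m2) {
      adv_inner <- if (i < m1 && j < m2) {
        (i + 1) / m1 <= (j + 1) / m2
      } else i < m1
      t <- t + 1L
      if (adv_inner) {
        tt[t, ] <- c(inner(i), inner(i + 1L), outer(j))
        i <- i + 1L
      } else {
        tt[t, ] <- c(outer(j), inner(i), outer(j + 1L))
        j <- j + 1L
      }
    }
    tri[[k]] <- tt
  }
  elements <- do.call(rbind, tri)

  # enforce counterclockwise orientation, verify non-degeneracy
  p1 <- nodes[elements[, 1], , drop = FALSE]
  p2 <- nodes[elements[, 2], , drop = FALSE]
  p3 <- nodes[elements[, 3], , drop = FALSE]
  signed <- 0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                   (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
  flip <- signed < 0
  if (any(flip))
    elements[flip, c(2, 3)] <- elements[flip, c(3, 2)]
  areas <- abs(signed)
  if (any(areas <= .Machine$double.eps * domain_radius^2))
    stop("mesher produced a degenerate (zero-area) triangle")

  bnd <- ring_start[n + 1] + seq_len(8L * n) - 1L
  bedges <- cbind(bnd, c(bnd[-1], bnd[1]))
  mesh <- structure(list(nodes = nodes, elements = elements,
                         boundary_nodes = bnd, boundary_edges = bedges,
                         radius = domain_radius, h = domain_radius / n,
                         areas = areas),
                    class = "fem_mesh")
  mesh$lookup <- .mesh_lookup(mesh)
  mesh$fem <- fem_matrices(mesh)   # cached unit stiffness/mass matrices
  mesh
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("FEM mesh: %d nodes, %d triangles, radius %g mm, h ~ %.3g mm\n",
              nrow(x$nodes), nrow(x$elements), x$radius, x$h))
  invisible(x)
}

## uniform-grid spatial index over triangle bounding boxes, for point location
.mesh_lookup <- function(mesh, cell = NULL) {
  if (is.null(cell)) cell <- 2 * mesh$h
  R <- mesh$radius
  nc <- max(1L, ceiling(2 * R / cell))
  cell <- 2 * R / nc
  el <- mesh$elements
  xs <- matrix(mesh$nodes[el, 1], ncol = 3)
  ys <- matrix(mesh$nodes[el, 2], ncol = 3)
  cx0 <- pmax(1L, pmin(nc, 1L + floor((apply(xs, 1, min) + R) / cell)))
  cx1 <- pmax(1L, pmin(nc, 1L + floor((apply(xs, 1, max) + R) / cell)))
  cy0 <- pmax(1L, pmin(nc, 1L + floor((apply(ys, 1, min) + R) / cell)))
  cy1 <- pmax(1L, pmin(nc, 1L + floor((apply(ys, 1, max) + R) / cell)))
  buckets <- vector("list", nc * nc)
  for (t in seq_len(nrow(el))) {
    for (ix in cx0[t]:cx1[t]) for (iy in cy0[t]:cy1[t]) {
      id <- ix + (iy - 1L) * nc
      buckets[[id]] <- c(buckets[[id]], t)
    }
  }
  list(cell = cell, nc = nc, buckets = buckets)
}

#' Locate points in a mesh
#'
#' Finds, for each query point, the containing triangle and its barycentric
#' coordinates (P1 shape-function values).
#'
#' @param mesh a \code{\link{build_mesh}} result.
#' @param points n x 2 matrix (mm).
#' @param tol barycentric tolerance for boundary points.
#' @return list with integer vector \code{element} (NA if outside) and an
#'   n x 3 matrix \code{bary}.
#' @export
locate_points <- function(mesh, points, tol = 1e-9) {
  points <- matrix(points, ncol = 2)
  np <- nrow(points)
  lk <- mesh$lookup
  R <- mesh$radius
  ix <- pmax(1L, pmin(lk$nc, 1L + floor((points[, 1] + R) / lk$cell)))
  iy <- pmax(1L, pmin(lk$nc, 1L + floor((points[, 2] + R) / lk$cell)))
  cand <- lk$buckets[ix + (iy - 1L) * lk$nc]
  nci <- lengths(cand)
  pid <- rep.int(seq_len(np), nci)
  tid <- unlist(cand, use.names = FALSE)
  elem <- rep(NA_integer_, np)
  bary <- matrix(NA_real_, np, 3)
  if (length(tid)) {
    el <- mesh$elements
    a <- mesh$nodes[el[tid, 1], , drop = FALSE]
    b <- mesh$nodes[el[tid, 2], , drop = FALSE]
    cc <- mesh$nodes[el[tid, 3], , drop = FALSE]
    px <- points[pid, 1]; py <- points[pid, 2]
    det <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
           (cc[, 1] - a[, 1]) * (b[, 2] - a[, 2])
    l2 <- ((px - a[, 1]) * (cc[, 2] - a[, 2]) -
           (cc[, 1] - a[, 1]) * (py - a[, 2])) / det
    l3 <- ((b[, 1] - a[, 1]) * (py - a[, 2]) -
           (px - a[, 1]) * (b[, 2] - a[, 2])) / det
    l1 <- 1 - l2 - l3
    hit <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (any(hit)) {
      # first hit per point
      ok <- which(hit)
      keep <- ok[!duplicated(pid[ok])]
      elem[pid[keep]] <- tid[keep]
      bary[pid[keep], ] <- cbind(l1[keep], l2[keep], l3[keep])
    }
  }
  list(element = elem, bary = bary)
}

#' Export a mesh as plain-text node / element tables
#'
#' One node per line (\code{x y}); one element per line (\code{i j k},
#' 0-based indices).
#'
#' @param mesh a \code{\link{build_mesh}} result.
#' @param nodes_file,elements_file output paths.
#' @export
write_mesh <- function(mesh, nodes_file, elements_file) {
  utils::write.table(mesh$nodes, nodes_file, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(mesh$elements - 1L, elements_file, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}
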