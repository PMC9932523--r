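## P1 Galerkin finite elements for the continuous-wave diffusion equation
##   -div(D grad Phi) + mu_a Phi = S        in the disk
##    Phi + 2 A D dPhi/dn = 0               on the boundary (Robin, A = 1)
## The excitation and emission fields share the same mesh; only (mu_a, D)
## and the right-hand side differ.

## unit stiffness K (D = 1), unit mass M (coefficient 1), boundary mass Mb
fem_matrices <- function(mesh) {
  el <- mesh$elements
  ne <- nrow(el)
  x <- matrix(mesh$nodes[el, 1], ncol = 3)
  y <- matrix(mesh$nodes[el, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  c2 <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A <- mesh$areas
  ii <- jj <- kk <- mm <- numeric(9 * ne)
  pos <- 0
  for (a in 1:3) for (bb in 1:3) {
    idx <- pos * ne + seq_len(ne)
    ii[idx] <- el[, a]
    jj[idx] <- el[, bb]
    kk[idx] <- (b[, a] * b[, bb] + c2[, a] * c2[, bb]) / (4 * A)
    mm[idx] <- A / 12 * ifelse(a == bb, 2, 1)
    pos <- pos + 1
  }
  n <- nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(n, n))
  be <- mesh$boundary_edges
  len <- sqrt(rowSums((mesh$nodes[be[, 1], ] - mesh$nodes[be[, 2], ])^2))
  Mb <- Matrix::sparseMatrix(
    i = c(be[, 1], be[, 2], be[, 1], be[, 2]),
    j = c(be[, 1], be[, 2], be[, 2], be[, 1]),
    x = c(len / 3, len / 3, len / 6, len / 6), dims = c(n, n))
  list(K = K, M = M, Mb = Mb)
}

#' Assemble the FEM system for one wavelength
#'
#' Builds the symmetric positive-definite Galerkin matrix
#' \eqn{A = D K + \mu_a M + \gamma M_b} for
#' \eqn{-\nabla\cdot D\nabla\Phi + \mu_a\Phi = S} with the Robin boundary
#' condition \eqn{\Phi + 2 A_n D\,\partial\Phi/\partial n = 0}
#' (\eqn{\gamma = 1/(2A_n)}, index-matched \eqn{A_n = 1}).
#'
#' @param mesh a \code{\link{build_mesh}} result.
#' @param mu_a absorption coefficient (mm^-1).
#' @param D diffusion coefficient (mm).
#' @param robin_A boundary reflection parameter \eqn{A_n}; default 1.
#' @return a \code{fem_system}: list with the sparse matrix \code{A}, the
#'   unit mass matrix \code{M} (used to form load vectors from nodal source
#'   densities), the mesh, and a lazily cached Cholesky factor.
#' @export
assemble_fem_system <- function(mesh, mu_a, D, robin_A = 1) {
  stopifnot(mu_a > 0, D > 0, robin_A > 0)
  fm <- mesh$fem
  if (is.null(fm)) fm <- fem_matrices(mesh)
  A <- D * fm$K + mu_a * fm$M + (1 / (2 * robin_A)) * fm$Mb
  sys <- new.env(parent = emptyenv())
  sys$A <- methods::as(Matrix::forceSymmetric(A), "CsparseMatrix")
  sys$M <- fm$M
  sys$mesh <- mesh
  sys$mu_a <- mu_a
  sys$D <- D
  sys$factor <- NULL
  class(sys) <- "fem_system"
  sys
}

fem_factor <- function(system, fresh = FALSE) {
  if (fresh) return(Matrix::Cholesky(system$A, LDL = FALSE))
  if (is.null(system$factor))
    system$factor <- Matrix::Cholesky(system$A, LDL = FALSE)
  system$factor
}

## direct sparse solve (cached or fresh factorization), dense multi-RHS ok
fem_solve <- function(system, b, fresh_factor = FALSE) {
  f <- fem_factor(system, fresh = fresh_factor)
  as.matrix(Matrix::solve(f, b, system = "A"))
}

field_solution <- function(values, tag) {
  structure(list(values = as.numeric(values), wavelength_tag = tag),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("%s field on %d nodes: range [%.3g, %.3g]\n",
              x$wavelength_tag, length(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

#' Sheet-shaped excitation source
#'
#' Describes one LINAC beam sheet: a line at `angle` degrees whose signed
#' distance from the domain center is `offset` mm.  The sheet direction is
#' \eqn{(-\sin\theta, \cos\theta)} and its normal \eqn{(\cos\theta, \sin\theta)}.
#'
#' @param angle rotation angle (degrees).
#' @param offset signed sheet-to-center distance (mm).
#' @param strength source amplitude per unit length.
#' @param width effective half-width (mm); the source itself is modeled as a
#'   zero-width line, `width` only widens the intersection test.
#' @return a \code{sheet_source_spec}.
#' @export
sheet_spec <- function(angle, offset, strength = 1, width = 0) {
  stopifnot(strength > 0, width >= 0)
  structure(list(angle = angle, offset = offset, strength = strength,
                 width = width), class = "sheet_source_spec")
}

## quadrature points of a sheet chord and their weights; NULL if no overlap
sheet_chord <- function(mesh, sheet, step = 0.5) {
  R <- mesh$radius
  s <- sheet$offset
  if (abs(s) >= R + sheet$width || abs(s) >= R) return(NULL)
  th <- sheet$angle * pi / 180
  u <- c(cos(th), sin(th))    # normal
  v <- c(-sin(th), cos(th))   # along the sheet
  th2 <- sqrt(R^2 - s^2)
  npts <- max(2L, ceiling(2 * th2 / step))
  dt <- 2 * th2 / npts
  t <- -th2 + (seq_len(npts) - 0.5) * dt
  list(points = cbind(s * u[1] + t * v[1], s * u[2] + t * v[2]), dt = dt)
}

## consistent nodal vector for the line integral of P1 shape functions along
## the sheet chord; equals load vector / strength = measurement vector
sheet_quadrature_vector <- function(mesh, sheet, step = 0.5) {
  n <- nrow(mesh$nodes)
  ch <- sheet_chord(mesh, sheet, step)
  if (is.null(ch)) return(numeric(n))
  loc <- locate_points(mesh, ch$points)
  keep <- !is.na(loc$element)
  if (!any(keep)) return(numeric(n))
  idx <- as.vector(mesh$elements[loc$element[keep], ])
  w <- as.vector(loc$bary[keep, ]) * ch$dt
  out <- numeric(n)
  acc <- rowsum(w, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Nodal load vector for a sheet source
#'
#' Distributes a constant-strength line source along the sheet chord to mesh
#' nodes via P1 shape-function quadrature (0.5 mm steps).  The total load
#' equals \code{strength * chord length} up to quadrature error; a sheet
#' that misses the domain yields the zero vector.
#'
#' @param mesh a \code{\link{build_mesh}} result.
#' @param sheet a \code{\link{sheet_spec}}.
#' @param step quadrature step along the chord (mm).
#' @return numeric vector of length \code{nrow(mesh$nodes)}.
#' @export
sheet_source <- function(mesh, sheet, step = 0.5) {
  sheet$strength * sheet_quadrature_vector(mesh, sheet, step)
}

#' Solve the excitation diffusion equation
#'
#' @param system an excitation-wavelength \code{\link{assemble_fem_system}}.
#' @param source nodal load vector (e.g. \code{\link{sheet_source}}).
#' @param fresh_factor refactorize instead of using the cached Cholesky.
#' @return a \code{field_solution} with per-node excitation fluence.
#' @export
solve_excitation <- function(system, source, fresh_factor = FALSE) {
  phi <- fem_solve(system, source, fresh_factor)
  check_field(system, phi, source)
  field_solution(phi, "excitation")
}

#' Solve the emission diffusion equation
#'
#' The emission source density is \eqn{\Phi_x(r)\,\eta\mu_{af}(r)}; its
#' consistent load vector is \code{M \%*\% (phi_x * yield)}.
#'
#' @param system_m an emission-wavelength \code{\link{assemble_fem_system}}.
#' @param phi_x excitation \code{field_solution} on the same mesh.
#' @param yield_nodes per-node fluorescence yield \eqn{\eta\mu_{af}}.
#' @param fresh_factor refactorize instead of using the cached Cholesky.
#' @return a \code{field_solution} with per-node emission fluence.
#' @export
solve_emission <- function(system_m, phi_x, yield_nodes,
                           fresh_factor = FALSE) {
  stopifnot(length(yield_nodes) == nrow(system_m$mesh$nodes))
  vx <- if (inherits(phi_x, "field_solution")) phi_x$values else phi_x
  b <- as.numeric(system_m$M %*% (vx * yield_nodes))
  phi <- fem_solve(system_m, b, fresh_factor)
  check_field(system_m, phi, b)
  field_solution(phi, "emission")
}

check_field <- function(system, phi, b, rtol = 1e-8) {
  nb <- sqrt(sum(b^2))
  if (nb > 0) {
    res <- sqrt(sum((as.numeric(system$A %*% phi) - b)^2)) / nb
    if (res > rtol)
      stop(sprintf("linear solver residual %.3g exceeds %.1g", res, rtol))
  }
  invisible(TRUE)
}

#' Detector reading for one sheet
#'
#' Default mode integrates the interpolated emission field along the sheet
#' chord (the Radon-type line integral); \code{boundary_sum} instead sums
#' the emission fluence over all boundary nodes, mimicking a single-pixel
#' detector collecting the whole escaping flux.
#'
#' @param phi_m emission \code{field_solution}.
#' @param sheet a \code{\link{sheet_spec}}.
#' @param mesh the mesh the field lives on.
#' @param mode \code{"line_integral"} (default) or \code{"boundary_sum"}.
#' @param step quadrature step (mm) for the line integral.
#' @return a non-negative scalar.
#' @export
sheet_measurement <- function(phi_m, sheet, mesh,
                              mode = c("line_integral", "boundary_sum"),
                              step = 0.5) {
  mode <- match.arg(mode)
  v <- if (inherits(phi_m, "field_solution")) phi_m$values else phi_m
  if (mode == "boundary_sum") return(sum(v[mesh$boundary_nodes]))
  m <- sheet_quadrature_vector(mesh, sheet, step)
  sum(m * v)
}
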