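## Sheet-scan sinogram simulation: for every (angle, sheet offset) pair,
## solve excitation -> emission and integrate the emission field along the
## sheet.  The excitation and emission systems depend only on background
## optics, so both factorizations are computed once per phantom and reused
## across all sheets.

#' Sheet-scan acquisition geometry
#'
#' Defaults follow the standard protocol: 50 parallel sheets in 2 mm steps,
#' rotated from 0 to 170 degrees in 10-degree intervals (18 angles), with 1%
#' multiplicative Gaussian noise.
#'
#' @param n_angles number of rotation angles.
#' @param angle_start first angle (degrees).
#' @param angle_step angular increment (degrees).
#' @param n_sheets number of parallel sheets per angle.
#' @param sheet_step sheet spacing (mm).
#' @param noise_level relative noise sigma (fraction of each element).
#' @param noise_seed integer seed for the noise stream.
#' @return a \code{scan_geometry} list with derived \code{angles} and
#'   centered \code{offsets}.
#' @export
scan_geometry <- function(n_angles = 18L, angle_start = 0, angle_step = 10,
                          n_sheets = 50L, sheet_step = 2,
                          noise_level = 0.01, noise_seed = 1L) {
  n_angles <- as.integer(n_angles); n_sheets <- as.integer(n_sheets)
  stopifnot(n_angles >= 1, n_sheets >= 2, sheet_step > 0, noise_level >= 0)
  angles <- angle_start + angle_step * (seq_len(n_angles) - 1)
  offsets <- (seq_len(n_sheets) - (n_sheets + 1) / 2) * sheet_step
  structure(list(n_angles = n_angles, angle_start = angle_start,
                 angle_step = angle_step, n_sheets = n_sheets,
                 sheet_step = sheet_step, angles = angles, offsets = offsets,
                 noise_level = noise_level,
                 noise_seed = as.integer(noise_seed)),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "Scan geometry: %d angles (%g..%g deg), %d sheets (step %g mm), noise %g%%\n",
    x$n_angles, x$angles[1], x$angles[x$n_angles], x$n_sheets, x$sheet_step,
    100 * x$noise_level))
  invisible(x)
}

sinogram <- function(raw, geometry, upscaled = NULL) {
  structure(list(raw = raw, geometry = geometry, upscaled = upscaled),
            class = "xclt_sinogram")
}

#' @export
print.xclt_sinogram <- function(x, ...) {
  cat(sprintf("Sinogram: %d angles x %d sheets, max %.4g%s\n",
              nrow(x$raw), ncol(x$raw), max(x$raw),
              if (is.null(x$upscaled)) "" else
                sprintf(", upscaled %dx%d", nrow(x$upscaled),
                        ncol(x$upscaled))))
  invisible(x)
}

## sparse matrix whose columns are the sheet quadrature vectors m_s
## (load vector / strength), ordered angle-major (sheets fastest)
sheet_vector_matrix <- function(mesh, geometry, step = 0.5) {
  cols <- vector("list", geometry$n_angles * geometry$n_sheets)
  k <- 0
  for (a in geometry$angles) for (s in geometry$offsets) {
    k <- k + 1
    cols[[k]] <- sheet_quadrature_vector(mesh, sheet_spec(a, s), step)
  }
  n <- nrow(mesh$nodes)
  nz <- lapply(seq_along(cols), function(j) {
    i <- which(cols[[j]] != 0)
    cbind(i = i, j = rep.int(j, length(i)), x = cols[[j]][i])
  })
  nz <- do.call(rbind, nz)
  Matrix::sparseMatrix(i = nz[, "i"], j = nz[, "j"], x = nz[, "x"],
                       dims = c(n, length(cols)))
}

#' Simulate a noise-free sinogram for one phantom
#'
#' For every (angle, sheet) pair: solve the excitation diffusion equation
#' with that sheet as source, solve the emission equation driven by
#' \eqn{\Phi_x \eta\mu_{af}}, and integrate the emission field along the
#' sheet chord.  Both sparse systems are assembled and factorized once and
#' reused across all sheets.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param mesh a \code{\link{build_mesh}} result on the same domain.
#' @param geometry a \code{\link{scan_geometry}}.
#' @param strength source amplitude per unit length.
#' @param mode detector model, see \code{\link{sheet_measurement}}.
#' @param reuse_factorization if FALSE, each sheet refactorizes both systems
#'   from scratch (slow; provided to audit that cached factors change
#'   nothing).
#' @return an \code{xclt_sinogram} with the raw \code{n_angles x n_sheets}
#'   array (no noise, no upscaling).
#' @export
simulate_sinogram <- function(spec, mesh, geometry = scan_geometry(),
                              strength = 1,
                              mode = c("line_integral", "boundary_sum"),
                              reuse_factorization = TRUE) {
  mode <- match.arg(mode)
  bg <- spec$background
  sys_x <- assemble_fem_system(mesh, bg$mu_ax, bg$Dx)
  sys_m <- assemble_fem_system(mesh, bg$mu_am, bg$Dm)
  y <- yield_at(spec, mesh$nodes)
  if (reuse_factorization && mode == "line_integral") {
    B <- sheet_vector_matrix(mesh, geometry)
    phi_x <- fem_solve(sys_x, strength * B)
    phi_m <- fem_solve(sys_m, sys_m$M %*% (phi_x * y))
    p <- Matrix::colSums(B * phi_m)
  } else {
    p <- numeric(geometry$n_angles * geometry$n_sheets)
    k <- 0
    for (a in geometry$angles) for (s in geometry$offsets) {
      k <- k + 1
      sh <- sheet_spec(a, s, strength = strength)
      b <- sheet_source(mesh, sh)
      if (all(b == 0)) next
      px <- solve_excitation(sys_x, b, fresh_factor = !reuse_factorization)
      pm <- solve_emission(sys_m, px, y, fresh_factor = !reuse_factorization)
      p[k] <- sheet_measurement(pm, sh, mesh, mode = mode)
    }
  }
  raw <- t(matrix(p, nrow = geometry$n_sheets))  # angles x sheets
  sinogram(raw, geometry)
}

#' Precompute the phantom-to-sinogram linear operator
#'
#' Because targets perturb only \eqn{\mu_{af}}, the excitation and emission
#' systems are phantom-independent and the noise-free sinogram is linear in
#' the nodal yield: \eqn{p_s = \sum_i Q_{si} y_i}.  This precomputes Q
#' (rows: angle-major sheet index; columns: mesh nodes) so that thousands of
#' phantoms can be simulated with one matrix-vector product each.  Exactly
#' the same algebra as \code{\link{simulate_sinogram}}.
#'
#' @inheritParams simulate_sinogram
#' @param background an \code{\link{optical_properties}} object.
#' @return a \code{sinogram_operator}: list with dense matrix \code{Q},
#'   the mesh and geometry.
#' @export
sinogram_operator <- function(mesh, geometry = scan_geometry(),
                              background = optical_properties(),
                              strength = 1) {
  sys_x <- assemble_fem_system(mesh, background$mu_ax, background$Dx)
  sys_m <- assemble_fem_system(mesh, background$mu_am, background$Dm)
  B <- sheet_vector_matrix(mesh, geometry)
  phi_x <- fem_solve(sys_x, strength * B)        # nodes x nsheet*nangle
  G <- fem_solve(sys_m, B)                       # A_m^{-1} m_s
  MG <- as.matrix(sys_m$M %*% G)
  structure(list(Q = t(MG * phi_x), mesh = mesh, geometry = geometry,
                 background = background, strength = strength),
            class = "sinogram_operator")
}

#' Apply a precomputed sinogram operator to a phantom
#'
#' @param op a \code{\link{sinogram_operator}}.
#' @param spec a \code{\link{phantom_spec}} on the same domain/background.
#' @return an \code{xclt_sinogram} (noise-free raw array).
#' @export
apply_sinogram_operator <- function(op, spec) {
  y <- yield_at(spec, op$mesh$nodes)
  p <- as.numeric(op$Q %*% y)
  raw <- t(matrix(p, nrow = op$geometry$n_sheets))
  sinogram(raw, op$geometry)
}

#' Add multiplicative Gaussian noise to a sinogram
#'
#' Each raw element x is replaced by \code{x * (1 + level * z)} with
#' standard-normal z, then clipped at 0.  Seeded and reproducible.
#'
#' @param sino an \code{xclt_sinogram}.
#' @param level relative noise sigma (default: geometry's
#'   \code{noise_level}).
#' @param seed integer seed (default: geometry's \code{noise_seed}).
#' @return the noisy sinogram (upscaled slot dropped).
#' @export
add_noise <- function(sino, level = NULL, seed = NULL) {
  if (is.null(level)) level <- sino$geometry$noise_level
  if (is.null(seed)) seed <- sino$geometry$noise_seed
  stopifnot(level >= 0)
  if (level == 0) return(sinogram(sino$raw, sino$geometry))
  raw <- with_seed(seed, {
    z <- matrix(stats::rnorm(length(sino$raw)), nrow = nrow(sino$raw))
    pmax(sino$raw * (1 + level * z), 0)
  })
  sinogram(raw, sino$geometry)
}

## corner-aligned bilinear resize of a matrix
bilinear_resize <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  ri <- if (nr == 1) rep(1, 1) else 1 + (seq_len(nr) - 1) * (sr - 1) / (nr - 1)
  ci <- if (nc == 1) rep(1, 1) else 1 + (seq_len(nc) - 1) * (sc - 1) / (nc - 1)
  r0 <- pmin(floor(ri), sr - 1); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), sc - 1); c1 <- c0 + 1; fc <- ci - c0
  if (sr == 1) { r0 <- r1 <- rep(1, nr); fr <- rep(0, nr) }
  if (sc == 1) { c0 <- c1 <- rep(1, nc); fc <- rep(0, nc) }
  a <- m[r0, c0, drop = FALSE] * (1 - fr) + m[r1, c0, drop = FALSE] * fr
  b <- m[r0, c1, drop = FALSE] * (1 - fr) + m[r1, c1, drop = FALSE] * fr
  a * rep(1 - fc, each = nr) + b * rep(fc, each = nr)
}

#' Upscale a sinogram to the network input size
#'
#' Normalizes the raw array by its maximum and resizes it to N x N with
#' corner-aligned bilinear interpolation (rows: angle axis, columns: sheet
#' axis).  Output values lie in [0, 1].
#'
#' @param sino an \code{xclt_sinogram}.
#' @param N output side (default 128).
#' @return the sinogram with its \code{upscaled} slot filled.
#' @export
upscale_sinogram <- function(sino, N = 128L) {
  N <- as.integer(N)
  mx <- max(sino$raw)
  norm <- if (mx > 0) sino$raw / mx else sino$raw
  up <- bilinear_resize(norm, N, N)
  sinogram(sino$raw, sino$geometry, upscaled = up)
}
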