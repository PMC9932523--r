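## Discrete Radon operator W (ray-driven, bilinear sampling at sub-pixel
## steps, stored as a sparse matrix) and filtered backprojection
## mu = W^T C P with a ramp-family frequency filter C.

#' Discrete Radon operator
#'
#' Builds the sparse forward-projection matrix W mapping an N x N image
#' (over the square \eqn{[-R, R]^2}, same pixel convention as
#' \code{\link{rasterize_yield}}) to line integrals at every
#' (angle, offset) pair.  Rays are sampled at \code{step} pixel intervals
#' with bilinear interpolation; the transpose of W is the exact adjoint used
#' for backprojection.
#'
#' @param grid_size image side N.
#' @param angles projection angles (degrees).
#' @param offsets signed ray offsets from center (mm).
#' @param domain_radius half-side of the image square (mm).
#' @param step quadrature step along rays, in pixels.
#' @return a \code{radon_operator}: list with sparse \code{W}
#'   (n_rays x N^2), the geometry vectors, and grid metadata.
#' @export
radon_operator <- function(grid_size, angles, offsets, domain_radius = 50,
                           step = 0.5) {
  N <- as.integer(grid_size)
  px <- 2 * domain_radius / N
  ds <- step * px
  half <- domain_radius * sqrt(2)
  npts <- ceiling(2 * half / ds)
  dt <- 2 * half / npts
  t <- -half + (seq_len(npts) - 0.5) * dt
  nray <- length(angles) * length(offsets)

  ang <- rep(angles, each = length(offsets))       # ray order: angle-major
  off <- rep(offsets, times = length(angles))
  th <- ang * pi / 180
  trips <- vector("list", length(t))
  for (q in seq_along(t)) {
    x <- off * cos(th) - t[q] * sin(th)
    y <- off * sin(th) + t[q] * cos(th)
    fi <- (domain_radius - y) / px + 0.5           # fractional row
    fj <- (x + domain_radius) / px + 0.5           # fractional col
    i0 <- floor(fi); j0 <- floor(fj)
    wi <- fi - i0; wj <- fj - j0
    ray <- seq_len(nray)
    ii <- c(i0, i0 + 1, i0, i0 + 1)
    jj <- c(j0, j0, j0 + 1, j0 + 1)
    ww <- c((1 - wi) * (1 - wj), wi * (1 - wj), (1 - wi) * wj, wi * wj) * dt
    rr <- rep(ray, 4)
    ok <- ii >= 1 & ii <= N & jj >= 1 & jj <= N & ww != 0
    trips[[q]] <- cbind(r = rr[ok], c = ii[ok] + (jj[ok] - 1) * N,
                        x = ww[ok])
  }
  trips <- do.call(rbind, trips)
  W <- Matrix::sparseMatrix(i = trips[, "r"], j = trips[, "c"],
                            x = trips[, "x"], dims = c(nray, N * N))
  structure(list(W = W, grid_size = N, angles = angles, offsets = offsets,
                 domain_radius = domain_radius, pixel_mm = px),
            class = "radon_operator")
}

#' @export
print.radon_operator <- function(x, ...) {
  cat(sprintf("Radon operator: %d angles x %d offsets -> %dx%d grid (%d nnz)\n",
              length(x$angles), length(x$offsets), x$grid_size, x$grid_size,
              length(x$W@x)))
  invisible(x)
}

#' Forward Radon projection of an image
#'
#' @param image N x N matrix on the operator grid.
#' @param op a \code{\link{radon_operator}}.
#' @return matrix of line integrals, \code{length(angles) x length(offsets)}.
#' @export
radon_transform <- function(image, op) {
  N <- op$grid_size
  if (!all(dim(image) == c(N, N))) stop("image does not match operator grid")
  p <- as.numeric(op$W %*% as.vector(image))
  matrix(p, nrow = length(op$angles), byrow = TRUE)
}

#' Ramp-family frequency filter for FBP
#'
#' @param kind \code{"ramp"} (Ram-Lak), \code{"shepp-logan"} or
#'   \code{"cosine"}.
#' @param cutoff cutoff as a fraction of the Nyquist frequency; response is
#'   zero beyond it.
#' @return an \code{fbp_filter} closure mapping frequencies (cycles/mm, with
#'   attribute-free sign) and the Nyquist frequency to gains.
#' @export
fbp_filter <- function(kind = c("ramp", "shepp-logan", "cosine"),
                       cutoff = 1.0) {
  kind <- match.arg(kind)
  stopifnot(cutoff > 0, cutoff <= 1)
  f <- function(freq, nyquist) {
    af <- abs(freq)
    g <- af
    if (kind == "shepp-logan") {
      z <- af / (2 * nyquist)
      g <- ifelse(af > 0, af * sin(pi * z) / pmax(pi * z, 1e-300), 0)
    } else if (kind == "cosine") {
      g <- af * cos(pi * af / (2 * nyquist))
    }
    g[af > cutoff * nyquist] <- 0
    g
  }
  structure(list(kind = kind, cutoff = cutoff, gain = f),
            class = "fbp_filter")
}

#' Filtered backprojection
#'
#' Implements \eqn{\hat\mu_\eta = W^T C P}: each angle's projection is
#' filtered in the frequency domain with a ramp-family filter, then
#' backprojected with the exact adjoint of the Radon operator and weighted
#' by \eqn{\Delta\theta = \pi / n_{angles}}.  The output is min-max
#' normalized to [0, 1].
#'
#' @param P projection array (\code{length(angles) x length(offsets)}), e.g.
#'   a raw sinogram.
#' @param op a \code{\link{radon_operator}} with matching geometry.
#' @param filter an \code{\link{fbp_filter}}.
#' @param normalize min-max normalize the output (default TRUE); with
#'   FALSE the raw filtered backprojection is returned (linear in P).
#' @return N x N reconstructed image (in [0, 1] when normalized).
#' @export
fbp_reconstruct <- function(P, op, filter = fbp_filter("ramp"),
                            normalize = TRUE) {
  na <- length(op$angles); ns <- length(op$offsets)
  if (!all(dim(P) == c(na, ns)))
    stop("projection array does not match operator geometry")
  if (na < 2) stop("filtered backprojection needs at least 2 angles")
  ds <- if (ns > 1) diff(op$offsets[1:2]) else op$pixel_mm
  npad <- 2^ceiling(log2(2 * ns))
  freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * ds)
  nyq <- 1 / (2 * ds)
  gain <- filter$gain(freq, nyq)
  q <- matrix(0, na, ns)
  for (a in seq_len(na)) {
    row <- c(P[a, ], rep(0, npad - ns))
    fr <- stats::fft(row) * gain
    q[a, ] <- Re(stats::fft(fr, inverse = TRUE) / npad)[seq_len(ns)]
  }
  dtheta <- pi / na
  img_vec <- as.numeric(Matrix::crossprod(op$W, as.vector(t(q)))) * dtheta
  img <- matrix(img_vec, op$grid_size, op$grid_size)
  if (normalize) {
    rng <- range(img)
    if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  }
  img
}
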