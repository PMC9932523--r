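test_that("radon projections conserve mass and vanish on zero images", {
  N <- 64L
  px <- 100 / N
  xs <- -50 + (seq_len(N) - 0.5) * px
  disk <- outer(rev(xs), xs, function(y, x) as.numeric(x^2 + y^2 < 20^2))
  op <- radon_operator(N, seq(0, 170, 10), (seq_len(N) - (N + 1) / 2) * px)
  pr <- radon_transform(disk, op)
  # Fubini: every angle integrates to the image mass, which in turn
  # approximates the analytic disk area up to pixelization
  mass <- sum(disk) * px^2
  expect_lt(rel_err(mass, pi * 400), 0.02)
  for (a in seq_len(nrow(pr)))
    expect_lt(rel_err(sum(pr[a, ]) * px, mass), 0.01)
  expect_true(all(radon_transform(matrix(0, N, N), op) == 0))
  # linearity
  img2 <- outer(rev(xs), xs, function(y, x) as.numeric((x - 10)^2 + y^2 < 64))
  lhs <- radon_transform(2 * disk + 3 * img2, op)
  expect_lt(max(abs(lhs - 2 * pr - 3 * radon_transform(img2, op))), 1e-9)
})

test_that("a single bright pixel traces its sinusoid", {
  N <- 64L
  px <- 100 / N
  img <- matrix(0, N, N)
  i <- 20L; j <- 44L
  img[i, j] <- 1
  x <- -50 + (j - 0.5) * px
  y <- 50 - (i - 0.5) * px
  angles <- seq(0, 170, 10)
  offsets <- (seq_len(N) - (N + 1) / 2) * px
  op <- radon_operator(N, angles, offsets)
  pr <- radon_transform(img, op)
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    expected <- x * cos(th) + y * sin(th)
    got <- offsets[which.max(pr[a, ])]
    expect_lte(abs(got - expected), px)
  }
})

test_that("the backprojector is the exact adjoint of the projector", {
  op <- radon_operator(32L, seq(0, 170, 10), seq(-49, 49, 2))
  set.seed(1)
  x <- rnorm(32 * 32)
  y <- rnorm(18 * 50)
  lhs <- sum(as.numeric(op$W %*% x) * y)
  rhs <- sum(x * as.numeric(Matrix::crossprod(op$W, y)))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("dense-view FBP self-reconstruction is accurate inside the disk", {
  N <- 128L
  px <- 100 / N
  xs <- -50 + (seq_len(N) - 0.5) * px
  disk <- outer(rev(xs), xs, function(y, x) as.numeric(x^2 + y^2 < 400))
  op <- radon_operator(N, seq(0, 179), (seq_len(N) - (N + 1) / 2) * px)
  rec <- fbp_reconstruct(radon_transform(disk, op), op)
  inside <- disk == 1
  expect_lt(sqrt(mean((rec[inside] - 1)^2)), 0.10)
  # zero projections give a zero image
  expect_true(all(fbp_reconstruct(matrix(0, 180, N), op) == 0))
})

test_that("FBP filters are ramp-like with zero DC response", {
  for (kind in c("ramp", "shepp-logan", "cosine")) {
    f <- fbp_filter(kind)
    expect_equal(f$gain(0, 0.5), 0)
    expect_gt(f$gain(0.1, 0.5), 0)
    expect_equal(f$gain(0.6, 0.5), 0)  # beyond Nyquist cutoff
  }
  fr <- fbp_filter("ramp")
  expect_equal(fr$gain(0.2, 0.5), 0.2)
})

# PSNR after fitting the reconstruction's free global scale: isolates
# operator fidelity from the min-max output normalization (whose Gibbs
# overshoot penalizes dense-view reconstructions)
psnr_scaled <- function(gt, rec) {
  cc <- sum(rec * gt) / sum(rec * rec)
  10 * log10(max(gt)^2 / mean((cc * rec - gt)^2))
}

test_that("more view angles improve FBP self-reconstruction on average", {
  N <- 48L
  px <- 100 / N
  offsets <- (seq_len(N) - (N + 1) / 2) * px
  angle_sets <- list(seq(0, 170, 30), seq(0, 170, 10), seq(0, 177, 3))
  ops <- lapply(angle_sets, function(a) radon_operator(N, a, offsets))
  psnr_by_k <- matrix(0, 20, length(ops))
  for (i in 1:20) {
    spec <- sample_phantom_spec(100L + i, sample(1:2, 1))
    img <- normalize_max(rasterize_yield(spec, N))
    for (k in seq_along(ops)) {
      rec <- fbp_reconstruct(radon_transform(img, ops[[k]]), ops[[k]],
                             normalize = FALSE)
      psnr_by_k[i, k] <- psnr_scaled(img, rec)
    }
  }
  means <- colMeans(psnr_by_k)
  expect_true(all(diff(means) > 0))
})

test_that("18-view FBP of diffuse sinograms is far below the dense-view case", {
  m <- coarse_mesh()
  spec <- phantom_spec(list(target_spec(c(12, -6), 7)), optical_properties())
  sino <- simulate_sinogram(spec, m)
  N <- 128L
  gt <- normalize_max(rasterize_yield(spec, N))
  geo <- sino$geometry
  op18 <- radon_operator(N, geo$angles, geo$offsets)
  psnr18 <- psnr_scaled(gt, fbp_reconstruct(sino$raw, op18,
                                            normalize = FALSE))
  # dense-view reconstruction of ideal (Radon) projections of the truth
  px <- 100 / N
  opd <- radon_operator(N, seq(0, 178, 2), (seq_len(N) - (N + 1) / 2) * px)
  recd <- fbp_reconstruct(radon_transform(gt, opd), opd, normalize = FALSE)
  psnrd <- psnr_scaled(gt, recd)
  expect_lt(psnr18, psnrd - 3)   # several dB below the ideal-data case
})

test_that("FBP is linear in the projections before normalization", {
  op <- radon_operator(32L, seq(0, 170, 10), seq(-49, 49, 2))
  set.seed(2)
  p1 <- matrix(runif(18 * 50), 18)
  p2 <- matrix(runif(18 * 50), 18)
  f <- fbp_filter("ramp")
  lhs <- fbp_reconstruct(2 * p1 + 3 * p2, op, f, normalize = FALSE)
  rhs <- 2 * fbp_reconstruct(p1, op, f, normalize = FALSE) +
         3 * fbp_reconstruct(p2, op, f, normalize = FALSE)
  expect_lt(max(abs(lhs - rhs)), 1e-10 * max(abs(lhs)))
  expect_error(fbp_reconstruct(p1[1, , drop = FALSE], op), "geometry")
})
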