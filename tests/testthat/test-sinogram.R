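test_that("default geometry produces an 18 x 50 sinogram with symmetry", {
  m <- coarse_mesh()
  spec <- phantom_spec(list(target_spec(c(0, 0), 8)), optical_properties())
  sino <- simulate_sinogram(spec, m)
  expect_equal(dim(sino$raw), c(18L, 50L))
  expect_true(all(sino$raw >= 0))
  mx <- max(sino$raw)
  # centered target: each angle's sheet profile symmetric about the center
  for (a in c(1, 7, 13))
    expect_lt(max(abs(sino$raw[a, ] - rev(sino$raw[a, ]))) / mx, 0.02)
  # and the profile is the same at every angle (rotational symmetry)
  rng <- apply(sino$raw, 2, function(col) max(col) - min(col))
  expect_lt(max(rng) / mx, 0.02)
})

test_that("precomputed operator reproduces the per-sheet simulation", {
  m <- coarse_mesh()
  geo <- scan_geometry(n_angles = 4L, angle_step = 45, n_sheets = 9L,
                       sheet_step = 10)
  spec <- sample_phantom_spec(3L, 2L)
  direct <- simulate_sinogram(spec, m, geo)
  op <- sinogram_operator(m, geo)
  fast <- apply_sinogram_operator(op, spec)
  expect_lt(max(abs(fast$raw - direct$raw)) / max(direct$raw), 1e-10)
})

test_that("cached factorization is bitwise-identical to factorizing per sheet", {
  m <- tiny_mesh()
  geo <- scan_geometry(n_angles = 2L, angle_step = 90, n_sheets = 3L,
                       sheet_step = 25)
  spec <- sample_phantom_spec(5L, 1L)
  reused <- simulate_sinogram(spec, m, geo, reuse_factorization = TRUE,
                              mode = "boundary_sum")
  scratch <- simulate_sinogram(spec, m, geo, reuse_factorization = FALSE,
                               mode = "boundary_sum")
  expect_identical(reused$raw, scratch$raw)
})

test_that("mirror-symmetric phantoms mirror the sinogram sheets", {
  m <- coarse_mesh()
  geo <- scan_geometry(n_angles = 1L, n_sheets = 50L)  # single 0-deg view
  bg <- optical_properties()
  left <- phantom_spec(list(target_spec(c(-15, 0), 6)), bg)
  right <- phantom_spec(list(target_spec(c(15, 0), 6)), bg)
  op <- sinogram_operator(m, geo)
  pl <- apply_sinogram_operator(op, left)$raw[1, ]
  pr <- apply_sinogram_operator(op, right)$raw[1, ]
  expect_lt(max(abs(pl - rev(pr))) / max(pl), 0.02)
})

test_that("rotating phantom and scan start together leaves the sinogram fixed", {
  m <- coarse_mesh()
  bg <- optical_properties()
  rot <- 30
  geo0 <- scan_geometry(n_angles = 6L, angle_step = 30, n_sheets = 25L,
                        sheet_step = 4)
  geo1 <- scan_geometry(n_angles = 6L, angle_start = rot, angle_step = 30,
                        n_sheets = 25L, sheet_step = 4)
  th <- rot * pi / 180
  ctr <- c(12, 5)
  ctr_rot <- c(cos(th) * ctr[1] - sin(th) * ctr[2],
               sin(th) * ctr[1] + cos(th) * ctr[2])
  p0 <- apply_sinogram_operator(
    sinogram_operator(m, geo0),
    phantom_spec(list(target_spec(ctr, 6)), bg))$raw
  p1 <- apply_sinogram_operator(
    sinogram_operator(m, geo1),
    phantom_spec(list(target_spec(ctr_rot, 6)), bg))$raw
  expect_lt(max(abs(p0 - p1)) / max(p0), 0.02)
})

test_that("multiplicative noise has the configured relative sigma", {
  geo <- scan_geometry(noise_level = 0.01)
  const <- sinogram_constant <- matrix(5, 10, 100)
  sino <- structure(list(raw = const, geometry = geo),
                    class = "xclt_sinogram")
  # level 0 is the identity
  expect_identical(add_noise(sino, 0, 1)$raw, const)
  # same seed, same result
  expect_identical(add_noise(sino, 0.01, 42)$raw, add_noise(sino, 0.01, 42)$raw)
  expect_false(identical(add_noise(sino, 0.01, 42)$raw,
                         add_noise(sino, 0.01, 43)$raw))
  # Monte-Carlo estimate of the relative sigma over 1000 repetitions
  devs <- vapply(1:1000, function(s)
    stats::sd(add_noise(sino, 0.01, s)$raw / 5), numeric(1))
  expect_gte(mean(devs), 0.009)
  expect_lte(mean(devs), 0.011)
})

test_that("upscaling normalizes and bilinearly resizes the sinogram", {
  m <- coarse_mesh()
  spec <- sample_phantom_spec(2L, 1L)
  sino <- simulate_sinogram(spec, m)
  up <- upscale_sinogram(sino, 128L)
  expect_equal(dim(up$upscaled), c(128L, 128L))
  expect_gte(min(up$upscaled), 0)
  expect_lte(max(up$upscaled), 1 + 1e-12)
  expect_gt(max(up$upscaled), 0.9)    # raw max mapped to ~1 before resampling

  # constant sinogram stays constant
  cs <- structure(list(raw = matrix(3, 18, 50), geometry = sino$geometry),
                  class = "xclt_sinogram")
  cu <- upscale_sinogram(cs, 64L)
  expect_true(all(abs(cu$upscaled - 1) < 1e-12))

  # round trip: downscaling the upscaled array recovers the normalized raw
  norm <- sino$raw / max(sino$raw)
  back <- xclt:::bilinear_resize(up$upscaled, 18L, 50L)
  rms <- sqrt(mean((back - norm)^2)) / sqrt(mean(norm^2))
  expect_lt(rms, 0.05)
})

test_that("fields and measurements stay non-negative within tolerance", {
  m <- coarse_mesh()
  spec <- sample_phantom_spec(8L, 2L)
  sino <- simulate_sinogram(spec, m)
  expect_gt(min(sino$raw), -1e-10)
  noisy <- add_noise(sino, 0.05, 9L)
  expect_gte(min(noisy$raw), 0)
})
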