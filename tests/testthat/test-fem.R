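op_bg <- optical_properties()

test_that("assembled system is symmetric positive definite", {
  m <- tiny_mesh()
  sys <- assemble_fem_system(m, op_bg$mu_ax, op_bg$Dx)
  A <- as.matrix(sys$A)
  expect_equal(max(abs(A - t(A))), 0)
  expect_lte(nrow(A), 200)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("assembly is affine in the absorption coefficient", {
  m <- tiny_mesh()
  s1 <- assemble_fem_system(m, 0.01, 0.3)
  s2 <- assemble_fem_system(m, 0.01 + 0.05, 0.3)
  diff <- s2$A - s1$A
  expect_lt(max(abs(diff - 0.05 * s1$M)), 1e-14)
})

test_that("sheet source integrates to strength times chord length", {
  m <- coarse_mesh()
  b <- sheet_source(m, sheet_spec(35, 0, strength = 2.5))
  expect_lt(rel_err(sum(b), 2.5 * 100), 0.02)
  # off-center chord
  b2 <- sheet_source(m, sheet_spec(0, 30))
  expect_lt(rel_err(sum(b2), 2 * sqrt(50^2 - 30^2)), 0.02)
  # sheet missing the domain: zero vector
  expect_true(all(sheet_source(m, sheet_spec(10, 60)) == 0))
  # rotating by the angular step leaves the total load unchanged
  b3 <- sheet_source(m, sheet_spec(10, 12))
  b4 <- sheet_source(m, sheet_spec(10 + 45, 12))  # 45 deg = mesh symmetry
  expect_lt(rel_err(sum(b4), sum(b3)), 1e-10)
})

test_that("excitation solve is linear with controlled residual", {
  m <- coarse_mesh()
  sys <- assemble_fem_system(m, op_bg$mu_ax, op_bg$Dx)
  expect_true(all(solve_excitation(sys, numeric(nrow(m$nodes)))$values == 0))
  b <- sheet_source(m, sheet_spec(0, 10))
  p1 <- solve_excitation(sys, b)$values
  p2 <- solve_excitation(sys, 2 * b)$values
  expect_lt(max(abs(p2 - 2 * p1)), 1e-12 * max(abs(p1)))
  expect_gt(min(p1), -1e-10)
})

test_that("excitation field follows the 2-D diffusion Green's function", {
  m <- build_mesh(50, 50 / 36)
  sys <- assemble_fem_system(m, op_bg$mu_ax, op_bg$Dx)
  b <- numeric(nrow(m$nodes)); b[1] <- 1     # unit point source at center
  phi <- solve_excitation(sys, b)$values
  r <- sqrt(rowSums(m$nodes^2))
  sel <- r >= 10 & r <= 25
  mu_eff <- sqrt(op_bg$mu_ax / op_bg$Dx)
  green <- besselK(mu_eff * r[sel], 0) / (2 * pi * op_bg$Dx)
  expect_lt(max(abs(phi[sel] / green - 1)), 0.10)
})

test_that("emission solve is linear in the yield field", {
  m <- coarse_mesh()
  sys_x <- assemble_fem_system(m, op_bg$mu_ax, op_bg$Dx)
  sys_m <- assemble_fem_system(m, op_bg$mu_am, op_bg$Dm)
  phi_x <- solve_excitation(sys_x, sheet_source(m, sheet_spec(0, 0)))
  y0 <- rep(op_bg$yield, nrow(m$nodes))
  expect_true(all(solve_emission(sys_m, phi_x, 0 * y0)$values == 0))
  e1 <- solve_emission(sys_m, phi_x, y0)$values
  e4 <- solve_emission(sys_m, phi_x, 4 * y0)$values
  expect_lt(max(abs(e4 - 4 * e1)), 1e-10 * max(e1))
})

test_that("a target near the sheet emits more than the same target far away", {
  m <- coarse_mesh()
  bg <- op_bg
  sys_x <- assemble_fem_system(m, bg$mu_ax, bg$Dx)
  sys_m <- assemble_fem_system(m, bg$mu_am, bg$Dm)
  sheet <- sheet_spec(90, 20)   # vertical-offset sheet at y = ... (normal 90 deg)
  phi_x <- solve_excitation(sys_x, sheet_source(m, sheet))
  near <- phantom_spec(list(target_spec(c(0, 20), 6)), bg)
  far <- phantom_spec(list(target_spec(c(0, -20), 6)), bg)
  int_near <- sum(solve_emission(sys_m, phi_x, yield_at(near, m$nodes))$values)
  int_far <- sum(solve_emission(sys_m, phi_x, yield_at(far, m$nodes))$values)
  expect_gt(int_near, int_far)
})

test_that("sheet measurement integrates the interpolated field", {
  m <- coarse_mesh()
  const <- rep(3.7, nrow(m$nodes))
  sheet <- sheet_spec(25, 0)
  expect_lt(rel_err(sheet_measurement(const, sheet, m), 3.7 * 100), 0.02)
  expect_equal(sheet_measurement(const, sheet_spec(0, 70), m), 0)
  # quadrature refinement changes the value by < 0.5%
  sys_x <- assemble_fem_system(m, op_bg$mu_ax, op_bg$Dx)
  sys_m <- assemble_fem_system(m, op_bg$mu_am, op_bg$Dm)
  phi_x <- solve_excitation(sys_x, sheet_source(m, sheet))
  spec <- phantom_spec(list(target_spec(c(5, 5), 7)), op_bg)
  phi_m <- solve_emission(sys_m, phi_x, yield_at(spec, m$nodes))
  v1 <- sheet_measurement(phi_m, sheet, m, step = 0.5)
  v2 <- sheet_measurement(phi_m, sheet, m, step = 0.25)
  expect_lt(rel_err(v1, v2), 0.005)
  # boundary_sum mode sums the escaping fluence over boundary nodes
  expect_equal(sheet_measurement(phi_m, sheet, m, mode = "boundary_sum"),
               sum(phi_m$values[m$boundary_nodes]))
})
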