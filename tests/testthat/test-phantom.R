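test_that("sampled phantoms are valid, in range and deterministic", {
  cfg <- phantom_config()
  s1 <- sample_phantom_spec(0L, 1L, cfg)
  expect_length(s1$targets, 1)
  tg <- s1$targets[[1]]
  expect_gte(tg$radius, 4); expect_lte(tg$radius, 8)
  expect_lte(sqrt(sum(tg$center^2)) + tg$radius, 50 - cfg$margin + 1e-12)

  s2 <- sample_phantom_spec(0L, 1L, cfg)
  expect_identical(s1, s2)
  s3 <- sample_phantom_spec(1L, 1L, cfg)
  expect_false(identical(s1$targets, s3$targets))
})

test_that("two-target sampling never produces overlapping disks", {
  # brute-force pairwise audit over many sampled specs
  min_gap <- Inf
  for (seed in 1:2000) {
    sp <- sample_phantom_spec(seed, 2L)
    d <- sqrt(sum((sp$targets[[1]]$center - sp$targets[[2]]$center)^2))
    gap <- d - sp$targets[[1]]$radius - sp$targets[[2]]$radius
    min_gap <- min(min_gap, gap)
    expect_gte(gap, -1e-12)
  }
  expect_true(is.finite(min_gap))
})

test_that("three-target sampling stays inside the domain", {
  for (seed in 1:50) {
    sp <- sample_phantom_spec(seed, 3L)
    for (tg in sp$targets)
      expect_lte(sqrt(sum(tg$center^2)) + tg$radius, 48 + 1e-12)
  }
})

test_that("rejection sampling failure is reported for impossible configs", {
  cfg <- phantom_config(radius_range = c(30, 30), max_attempts = 20)
  expect_error(sample_phantom_spec(1L, 3L, cfg), "crowded")
})

test_that("resolution specs have the prescribed edge-to-edge separation", {
  for (sep in c(2, 4, 6, 8)) {
    sp <- sample_resolution_spec(11L, sep)
    d <- sqrt(sum((sp$targets[[1]]$center - sp$targets[[2]]$center)^2))
    expect_equal(d - sp$targets[[1]]$radius - sp$targets[[2]]$radius, sep,
                 tolerance = 1e-10)
  }
})

test_that("rasterized yield matches disk geometry and analytic mass", {
  bg <- optical_properties()
  spec <- phantom_spec(list(target_spec(c(10, -8), 8)), bg, 50, 1L)
  img <- rasterize_yield(spec, 128L)
  px <- 100 / 128
  target_level <- 4 * bg$yield
  n_target <- sum(abs(img - target_level) < 1e-12)
  expect_lt(rel_err(n_target, pi * 64 / px^2), 0.05)

  # raster mass vs analytic integral of the yield field
  mass <- sum(img) * px^2
  analytic <- bg$yield * (pi * 50^2 + 3 * pi * 64)   # background + contrast excess
  expect_lt(rel_err(mass, analytic), 0.02)

  # no targets: constant inside the disk, zero outside
  flat <- rasterize_yield(phantom_spec(list(), bg, 50, 1L), 64L)
  inside <- flat != 0
  expect_true(all(abs(flat[inside] - bg$yield) < 1e-15))
  xs <- -50 + (seq_len(64) - 0.5) * (100 / 64)
  outside_disk <- outer(rev(xs), xs, function(y, x) x^2 + y^2 > 2500)
  expect_true(all(flat[outside_disk] == 0))
})

test_that("two disjoint targets rasterize as two 4-connected components", {
  bg <- optical_properties()
  spec <- phantom_spec(list(target_spec(c(-15, 0), 6),
                            target_spec(c(15, 10), 5)), bg, 50, 1L)
  img <- rasterize_yield(spec, 128L)
  expect_equal(count_components(img > bg$yield + 1e-12), 2L)
})

test_that("phantom specs survive a JSON round trip", {
  sp <- sample_phantom_spec(7L, 2L)
  sp2 <- phantom_from_json(phantom_to_json(sp))
  expect_equal(sp2$targets, sp$targets, tolerance = 1e-12)
  expect_equal(sp2$background$mu_af, sp$background$mu_af)
  expect_equal(sp2$domain_radius, sp$domain_radius)
})

test_that("invalid optical properties and phantom geometry are rejected", {
  expect_error(optical_properties(mu_ax = -1), "positive")
  expect_error(optical_properties(eta = 1.5), "eta")
  bg <- optical_properties()
  expect_error(phantom_spec(list(target_spec(c(48, 0), 8)), bg), "outside")
  expect_error(phantom_spec(list(target_spec(c(0, 0), 6),
                                 target_spec(c(5, 0), 6)), bg), "overlap")
})
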