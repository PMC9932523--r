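# helper: zero every parameter of a set of layers
zero_layers <- function(layers) {
  for (ly in layers)
    for (j in seq_along(ly$params)) ly$params[[j]][] <- 0
}

test_that("patch embedding produces the printed token count and width", {
  for (cfg in list(network_config_small(32L), network_config_small(64L))) {
    m <- build_model("swin_cnn", cfg, seed = 1)
    N <- cfg$N
    x <- array(runif(N * N), c(1L, N, N, 1L))
    e <- m$arch$emb$s2d$fwd(m$arch$emb$conv$fwd(x))
    dim(e) <- c(1L, (N / cfg$n)^2, cfg$n^2 * 3L)
    toks <- m$arch$emb$ln$fwd(m$arch$emb$lin$fwd(e))
    expect_equal(dim(toks), c(1L, as.integer((N / cfg$n)^2), cfg$C))
  }
  # (128/4)^2 = 1024 tokens of dimension C at full scale: N^2 C / 16 values
  cfg <- network_config()
  expect_equal((cfg$N / cfg$n)^2, 1024)
})

test_that("encoder stages follow the token/channel ladder for any valid config", {
  for (cfg in list(network_config_small(32L),
                   network_config(N = 64L, C = 8L, depths = c(1, 2, 1, 1),
                                  heads = c(2, 2, 4, 8), window = 4L))) {
    m <- build_model("swin_cnn", cfg, seed = 2)
    N <- cfg$N
    G1 <- N %/% cfg$n
    x <- array(runif(2 * N * N), c(2L, N, N, 1L))
    e <- m$arch$emb$s2d$fwd(m$arch$emb$conv$fwd(x))
    dim(e) <- c(2L, G1^2, cfg$n^2 * 3L)
    t <- m$arch$emb$ln$fwd(m$arch$emb$lin$fwd(e))
    for (s in 1:4) {
      if (s > 1) t <- xclt:::patch_merge_fwd(m$arch$merges[[s]], t)
      for (blk in m$arch$stages[[s]]) t <- xclt:::swin_block_fwd(blk, t)
      G <- G1 %/% 2^(s - 1)
      expect_equal(dim(t), c(2L, as.integer(G^2), as.integer(cfg$C * 2^(s - 1))),
                   info = sprintf("stage %d", s))
    }
  }
})

test_that("shifted-window blocks preserve shape and differ from unshifted", {
  C <- 8L; G <- 8L; heads <- 2L
  set.seed(7)
  x <- array(rnorm(2 * G * G * C), c(2L, G * G, C))
  blk_s <- xclt:::with_seed(1, xclt:::swin_block(C, heads, G, 4L, shift = 2L))
  blk_u <- xclt:::with_seed(1, xclt:::swin_block(C, heads, G, 4L, shift = 0L))
  ys <- xclt:::swin_block_fwd(blk_s, x)
  yu <- xclt:::swin_block_fwd(blk_u, x)
  expect_equal(dim(ys), dim(x))
  expect_false(isTRUE(all.equal(ys, yu)))  # shifted tiling mixes windows
  expect_equal(blk_s$attn$shift, 2L)
})

test_that("zeroed attention and MLP reduce a stage to its merging path", {
  cfg <- network_config_small(32L)
  m <- build_model("swin_cnn", cfg, seed = 3)
  set.seed(8)
  t1 <- array(rnorm(2 * 64 * cfg$C), c(2L, 64L, cfg$C))  # stage-1 tokens
  blocks <- m$arch$stages[[2]]
  pm <- m$arch$merges[[2]]
  for (blk in blocks)
    zero_layers(list(blk$attn, blk$fc1, blk$fc2, blk$ln1, blk$ln2))
  # with weights zero, ln/attn/mlp outputs are zero, residuals pass through
  t2 <- xclt:::patch_merge_fwd(pm, t1)
  out <- t2
  for (blk in blocks) out <- xclt:::swin_block_fwd(blk, out)
  expect_equal(out, t2)
})

test_that("the locality module is an exact identity when its path is zeroed", {
  cfg <- network_config_small(32L)
  m <- build_model("swin_cnn", cfg, seed = 4)
  lc <- m$arch$locs[[1]]
  zero_layers(xclt:::loc_layers(lc))
  set.seed(9)
  x <- array(rnorm(2 * 8 * 8 * cfg$C), c(2L, 8L, 8L, cfg$C))
  expect_identical(xclt:::loc_fwd(lc, x), x)
  # same for the no-CNN (ablation) variant
  m2 <- build_model("swin_without_cnn", cfg, seed = 4)
  lc2 <- m2$arch$locs[[1]]
  zero_layers(xclt:::loc_layers(lc2))
  expect_identical(xclt:::loc_fwd(lc2, x), x)
})

test_that("gradients flow through both the residual and the inner path", {
  cfg <- network_config_small(32L)
  m <- build_model("swin_cnn", cfg, seed = 5)
  lc <- m$arch$locs[[1]]
  set.seed(10)
  x <- array(rnorm(8 * 8 * cfg$C), c(1L, 8L, 8L, cfg$C))
  y <- xclt:::loc_fwd(lc, x)
  xclt:::zero_grads(xclt:::loc_layers(lc))
  dy <- array(1, dim(y))
  dx <- xclt:::loc_bwd(lc, dy)
  # inner-path parameters receive gradient
  expect_gt(sum(abs(lc$fc1$grads$W)), 0)
  expect_gt(sum(abs(lc$conv1$grads$W)), 0)
  # residual path contributes identity: dx includes dy plus inner-path term
  expect_false(isTRUE(all.equal(dx, dy)))        # inner path active
  lc0 <- m$arch$locs[[2]]
  zero_layers(xclt:::loc_layers(lc0))
  x2 <- array(rnorm(4 * 4 * 2 * cfg$C), c(1L, 4L, 4L, 2L * cfg$C))
  y2 <- xclt:::loc_fwd(lc0, x2)
  dx2 <- xclt:::loc_bwd(lc0, array(1, dim(y2)))
  expect_equal(dx2, array(1, dim(y2)))           # zeroed inner path: pure identity
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- network_config_small(32L)
  m <- build_model("swin_cnn", cfg, seed = 6)
  set.seed(11)
  x <- array(runif(32 * 32), c(1L, 32L, 32L, 1L))
  target <- array(runif(32 * 32), c(1L, 32L, 32L, 1L))
  lossf <- function() mean((m$fwd(m$arch, x) - target)^2)
  xclt:::zero_grads(m$layers)
  y <- m$fwd(m$arch, x)
  m$bwd(m$arch, 2 * (y - target) / length(y))
  set.seed(12)
  for (li in sample(seq_along(m$layers), 6)) {
    ly <- m$layers[[li]]
    pn <- sample(seq_along(ly$params), 1)
    k <- sample(length(ly$params[[pn]]), 1)
    eps <- 1e-5
    v0 <- ly$params[[pn]][k]
    ly$params[[pn]][k] <- v0 + eps; lp <- lossf()
    ly$params[[pn]][k] <- v0 - eps; lm <- lossf()
    ly$params[[pn]][k] <- v0
    fd <- (lp - lm) / (2 * eps)
    an <- ly$grads[[pn]][k]
    expect_lt(abs(fd - an) / max(1e-7, abs(fd) + abs(an)), 1e-3,
              label = sprintf("layer %d (%s)", li, ly$kind))
  }
})

test_that("model builds are seed-deterministic and kinds are validated", {
  cfg <- network_config_small(32L)
  m1 <- build_model("automap", cfg, seed = 7)
  m2 <- build_model("automap", cfg, seed = 7)
  x <- array(runif(32 * 32), c(1L, 32L, 32L, 1L))
  expect_identical(m1$fwd(m1$arch, x), m2$fwd(m2$arch, x))
  m3 <- build_model("automap", cfg, seed = 8)
  expect_false(identical(m1$fwd(m1$arch, x), m3$fwd(m3$arch, x)))
  expect_error(build_model("resnet", cfg), "arg")
})

test_that("parameter counts scale as designed", {
  cfg <- network_config_small(32L)
  # meta-mode count equals the count of an actually built model
  built <- build_model("swin_cnn", cfg, seed = 1)
  expect_equal(count_params("swin_cnn", cfg), count_params(built))
  # AUTOMAP at N=128 is dominated by its ~3 N^4 fully-connected weights
  cfg128 <- network_config()
  am <- count_params("automap", cfg128)
  expect_lt(abs(am - 3 * 128^4) / (3 * 128^4), 0.01)
  # the windowed-attention model needs far fewer parameters
  expect_lt(count_params("swin_cnn", cfg128), am)
  # variants strictly order by capacity of the skip path
  expect_gt(count_params("swin_cnn", cfg),
            count_params("swin_without_cnn", cfg))
  expect_gt(count_params("swin_without_cnn", cfg),
            count_params("swin_without_locality", cfg))
})

test_that("reconstruct is deterministic, clipped and shape-preserving", {
  cfg <- network_config_small(32L)
  m <- build_model("swin_cnn", cfg, seed = 9)
  set.seed(13)
  P <- matrix(runif(32 * 32), 32)
  r1 <- reconstruct(m, P)
  r2 <- reconstruct(m, P)
  expect_identical(r1, r2)
  expect_equal(dim(r1), c(32L, 32L))
  expect_gte(min(r1), 0); expect_lte(max(r1), 1)
  batch <- reconstruct(m, array(runif(3 * 32 * 32), c(3, 32, 32)))
  expect_equal(dim(batch), c(3L, 32L, 32L))
  expect_error(reconstruct(m, matrix(0, 16, 16)), "16")
})

test_that("all five model kinds map N x N x 1 to N x N x 1", {
  cfg <- network_config_small(32L)
  x <- array(runif(2 * 32 * 32), c(2L, 32L, 32L, 1L))
  for (kind in c("swin_cnn", "swin_without_locality", "swin_without_cnn",
                 "automap", "mfcnn")) {
    m <- build_model(kind, cfg, seed = 1)
    y <- m$fwd(m$arch, x)
    expect_equal(dim(y), c(2L, 32L, 32L, 1L), info = kind)
  }
})
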