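## Reconstruction networks mapping an N x N sinogram to an N x N yield
## image: the Swin-CNN (shifted-window transformer encoder, convolutional
## decoder, locality-module skips), its two ablation variants, and the
## AUTOMAP / MFCNN fully-connected baselines.

#' Network configuration
#'
#' @param N input/output image side; divisible by \code{n} and by 32.
#' @param n patch side for the embedding (default 4).
#' @param C embedding channels; stages use C, 2C, 4C, 8C.
#' @param depths Swin blocks per stage (length 4).
#' @param heads attention heads per stage (length 4); each must divide the
#'   stage's channel count.
#' @param window attention window side; must tile the stage-1 token grid
#'   (deeper stages clamp the window to the grid).
#' @param mlp_ratio hidden expansion of the transformer MLP.
#' @param locality_hidden width of the locality-module MNN; \code{NULL}
#'   (default) uses a quarter of the flattened feature size, capped at
#'   \code{locality_hidden_max}.
#' @param locality_hidden_max cap on the auto-sized MNN width.
#' @return a \code{network_config} list.
#' @export
network_config <- function(N = 128L, n = 4L, C = 96L,
                           depths = c(2L, 2L, 6L, 2L),
                           heads = c(3L, 6L, 12L, 24L),
                           window = 8L, mlp_ratio = 4,
                           locality_hidden = NULL,
                           locality_hidden_max = 1024L) {
  N <- as.integer(N); n <- as.integer(n); C <- as.integer(C)
  stopifnot(length(depths) == 4, length(heads) == 4, n %in% c(2L, 4L),
            N %% n == 0, N %% 32 == 0, (N %/% n) %% window == 0,
            all(c(C, 2 * C, 4 * C, 8 * C) %% heads == 0))
  structure(list(N = N, n = n, C = C, depths = as.integer(depths),
                 heads = as.integer(heads), window = as.integer(window),
                 mlp_ratio = mlp_ratio, locality_hidden = locality_hidden,
                 locality_hidden_max = as.integer(locality_hidden_max)),
            class = "network_config")
}

#' Scaled-down configuration for CPU-sized experiments
#'
#' @param N image side (default 32).
#' @return a \code{\link{network_config}} with C = 16, one block per stage.
#' @export
network_config_small <- function(N = 32L) {
  network_config(N = N, n = 4L, C = 16L, depths = c(1L, 1L, 1L, 1L),
                 heads = c(2L, 2L, 4L, 4L), window = 4L, mlp_ratio = 2,
                 locality_hidden_max = 512L)
}

stage_dims <- function(config) {
  G1 <- config$N %/% config$n
  list(G = c(G1, G1 %/% 2, G1 %/% 4, G1 %/% 8),
       C = config$C * c(1L, 2L, 4L, 8L))
}

loc_hidden_width <- function(config, flat) {
  if (!is.null(config$locality_hidden)) return(as.integer(config$locality_hidden))
  max(8L, min(as.integer(round(flat / 2)), config$locality_hidden_max))
}

## ---- locality module -------------------------------------------------------
## CNN -> flatten -> two-layer MNN -> reshape -> CNN, plus identity residual.
## variant "no_cnn" drops the two convolutions, keeping the MNN.

loc_make <- function(C, G, config, variant = c("full", "no_cnn")) {
  variant <- match.arg(variant)
  flat <- G * G * C
  hid <- loc_hidden_width(config, flat)
  lc <- list(variant = variant, C = C, G = G, flat = flat,
             fc1 = nn_linear(flat, hid), actm = nn_act("relu"),
             fc2 = nn_linear(hid, flat))
  if (variant == "full") {
    lc$conv1 <- nn_conv2d(C, C, 3)
    lc$act1 <- nn_act("relu")
    lc$conv2 <- nn_conv2d(C, C, 3)
  }
  lc
}

loc_layers <- function(lc) {
  ls <- list(lc$fc1, lc$fc2)
  if (lc$variant == "full") ls <- c(ls, list(lc$conv1, lc$conv2))
  ls
}

loc_fwd <- function(lc, x) {
  B <- dim(x)[1]
  h <- x
  if (lc$variant == "full") h <- lc$act1$fwd(lc$conv1$fwd(h))
  dim(h) <- c(B, lc$flat)
  f <- lc$fc2$fwd(lc$actm$fwd(lc$fc1$fwd(h)))
  dim(f) <- dim(x)
  if (lc$variant == "full") f <- lc$conv2$fwd(f)
  x + f
}

loc_bwd <- function(lc, dy) {
  B <- dim(dy)[1]
  d <- dy
  if (lc$variant == "full") d <- lc$conv2$bwd(d)
  dim(d) <- c(B, lc$flat)
  d <- lc$fc1$bwd(lc$actm$bwd(lc$fc2$bwd(d)))
  dim(d) <- dim(dy)
  if (lc$variant == "full") d <- lc$conv1$bwd(lc$act1$bwd(d))
  dy + d
}

## channel concatenation helpers
cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1:3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}
split_ch <- function(d, c1) {
  list(d[, , , seq_len(c1), drop = FALSE],
       d[, , , -seq_len(c1), drop = FALSE])
}

## ---- model builders --------------------------------------------------------

build_swin <- function(config, skip = c("locality", "no_cnn", "concat")) {
  skip <- match.arg(skip)
  sd <- stage_dims(config)
  n <- config$n
  emb <- list(conv = nn_conv2d(1L, 3L, 1), s2d = nn_space2depth(n),
              lin = nn_linear(n * n * 3L, config$C),
              ln = nn_layernorm(config$C))
  stages <- vector("list", 4)
  merges <- vector("list", 4)
  for (s in 1:4) {
    if (s > 1) merges[[s]] <- patch_merge(sd$C[s - 1], sd$G[s - 1])
    blocks <- vector("list", config$depths[s])
    for (d in seq_len(config$depths[s])) {
      w <- min(config$window, sd$G[s])
      shift <- if (d %% 2 == 0) w %/% 2 else 0L
      blocks[[d]] <- swin_block(sd$C[s], config$heads[s], sd$G[s],
                                config$window, shift, config$mlp_ratio)
    }
    stages[[s]] <- blocks
  }
  locs <- NULL
  if (skip != "concat")
    locs <- lapply(1:4, function(s)
      loc_make(sd$C[s], sd$G[s], config,
               if (skip == "locality") "full" else "no_cnn"))
  # decoder: up from N/32; concat skip; 3x3 conv; final 2x transposed conv
  dec <- list(
    up4 = nn_upsample2x(), conv4 = nn_conv2d(sd$C[4] + sd$C[3], sd$C[3], 3),
    act4 = nn_act("relu"),
    up3 = nn_upsample2x(), conv3 = nn_conv2d(sd$C[3] + sd$C[2], sd$C[2], 3),
    act3 = nn_act("relu"),
    up2 = nn_upsample2x(), conv2 = nn_conv2d(sd$C[2] + sd$C[1], sd$C[1], 3),
    act2 = nn_act("relu"),
    out = nn_convtranspose2x(sd$C[1], 1L))
  # the skip ladder ends at the stage-1 grid N/n; one extra upsample+conv
  # level is needed for n = 4 so the final stride-2 transpose lands on N
  if (n == 4L) {
    dec$up1 <- nn_upsample2x()
    dec$conv1 <- nn_conv2d(sd$C[1], sd$C[1], 3)
    dec$act1 <- nn_act("relu")
  }
  list(emb = emb, stages = stages, merges = merges, locs = locs, dec = dec,
       sd = sd, skip = skip, n = n)
}

swin_layers <- function(arch) {
  ls <- list(arch$emb$conv, arch$emb$lin, arch$emb$ln)
  for (s in 1:4) {
    if (s > 1) ls <- c(ls, list(arch$merges[[s]]$ln, arch$merges[[s]]$red))
    for (blk in arch$stages[[s]])
      ls <- c(ls, list(blk$ln1, blk$attn, blk$ln2, blk$fc1, blk$fc2))
  }
  if (!is.null(arch$locs))
    for (lc in arch$locs) ls <- c(ls, loc_layers(lc))
  ls <- c(ls, list(arch$dec$conv4, arch$dec$conv3, arch$dec$conv2),
          if (!is.null(arch$dec$conv1)) list(arch$dec$conv1),
          list(arch$dec$out))
  ls
}

swin_fwd <- function(arch, x) {
  B <- dim(x)[1]
  sd <- arch$sd
  e <- arch$emb$s2d$fwd(arch$emb$conv$fwd(x))
  dim(e) <- c(B, sd$G[1]^2, dim(e)[4])
  t <- arch$emb$ln$fwd(arch$emb$lin$fwd(e))
  toks <- vector("list", 4)
  for (s in 1:4) {
    if (s > 1) t <- patch_merge_fwd(arch$merges[[s]], t)
    for (blk in arch$stages[[s]]) t <- swin_block_fwd(blk, t)
    toks[[s]] <- t
  }
  maps <- lapply(1:4, function(s) {
    m <- toks[[s]]
    dim(m) <- c(B, sd$G[s], sd$G[s], sd$C[s])
    m
  })
  skips <- if (is.null(arch$locs)) maps else
    lapply(1:4, function(s) loc_fwd(arch$locs[[s]], maps[[s]]))
  d <- arch$dec
  h4 <- d$act4$fwd(d$conv4$fwd(cat_ch(d$up4$fwd(skips[[4]]), skips[[3]])))
  h3 <- d$act3$fwd(d$conv3$fwd(cat_ch(d$up3$fwd(h4), skips[[2]])))
  h2 <- d$act2$fwd(d$conv2$fwd(cat_ch(d$up2$fwd(h3), skips[[1]])))
  h1 <- if (is.null(d$up1)) h2 else d$act1$fwd(d$conv1$fwd(d$up1$fwd(h2)))
  d$out$fwd(h1)
}

swin_bwd <- function(arch, dy) {
  sd <- arch$sd
  d <- arch$dec
  dh1 <- d$out$bwd(dy)
  if (!is.null(d$up1)) dh1 <- d$up1$bwd(d$conv1$bwd(d$act1$bwd(dh1)))
  sp <- split_ch(d$conv2$bwd(d$act2$bwd(dh1)), sd$C[2])
  dh2 <- d$up2$bwd(sp[[1]]); dskip1 <- sp[[2]]
  sp <- split_ch(d$conv3$bwd(d$act3$bwd(dh2)), sd$C[3])
  dh3 <- d$up3$bwd(sp[[1]]); dskip2 <- sp[[2]]
  sp <- split_ch(d$conv4$bwd(d$act4$bwd(dh3)), sd$C[4])
  dskip4 <- d$up4$bwd(sp[[1]]); dskip3 <- sp[[2]]
  dskips <- list(dskip1, dskip2, dskip3, dskip4)
  dmaps <- if (is.null(arch$locs)) dskips else
    lapply(1:4, function(s) loc_bwd(arch$locs[[s]], dskips[[s]]))
  B <- dim(dy)[1]
  dt <- NULL
  for (s in 4:1) {
    dm <- dmaps[[s]]
    dim(dm) <- c(B, sd$G[s]^2, sd$C[s])
    dt <- if (is.null(dt)) dm else dt + dm
    for (blk in rev(arch$stages[[s]])) dt <- swin_block_bwd(blk, dt)
    if (s > 1) dt <- patch_merge_bwd(arch$merges[[s]], dt)
  }
  de <- arch$emb$lin$bwd(arch$emb$ln$bwd(dt))
  dim(de) <- c(B, sd$G[1], sd$G[1], arch$n * arch$n * 3L)
  arch$emb$conv$bwd(arch$emb$s2d$bwd(de))
}

## ---- AUTOMAP / MFCNN baselines --------------------------------------------

build_automap <- function(config) {
  N <- config$N
  list(fc1 = nn_linear(N^2, N^2), a1 = nn_act("tanh"),
       fc2 = nn_linear(N^2, N^2), a2 = nn_act("tanh"),
       fc3 = nn_linear(N^2, N^2),
       conv1 = nn_conv2d(1L, 16L, 3), c1 = nn_act("relu"),
       conv2 = nn_conv2d(16L, 16L, 3), c2 = nn_act("relu"),
       out = nn_conv2d(16L, 1L, 3), N = N)
}

automap_layers <- function(arch)
  list(arch$fc1, arch$fc2, arch$fc3, arch$conv1, arch$conv2, arch$out)

automap_fwd <- function(arch, x) {
  B <- dim(x)[1]; N <- arch$N
  v <- x; dim(v) <- c(B, N * N)
  v <- arch$fc3$fwd(arch$a2$fwd(arch$fc2$fwd(arch$a1$fwd(arch$fc1$fwd(v)))))
  dim(v) <- c(B, N, N, 1L)
  arch$out$fwd(arch$c2$fwd(arch$conv2$fwd(
    arch$c1$fwd(arch$conv1$fwd(v)))))
}

automap_bwd <- function(arch, dy) {
  B <- dim(dy)[1]; N <- arch$N
  d <- arch$conv1$bwd(arch$c1$bwd(arch$conv2$bwd(arch$c2$bwd(
    arch$out$bwd(dy)))))
  dim(d) <- c(B, N * N)
  d <- arch$fc1$bwd(arch$a1$bwd(arch$fc2$bwd(arch$a2$bwd(arch$fc3$bwd(d)))))
  dim(d) <- c(B, N, N, 1L)
  d
}

build_mfcnn <- function(config, hidden = NULL) {
  N <- config$N
  if (is.null(hidden)) hidden <- 2L * N^2
  list(fc1 = nn_linear(N^2, hidden), a1 = nn_act("relu"),
       fc2 = nn_linear(hidden, hidden), a2 = nn_act("relu"),
       fc3 = nn_linear(hidden, N^2), N = N, hidden = hidden)
}

mfcnn_layers <- function(arch) list(arch$fc1, arch$fc2, arch$fc3)

mfcnn_fwd <- function(arch, x) {
  B <- dim(x)[1]; N <- arch$N
  v <- x; dim(v) <- c(B, N * N)
  v <- arch$fc3$fwd(arch$a2$fwd(arch$fc2$fwd(arch$a1$fwd(arch$fc1$fwd(v)))))
  dim(v) <- c(B, N, N, 1L)
  v
}

mfcnn_bwd <- function(arch, dy) {
  B <- dim(dy)[1]; N <- arch$N
  d <- dy; dim(d) <- c(B, N * N)
  d <- arch$fc1$bwd(arch$a1$bwd(arch$fc2$bwd(arch$a2$bwd(arch$fc3$bwd(d)))))
  dim(d) <- c(B, N, N, 1L)
  d
}

## ---- public builder --------------------------------------------------------

#' Build a reconstruction model
#'
#' Kinds: \code{swin_cnn} (full model), \code{swin_without_locality}
#' (plain concatenation skips), \code{swin_without_cnn} (locality modules
#' keep the MNN but drop both convolution layers), \code{automap}
#' (fully-connected stack + convolutional refinement) and \code{mfcnn}
#' (multilayer fully-connected baseline).
#'
#' @param kind model kind (see above).
#' @param config a \code{\link{network_config}}.
#' @param seed integer seed for weight initialization (same seed, same
#'   weights).
#' @return a \code{recon_model}: list with \code{kind}, \code{config}, the
#'   architecture, the flat layer list, and \code{fwd}/\code{bwd} closures.
#' @export
build_model <- function(kind = c("swin_cnn", "swin_without_locality",
                                 "swin_without_cnn", "automap", "mfcnn"),
                        config = network_config(), seed = 1L) {
  kind <- match.arg(kind)
  build <- function() {
    if (kind %in% c("swin_cnn", "swin_without_locality", "swin_without_cnn")) {
      skip <- switch(kind, swin_cnn = "locality",
                     swin_without_locality = "concat",
                     swin_without_cnn = "no_cnn")
      arch <- build_swin(config, skip)
      list(arch = arch, layers = swin_layers(arch),
           fwd = function(a, x) swin_fwd(a, x),
           bwd = function(a, d) swin_bwd(a, d))
    } else if (kind == "automap") {
      arch <- build_automap(config)
      list(arch = arch, layers = automap_layers(arch),
           fwd = function(a, x) automap_fwd(a, x),
           bwd = function(a, d) automap_bwd(a, d))
    } else {
      arch <- build_mfcnn(config)
      list(arch = arch, layers = mfcnn_layers(arch),
           fwd = function(a, x) mfcnn_fwd(a, x),
           bwd = function(a, d) mfcnn_bwd(a, d))
    }
  }
  parts <- if (isTRUE(.nn$meta)) build() else with_seed(seed, build())
  structure(list(kind = kind, config = config, seed = as.integer(seed),
                 arch = parts$arch, layers = parts$layers,
                 fwd = parts$fwd, bwd = parts$bwd),
            class = "recon_model")
}

#' @export
print.recon_model <- function(x, ...) {
  cat(sprintf("recon_model '%s': N=%d, %s parameters\n", x$kind,
              x$config$N, format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' For a built model, counts the stored arrays.  For a (kind, config) pair,
#' builds the model in shape-only mode (no allocation), so counts for very
#' large configurations are cheap.
#'
#' @param model a \code{recon_model}, or a kind string.
#' @param config required when \code{model} is a kind string.
#' @return integer parameter count.
#' @export
count_params <- function(model, config = NULL) {
  if (is.character(model)) {
    old <- .nn$meta
    .nn$meta <- TRUE
    on.exit(.nn$meta <- old)
    model <- build_model(model, config)
  }
  sum(vapply(model$layers, function(ly)
    sum(vapply(ly$params, nn_size, numeric(1))), numeric(1)))
}

#' Reconstruct yield images from sinograms
#'
#' Runs the model forward (deterministic; the networks have no stochastic
#' layers) and clips the output to [0, 1].
#'
#' @param model a trained or initialized \code{recon_model}.
#' @param P an N x N sinogram matrix, or an (B, N, N) array of them.
#' @return matching N x N matrix or (B, N, N) array in [0, 1].
#' @export
reconstruct <- function(model, P) {
  N <- model$config$N
  if (!is.null(model$preproc)) P <- apply_preproc(model$preproc, P)
  single <- length(dim(P)) == 2 || is.null(dim(P))
  if (single && !all(dim(P) == c(N, N)))
    stop("sinogram is ", paste(dim(P), collapse = "x"),
         " but the model expects ", N, "x", N)
  x <- if (single) array(P, c(1L, N, N, 1L)) else {
    stopifnot(all(dim(P)[2:3] == N))
    array(P, c(dim(P)[1], N, N, 1L))
  }
  y <- model$fwd(model$arch, x)
  y <- pmin(pmax(y, 0), 1)
  if (single) matrix(y, N, N) else array(y, dim(P))
}
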