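## Minimal neural-network kernel: parameterized layers with explicit
## forward/backward passes and an Adam optimizer.  Tensors are batch-first
## R arrays: token sequences (B, L, C), feature maps (B, H, W, C).  All
## heavy lifting is BLAS matrix multiplication on 2-D reshapes.

.nn <- new.env(parent = emptyenv())
.nn$meta <- FALSE   # when TRUE, parameters are shape stubs (for counting)

nn_param <- function(dims, init = c("xavier", "zeros", "tnormal"),
                     fan = NULL) {
  init <- match.arg(init)
  if (isTRUE(.nn$meta))
    return(structure(list(dims = dims), class = "nn_shape"))
  n <- prod(dims)
  x <- switch(init,
    zeros = rep(0, n),
    tnormal = stats::rnorm(n, sd = 0.02),
    xavier = {
      if (is.null(fan)) fan <- c(dims[1], dims[length(dims)])
      lim <- sqrt(6 / sum(fan))
      stats::runif(n, -lim, lim)
    })
  array(x, dim = dims)
}

nn_size <- function(p) if (inherits(p, "nn_shape")) prod(p$dims) else length(p)

## a layer is an environment with $params, $grads and closures $fwd, $bwd.
## Every layer appears exactly once in a model graph, so $bwd OVERWRITES
## $grads (no per-step zeroing needed); zero_grads() only (re)initializes.
new_layer <- function(kind, params) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- kind
  ly$params <- params
  ly$grads <- NULL
  ly
}

zero_grads <- function(layers) {
  for (ly in layers) {
    if (is.null(ly$grads))
      ly$grads <- lapply(ly$params, function(p) array(0, dim = dim(p)))
    else
      for (j in seq_along(ly$grads)) ly$grads[[j]][] <- 0
  }
  invisible(NULL)
}

## ---- dense -----------------------------------------------------------------

nn_linear <- function(d_in, d_out, bias = TRUE) {
  ly <- new_layer("linear", c(
    list(W = nn_param(c(d_in, d_out), "xavier", fan = c(d_in, d_out))),
    if (bias) list(b = nn_param(d_out, "zeros"))))
  ly$d_in <- d_in; ly$d_out <- d_out
  ly$fwd <- function(x) {
    dm <- dim(x)
    x2 <- x; dim(x2) <- c(prod(dm) / d_in, d_in)
    ly$x2 <- x2; ly$dm <- dm
    y <- x2 %*% ly$params$W
    if (!is.null(ly$params$b)) y <- y + rep(ly$params$b, each = nrow(y))
    dim(y) <- c(dm[-length(dm)], d_out)
    y
  }
  ly$bwd <- function(dy) {
    dy2 <- dy; dim(dy2) <- c(prod(dim(dy)) / d_out, d_out)
    ly$grads$W <- crossprod(ly$x2, dy2)
    if (!is.null(ly$params$b))
      ly$grads$b <- colSums(dy2)
    dx <- tcrossprod(dy2, ly$params$W)
    dim(dx) <- ly$dm
    dx
  }
  ly
}

## ---- layer norm over the trailing dimension --------------------------------

nn_layernorm <- function(C, eps = 1e-5) {
  g0 <- nn_param(C, "zeros")
  if (!isTRUE(.nn$meta)) g0 <- g0 + 1
  ly <- new_layer("layernorm", list(g = g0, b = nn_param(C, "zeros")))
  ly$fwd <- function(x) {
    dm <- dim(x)
    x2 <- x; dim(x2) <- c(prod(dm) / C, C)
    mu <- rowMeans(x2)
    xc <- x2 - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xh <- xc * inv
    ly$xh <- xh; ly$inv <- inv; ly$dm <- dm
    y <- xh * rep(ly$params$g, each = nrow(x2)) +
      rep(ly$params$b, each = nrow(x2))
    dim(y) <- dm
    y
  }
  ly$bwd <- function(dy) {
    dm <- ly$dm
    dy2 <- dy; dim(dy2) <- c(prod(dm) / C, C)
    ly$grads$g <- colSums(dy2 * ly$xh)
    ly$grads$b <- colSums(dy2)
    dxh <- dy2 * rep(ly$params$g, each = nrow(dy2))
    dx <- ly$inv * (dxh - rowMeans(dxh) - ly$xh * rowMeans(dxh * ly$xh))
    dim(dx) <- dm
    dx
  }
  ly
}

## ---- stateless activations (cache inside a layer env for backward) ---------

nn_act <- function(kind = c("gelu", "relu", "tanh")) {
  kind <- match.arg(kind)
  ly <- new_layer(paste0("act_", kind), list())
  k0 <- sqrt(2 / pi)
  ly$fwd <- function(x) {
    ly$x <- x
    switch(kind,
      relu = { y <- x; y[y < 0] <- 0; y },
      tanh = { y <- tanh(x); ly$y <- y; y },
      gelu = {
        t <- tanh(k0 * (x + 0.044715 * x^3))
        ly$t <- t
        0.5 * x * (1 + t)
      })
  }
  ly$bwd <- function(dy) {
    x <- ly$x
    switch(kind,
      relu = dy * (x > 0),
      tanh = dy * (1 - ly$y^2),
      gelu = {
        t <- ly$t
        dy * (0.5 * (1 + t) +
                0.5 * x * (1 - t^2) * k0 * (1 + 3 * 0.044715 * x^2))
      })
  }
  ly
}

## ---- 2-D convolution, stride 1, same padding -------------------------------

nn_conv2d <- function(c_in, c_out, k = 3) {
  stopifnot(k %in% c(1, 3))
  ly <- new_layer("conv2d", list(
    W = nn_param(c(k * k * c_in, c_out), "xavier",
                 fan = c(k * k * c_in, k * k * c_out)),
    b = nn_param(c_out, "zeros")))
  ly$k <- k; ly$c_in <- c_in; ly$c_out <- c_out
  # precomputed column indices for im2col on a (B, H, W, C) input:
  # all gathers/scatters run on 2-D (B, columns) reshapes
  conv_idx <- function(H, W) {
    Hp <- H + 2L; Wp <- W + 2L
    h <- rep(seq_len(H), times = W)
    w <- rep(seq_len(W), each = H)
    cc <- seq_len(c_in) - 1L
    interior <- as.vector(outer((h + 1L) + w * Hp, cc * Hp * Wp, "+"))
    gl <- vector("list", 9)
    o <- 0
    for (dx in 0:2) for (dyy in 0:2) {
      o <- o + 1
      gl[[o]] <- as.vector(outer((h + dyy) + (w + dx - 1L) * Hp,
                                 cc * Hp * Wp, "+"))
    }
    list(Hp = Hp, Wp = Wp, interior = interior, gather = unlist(gl),
         blocks = gl)
  }
  ly$fwd <- function(x) {
    dm <- dim(x)                      # (B, H, W, C)
    B <- dm[1]; H <- dm[2]; W <- dm[3]
    x2 <- x; dim(x2) <- c(B, H * W * c_in)
    if (k == 1) {
      dim(x2) <- c(B * H * W, c_in)
      ly$cols <- x2; ly$dm <- dm
      y <- x2 %*% ly$params$W + rep(ly$params$b, each = B * H * W)
      dim(y) <- c(B, H, W, c_out)
      return(y)
    }
    if (is.null(ly$idx) || !identical(ly$idx_hw, c(H, W))) {
      ly$idx <- conv_idx(H, W); ly$idx_hw <- c(H, W)
    }
    ix <- ly$idx
    xp <- matrix(0, B, ix$Hp * ix$Wp * c_in)
    xp[, ix$interior] <- x2
    cols <- xp[, ix$gather, drop = FALSE]
    dim(cols) <- c(B * H * W, 9 * c_in)
    ly$cols <- cols; ly$dm <- dm
    y <- cols %*% ly$params$W + rep(ly$params$b, each = B * H * W)
    dim(y) <- c(B, H, W, c_out)
    y
  }
  ly$bwd <- function(dy) {
    dm <- ly$dm
    B <- dm[1]; H <- dm[2]; W <- dm[3]
    dy2 <- dy; dim(dy2) <- c(B * H * W, c_out)
    ly$grads$W <- crossprod(ly$cols, dy2)
    ly$grads$b <- colSums(dy2)
    dcols <- tcrossprod(dy2, ly$params$W)
    if (k == 1) { dim(dcols) <- dm; return(dcols) }
    ix <- ly$idx
    dim(dcols) <- c(B, H * W * 9 * c_in)
    dxp <- matrix(0, B, ix$Hp * ix$Wp * c_in)
    nb <- H * W * c_in
    for (o in 1:9) {
      tgt <- ix$blocks[[o]]
      dxp[, tgt] <- dxp[, tgt, drop = FALSE] +
        dcols[, (o - 1L) * nb + seq_len(nb), drop = FALSE]
    }
    dx <- dxp[, ix$interior, drop = FALSE]
    dim(dx) <- dm
    dx
  }
  ly
}

## ---- transposed convolution, 2x2 kernel, stride 2 (pixel-shuffle form) -----

nn_convtranspose2x <- function(c_in, c_out) {
  ly <- new_layer("convtr2x", list(
    W = nn_param(c(c_in, 4 * c_out), "xavier", fan = c(c_in, 4 * c_out)),
    b = nn_param(c_out, "zeros")))
  ly$fwd <- function(x) {
    dm <- dim(x); B <- dm[1]; H <- dm[2]; W <- dm[3]
    x2 <- x; dim(x2) <- c(B * H * W, dm[4])
    ly$x2 <- x2; ly$dm <- dm
    y2 <- x2 %*% ly$params$W                       # (BHW, 4*c_out)
    # depth-to-space: 4 sub-pixels (dy, dx) in {0,1}^2
    y <- array(0, c(B, 2 * H, 2 * W, c_out))
    o <- 0
    for (dx in 0:1) for (dyy in 0:1) {
      blk <- y2[, o + seq_len(c_out), drop = FALSE]
      dim(blk) <- c(B, H, W, c_out)
      y[, seq(1 + dyy, 2 * H, 2), seq(1 + dx, 2 * W, 2), ] <- blk
      o <- o + c_out
    }
    y + rep(ly$params$b, each = B * 4 * H * W)
  }
  ly$bwd <- function(dy) {
    dm <- ly$dm; B <- dm[1]; H <- dm[2]; W <- dm[3]
    c_out <- length(ly$params$b)
    ly$grads$b <- colSums(matrix(dy, ncol = c_out))
    dy2 <- matrix(0, B * H * W, 4 * c_out)
    o <- 0
    for (dx in 0:1) for (dyy in 0:1) {
      blk <- dy[, seq(1 + dyy, 2 * H, 2), seq(1 + dx, 2 * W, 2), ,
                drop = FALSE]
      dim(blk) <- c(B * H * W, c_out)
      dy2[, o + seq_len(c_out)] <- blk
      o <- o + c_out
    }
    ly$grads$W <- crossprod(ly$x2, dy2)
    dx2 <- tcrossprod(dy2, ly$params$W)
    dim(dx2) <- dm
    dx2
  }
  ly
}

## ---- nearest-neighbour 2x upsampling (no parameters) -----------------------

nn_upsample2x <- function() {
  ly <- new_layer("upsample2x", list())
  up_idx <- function(H, W, C) {
    h2 <- rep(rep(seq_len(H), each = 2), times = 2 * W)
    w2 <- rep(rep(seq_len(W), each = 2), each = 2 * H)
    hw <- h2 + (w2 - 1L) * H
    as.vector(outer(hw, (seq_len(C) - 1L) * H * W, "+"))
  }
  ly$fwd <- function(x) {
    dm <- dim(x); B <- dm[1]; H <- dm[2]; W <- dm[3]; C <- dm[4]
    ly$dm <- dm
    if (is.null(ly$idx) || !identical(ly$idx_dm, dm[-1])) {
      ly$idx <- up_idx(H, W, C); ly$idx_dm <- dm[-1]
    }
    x2 <- x; dim(x2) <- c(B, H * W * C)
    y <- x2[, ly$idx, drop = FALSE]
    dim(y) <- c(B, 2 * H, 2 * W, C)
    y
  }
  ly$bwd <- function(dy) {
    dm <- ly$dm; B <- dm[1]; H <- dm[2]; W <- dm[3]; C <- dm[4]
    dy2 <- dy; dim(dy2) <- c(B, 4 * H * W * C)
    # group-sum the four sub-pixel contributions back to each source pixel
    dx <- t(rowsum(t(dy2), ly$idx))
    dim(dx) <- dm
    dx
  }
  ly
}

## ---- Adam ------------------------------------------------------------------

## Adam moments live inside each layer environment (ly$adam_m / ly$adam_v).
## The update itself is a fused in-place C++ kernel, so parameters, moments
## and gradients must never alias other live R objects: adam_state allocates
## fresh moment arrays and snapshot_params() deep-copies.
adam_state <- function(layers) {
  for (ly in layers) {
    ly$adam_m <- lapply(ly$params, function(p) array(0, dim = dim(p)))
    ly$adam_v <- lapply(ly$params, function(p) array(0, dim = dim(p)))
  }
  list(t = 0)
}

adam_step <- function(layers, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (ly in layers) {
    for (j in names(ly$params)) {
      adam_update_inplace(ly$params[[j]], ly$grads[[j]],
                          ly$adam_m[[j]], ly$adam_v[[j]],
                          lr, beta1, beta2, eps, bc1, bc2)
    }
  }
  state
}
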