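## Shifted-window multi-head self-attention and the Swin transformer block.
## Token sequences are (B, L, C) arrays over a G x G token grid with
## l = gi + (gj - 1) * G (grid row fastest, matching R's column-major order).

lin_index <- function(gi, gj, G) gi + (gj - 1L) * G

## permutation putting each w x w window's tokens contiguously
## (within-window row fastest, windows column-major)
window_perm <- function(G, w) {
  nwin <- G %/% w
  perm <- integer(G * G)
  m <- 0L
  for (wj in 0:(nwin - 1)) for (wi in 0:(nwin - 1))
    for (oj in 0:(w - 1)) for (oi in 0:(w - 1)) {
      m <- m + 1L
      perm[m] <- lin_index(wi * w + oi + 1L, wj * w + oj + 1L, G)
    }
  perm
}

## cyclic shift of the token grid by -s (position p shows original p + s)
roll_perm <- function(G, s) {
  gi <- ((seq_len(G) - 1L + s) %% G) + 1L
  as.vector(outer(gi, gi, function(a, b) lin_index(a, b, G)))
}

## attention mask (0 / -1e9) per window for the shifted configuration
shift_masks <- function(G, w, s) {
  lab1 <- function(p) ifelse(p <= G - w, 0L, ifelse(p <= G - s, 1L, 2L))
  nwin <- G %/% w
  M <- w * w
  masks <- vector("list", nwin * nwin)
  k <- 0
  for (wj in 0:(nwin - 1)) for (wi in 0:(nwin - 1)) {
    k <- k + 1
    oi <- rep(wi * w + seq_len(w), times = w)
    oj <- rep(wj * w + seq_len(w), each = w)
    lab <- lab1(oi) * 3L + lab1(oj)
    mk <- matrix(0, M, M)
    mk[outer(lab, lab, "!=")] <- -1e9
    masks[[k]] <- mk
  }
  masks
}

## relative-position-bias index matrix (M x M into a (2w-1)^2 table)
relpos_index <- function(w) {
  oi <- rep(seq_len(w), times = w)
  oj <- rep(seq_len(w), each = w)
  di <- outer(oi, oi, "-") + w - 1
  dj <- outer(oj, oj, "-") + w - 1
  di * (2 * w - 1) + dj + 1
}

## window-based multi-head self-attention (W-MSA, or SW-MSA when shift > 0)
nn_window_attention <- function(C, heads, G, window, shift = 0L) {
  w <- min(window, G)
  if (w == G) shift <- 0L                 # single window: shifting is moot
  stopifnot(G %% w == 0, C %% heads == 0)
  ly <- new_layer("wmsa", list(
    Wqkv = nn_param(c(C, 3 * C), "xavier", fan = c(C, 3 * C)),
    bqkv = nn_param(3 * C, "zeros"),
    Wproj = nn_param(c(C, C), "xavier"),
    bproj = nn_param(C, "zeros"),
    relbias = nn_param(c((2 * w - 1)^2, heads), "tnormal")))
  M <- w * w
  nwin <- (G %/% w)^2
  dh <- C %/% heads
  scale <- 1 / sqrt(dh)
  perm <- window_perm(G, w)
  if (shift > 0) perm <- roll_perm(G, shift)[perm]
  iperm <- integer(length(perm)); iperm[perm] <- seq_along(perm)
  masks <- if (shift > 0) shift_masks(G, w, shift) else NULL
  ridx <- relpos_index(w)
  hcols <- lapply(seq_len(heads), function(h) (h - 1) * dh + seq_len(dh))

  ly$fwd <- function(x) {
    B <- dim(x)[1]; L <- dim(x)[2]
    xp <- x[, perm, , drop = FALSE]
    x2 <- xp; dim(x2) <- c(B * L, C)
    ly$x2 <- x2
    qkv <- x2 %*% ly$params$Wqkv + rep(ly$params$bqkv, each = B * L)
    dim(qkv) <- c(B, L, 3 * C)
    out <- array(0, c(B, L, C))
    cache <- vector("list", B * nwin * heads)
    bias <- lapply(seq_len(heads), function(h)
      matrix(ly$params$relbias[ridx, h], M, M))
    ci <- 0
    for (win in seq_len(nwin)) {
      rows <- (win - 1L) * M + seq_len(M)
      mk <- if (!is.null(masks)) masks[[win]]
      for (b in seq_len(B)) {
        blk <- qkv[b, rows, ]; dim(blk) <- c(M, 3 * C)
        for (h in seq_len(heads)) {
          hc <- hcols[[h]]
          q <- blk[, hc, drop = FALSE] * scale
          k <- blk[, C + hc, drop = FALSE]
          v <- blk[, 2 * C + hc, drop = FALSE]
          s <- tcrossprod(q, k) + bias[[h]]
          if (!is.null(mk)) s <- s + mk
          s <- s - s[cbind(seq_len(nrow(s)), max.col(s, "first"))]
          e <- exp(s)
          A <- e / rowSums(e)
          out[b, rows, hc] <- A %*% v
          ci <- ci + 1
          cache[[ci]] <- list(q = q, k = k, v = v, A = A, b = b,
                              rows = rows, h = h)
        }
      }
    }
    ly$cache <- cache
    out2 <- out; dim(out2) <- c(B * L, C)
    ly$attn_out <- out2; ly$B <- B; ly$L <- L
    y <- out2 %*% ly$params$Wproj + rep(ly$params$bproj, each = B * L)
    dim(y) <- c(B, L, C)
    y[, iperm, , drop = FALSE]
  }

  ly$bwd <- function(dy) {
    B <- ly$B; L <- ly$L
    dyp <- dy[, perm, , drop = FALSE]
    dy2 <- dyp; dim(dy2) <- c(B * L, C)
    ly$grads$Wproj <- crossprod(ly$attn_out, dy2)
    ly$grads$bproj <- colSums(dy2)
    dout <- tcrossprod(dy2, ly$params$Wproj)
    dim(dout) <- c(B, L, C)
    dqkv <- array(0, c(B, L, 3 * C))
    dbias <- matrix(0, M * M, heads)
    for (cc in ly$cache) {
      hc <- hcols[[cc$h]]
      dO <- dout[cc$b, cc$rows, hc]; dim(dO) <- c(M, dh)
      dV <- crossprod(cc$A, dO)
      dA <- tcrossprod(dO, cc$v)
      dS <- cc$A * (dA - rowSums(dA * cc$A))
      dbias[, cc$h] <- dbias[, cc$h] + as.vector(dS)
      dQ <- (dS %*% cc$k) * scale
      dK <- crossprod(dS, cc$q)
      dqkv[cc$b, cc$rows, hc] <- dQ
      dqkv[cc$b, cc$rows, C + hc] <- dK
      dqkv[cc$b, cc$rows, 2 * C + hc] <- dV
    }
    # scatter bias gradients back through the shared index table
    db <- array(0, dim = c((2 * w - 1)^2, heads))
    for (h in seq_len(heads)) {
      acc <- rowsum(dbias[, h], as.vector(ridx))
      db[as.integer(rownames(acc)), h] <- acc
    }
    ly$grads$relbias <- db
    dqkv2 <- dqkv; dim(dqkv2) <- c(B * L, 3 * C)
    x2 <- ly_x2(ly)
    ly$grads$Wqkv <- crossprod(x2, dqkv2)
    ly$grads$bqkv <- colSums(dqkv2)
    dxp <- tcrossprod(dqkv2, ly$params$Wqkv)
    dim(dxp) <- c(B, L, C)
    dxp[, iperm, , drop = FALSE]
  }
  ly$w <- w; ly$shift <- shift
  ly
}

ly_x2 <- function(ly) ly$x2

## space-to-depth: (B, H, W, C) -> (B, H/s, W/s, s^2 C); parameter-free
nn_space2depth <- function(s) {
  ly <- new_layer("space2depth", list())
  ly$s <- s
  # pure column permutation of the (B, H*W*C) reshape; cached per shape
  s2d_idx <- function(H, W, C) {
    h2 <- rep(seq(1L, H, s), times = W %/% s)
    w2 <- rep(seq(1L, W, s), each = H %/% s)
    cc <- seq_len(C) - 1L
    gl <- vector("list", s * s)
    o <- 0
    for (dx in 0:(s - 1)) for (dyy in 0:(s - 1)) {
      o <- o + 1
      gl[[o]] <- as.vector(outer((h2 + dyy) + (w2 + dx - 1L) * H,
                                 cc * H * W, "+"))
    }
    unlist(gl)
  }
  ly$fwd <- function(x) {
    dm <- dim(x); B <- dm[1]; H <- dm[2]; W <- dm[3]; C <- dm[4]
    ly$dm <- dm
    if (is.null(ly$idx) || !identical(ly$idx_dm, dm[-1])) {
      ly$idx <- s2d_idx(H, W, C); ly$idx_dm <- dm[-1]
    }
    x2 <- x; dim(x2) <- c(B, H * W * C)
    y <- x2[, ly$idx, drop = FALSE]
    dim(y) <- c(B, H %/% s, W %/% s, s * s * C)
    y
  }
  ly$bwd <- function(dy) {
    dm <- ly$dm; B <- dm[1]
    dy2 <- dy; dim(dy2) <- c(B, prod(dm[-1]))
    dx <- matrix(0, B, prod(dm[-1]))
    dx[, ly$idx] <- dy2
    dim(dx) <- dm
    dx
  }
  ly
}

## composite helpers: a "chain" is an ordered list of layers applied in
## sequence; chain_fwd / chain_bwd thread activations through it
chain_fwd <- function(chain, x) {
  for (ly in chain) x <- ly$fwd(x)
  x
}
chain_bwd <- function(chain, dy) {
  for (ly in rev(chain)) dy <- ly$bwd(dy)
  dy
}

## one Swin transformer block: pre-norm attention + pre-norm MLP, residual
swin_block <- function(C, heads, G, window, shift, mlp_ratio = 4) {
  blk <- list(
    ln1 = nn_layernorm(C),
    attn = nn_window_attention(C, heads, G, window, shift),
    ln2 = nn_layernorm(C),
    fc1 = nn_linear(C, round(mlp_ratio * C)),
    act = nn_act("gelu"),
    fc2 = nn_linear(round(mlp_ratio * C), C))
  blk
}

swin_block_fwd <- function(blk, x) {
  x <- x + blk$attn$fwd(blk$ln1$fwd(x))
  x + blk$fc2$fwd(blk$act$fwd(blk$fc1$fwd(blk$ln2$fwd(x))))
}

swin_block_bwd <- function(blk, dy) {
  d2 <- blk$ln2$bwd(blk$fc1$bwd(blk$act$bwd(blk$fc2$bwd(dy))))
  dh <- dy + d2
  d1 <- blk$ln1$bwd(blk$attn$bwd(dh))
  dh + d1
}

## patch merging: 2x spatial downsample, channel doubling
patch_merge <- function(C, G) {
  list(s2d = nn_space2depth(2L), ln = nn_layernorm(4 * C),
       red = nn_linear(4 * C, 2 * C, bias = FALSE), G = G, C = C)
}

patch_merge_fwd <- function(pm, x) {
  B <- dim(x)[1]
  dim(x) <- c(B, pm$G, pm$G, pm$C)
  y <- pm$s2d$fwd(x)
  dim(y) <- c(B, (pm$G %/% 2)^2, 4 * pm$C)
  pm$red$fwd(pm$ln$fwd(y))
}

patch_merge_bwd <- function(pm, dy) {
  B <- dim(dy)[1]
  d <- pm$ln$bwd(pm$red$bwd(dy))
  dim(d) <- c(B, pm$G %/% 2, pm$G %/% 2, 4 * pm$C)
  dx <- pm$s2d$bwd(d)
  dim(dx) <- c(B, pm$G^2, pm$C)
  dx
}
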