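## Supervised training of reconstruction networks: mean-squared-error loss
## between the network output and the max-normalized ground-truth image,
## Adam optimizer, best-validation-checkpoint retention.

## deep copy: parameters are updated in place by the Adam kernel, so the
## snapshot must own its memory
snapshot_params <- function(model)
  lapply(model$layers, function(ly) lapply(ly$params, function(p) p + 0))

restore_params <- function(model, snap) {
  for (i in seq_along(model$layers)) model$layers[[i]]$params <- snap[[i]]
  invisible(model)
}

model_loss <- function(model, x, y, batch = 32L) {
  n <- dim(x)[1]
  tot <- 0
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    xb <- x[idx, , , drop = FALSE]
    dim(xb) <- c(length(idx), dim(x)[2], dim(x)[3], 1L)
    out <- model$fwd(model$arch, xb)
    yb <- y[idx, , , drop = FALSE]
    tot <- tot + sum((out - as.vector(yb))^2)
  }
  tot / (n * prod(dim(x)[2:3]))
}

#' Train a reconstruction model
#'
#' Minimizes the mean squared error between the network output and the
#' ground-truth yield image (both in [0, 1]) with Adam.  The weights with
#' the best validation loss are restored at the end (when validation data
#' are supplied).  Fully seeded: the same seed gives the same loss curve.
#'
#' @param model a \code{\link{build_model}} result (modified in place and
#'   returned).
#' @param x (n, N, N) array of network inputs (upscaled sinograms).
#' @param y (n, N, N) array of targets (max-normalized yield images).
#' @param x_val,y_val optional validation arrays in the same layout.
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param lr_decay per-epoch multiplicative learning-rate decay.
#' @param warmup epochs of linear learning-rate ramp-up from 0 (stabilizes
#'   the attention blocks at aggressive peak rates); decay starts after it.
#' @param peak_weight extra loss weight on bright ground-truth pixels: each
#'   pixel's squared error is weighted \code{1 + (peak_weight - 1) * y}
#'   (mean-normalized).  1 (default) is the plain MSE; values > 1
#'   counteract the regression-to-the-mean bias that flattens the small,
#'   bright inclusions which dominate the evaluation metrics.
#' @param seed integer seed controlling shuffling.
#' @param verbose print per-epoch losses.
#' @return the model, with a \code{history} data frame (epoch, train_loss,
#'   val_loss) attached.
#' @export
train_model <- function(model, x, y, x_val = NULL, y_val = NULL,
                        epochs = 20L, batch = 8L, lr = 1e-3, lr_decay = 1,
                        warmup = 0L, peak_weight = 1, seed = 1L,
                        verbose = FALSE) {
  n <- dim(x)[1]
  N <- model$config$N
  stopifnot(dim(x)[2] == N, dim(y)[1] == n)
  state <- adam_state(model$layers)
  zero_grads(model$layers)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- Inf
  best_snap <- NULL
  for (ep in seq_len(epochs)) {
    lr_ep <- if (ep <= warmup) lr * ep / (warmup + 1)
             else lr * lr_decay^(ep - warmup - 1)
    ord <- with_seed(seed * 10000L + ep, sample.int(n))
    ep_loss <- 0
    for (s in seq(1, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1, n)]
      B <- length(idx)
      xb <- x[idx, , , drop = FALSE]; dim(xb) <- c(B, N, N, 1L)
      yb <- y[idx, , , drop = FALSE]; dim(yb) <- c(B, N, N, 1L)
      out <- model$fwd(model$arch, xb)
      diff <- out - yb
      ep_loss <- ep_loss + sum(diff^2)
      if (peak_weight != 1) {
        w <- 1 + (peak_weight - 1) * yb
        w <- w / mean(w)
        diff <- w * diff
      }
      model$bwd(model$arch, 2 * diff / length(diff))
      state <- adam_step(model$layers, state, lr = lr_ep)
    }
    tr <- ep_loss / (n * N * N)
    vl <- NA_real_
    if (!is.null(x_val)) {
      vl <- model_loss(model, x_val, y_val)
      if (vl < best) { best <- vl; best_snap <- snapshot_params(model) }
    }
    if (!is.finite(tr)) stop("training diverged (non-finite loss) at epoch ", ep)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s", ep, tr,
                      ifelse(is.na(vl), "-", sprintf("%.5f", vl))))
  }
  if (!is.null(best_snap)) restore_params(model, best_snap)
  model$history <- hist
  model
}
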