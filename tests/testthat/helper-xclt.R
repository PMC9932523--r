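# shared fixtures, built once per test run

# coarse working mesh on the 50 mm domain (~1.3e3 nodes)
coarse_mesh <- function() {
  if (is.null(.fixtures$mesh)) .fixtures$mesh <- build_mesh(50, 2.5)
  .fixtures$mesh
}

# very coarse mesh for dense linear-algebra checks (<= 200 nodes)
tiny_mesh <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- build_mesh(50, 8.5)
  .fixtures$tiny
}

.fixtures <- new.env(parent = emptyenv())

# 4-connected component count of a binary image (flood fill)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- comp
      i <- (p - 1L) %% nrow(mask) + 1L
      j <- (p - 1L) %/% nrow(mask) + 1L
      nb <- c(if (i > 1) p - 1L, if (i < nrow(mask)) p + 1L,
              if (j > 1) p - nrow(mask), if (j < ncol(mask)) p + nrow(mask))
      queue <- c(queue, nb[mask[nb] & lab[nb] == 0L])
    }
  }
  comp
}

rel_err <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.eps)
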