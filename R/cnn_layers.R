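# Low-level CNN layer arithmetic. Everything is plain R arrays: images are
# H x W x C with values centred by the caller, convolutions are 3x3 stride-1
# with zero padding 1 (im2col + one matrix product), pooling is 2x2 max with
# stride 2 (odd trailing rows/columns are cropped, as in floor-division
# pooling). The backward pass supports the guided-backpropagation variant of
# the ReLU backward rule and can stop at any layer, which is what Grad-CAM
# and guided backpropagation need.

# Index matrices for the im2col gather are cached per (H, W, C) shape; the
# whole patch extraction is then a single indexed lookup.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  idx <- .im2col_cache[[key]]
  if (is.null(idx)) {
    Hp <- H + 2L; Wp <- W + 2L
    base_r <- rep(seq_len(H), W)
    base_c <- rep(seq_len(W), each = H)
    idx <- matrix(0L, H * W, 9L * C)
    k <- 0L
    for (dj in 0:2) for (di in 0:2) for (ch in seq_len(C)) {
      k <- k + 1L
      idx[, k] <- (base_r + di) + (base_c + dj - 1L) * Hp + (ch - 1L) * Hp * Wp
    }
    .im2col_cache[[key]] <- idx
  }
  idx
}

im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  idx <- im2col_index(H, W, C)
  matrix(xp[idx], nrow(idx), ncol(idx))
}

col2im3 <- function(dcols, H, W, C) {
  idx <- im2col_index(H, W, C)
  dxp <- numeric((H + 2L) * (W + 2L) * C)
  k <- 0L
  for (off in 1:9) {
    sel <- idx[, k + seq_len(C)]
    dxp[sel] <- dxp[sel] + dcols[, k + seq_len(C)]
    k <- k + C
  }
  array(dxp, c(H + 2L, W + 2L, C))[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

conv_forward <- function(x, layer) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cols <- im2col3(x)
  out <- cols %*% layer$W
  out <- sweep(out, 2, layer$b, "+")
  list(out = array(out, c(H, W, layer$cout)), cols = cols)
}

conv_backward <- function(dout, layer, cols, dims_in) {
  H <- dims_in[1]; W <- dims_in[2]; C <- dims_in[3]
  dmat <- matrix(dout, H * W, layer$cout)
  list(
    dx = col2im3(dmat %*% t(layer$W), H, W, C),
    dW = crossprod(cols, dmat),
    db = colSums(dmat)
  )
}

pool_forward <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  i1 <- seq.int(1L, 2L * H2, 2L); j1 <- seq.int(1L, 2L * W2, 2L)
  a <- x[i1, j1, , drop = FALSE];      b <- x[i1 + 1L, j1, , drop = FALSE]
  cc <- x[i1, j1 + 1L, , drop = FALSE]; d <- x[i1 + 1L, j1 + 1L, , drop = FALSE]
  m <- pmax(a, b, cc, d)
  ma <- a == m
  mb <- (b == m) & !ma
  mc <- (cc == m) & !ma & !mb
  md <- !(ma | mb | mc)
  list(out = m, masks = list(ma, mb, mc, md), dims_in = dim(x))
}

pool_backward <- function(dout, extra) {
  dims <- extra$dims_in
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  i1 <- seq.int(1L, 2L * H2, 2L); j1 <- seq.int(1L, 2L * W2, 2L)
  dx <- array(0, dims)
  dx[i1, j1, ] <- dout * extra$masks[[1]]
  dx[i1 + 1L, j1, ] <- dout * extra$masks[[2]]
  dx[i1, j1 + 1L, ] <- dout * extra$masks[[3]]
  dx[i1 + 1L, j1 + 1L, ] <- dout * extra$masks[[4]]
  dx
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' @keywords internal
#' @noRd
cnn_forward <- function(model, x, keep_cache = TRUE) {
  acts <- vector("list", length(model$layers))
  extras <- vector("list", length(model$layers))
  cur <- x
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    cur <- switch(layer$type,
      conv = {
        fw <- conv_forward(cur, layer)
        if (keep_cache) extras[[i]] <- fw["cols"]
        fw$out
      },
      relu = pmax(cur, 0),
      pool = {
        fw <- pool_forward(cur)
        if (keep_cache) extras[[i]] <- fw[c("masks", "dims_in")]
        fw$out
      },
      flatten = as.vector(cur),
      dense = as.vector(crossprod(layer$W, cur)) + layer$b,
      abort(sprintf("unknown layer type '%s'", layer$type))
    )
    if (keep_cache) acts[[i]] <- cur
  }
  logits <- cur
  list(logits = logits, probs = softmax(logits),
       cache = if (keep_cache) list(input = x, acts = acts, extras = extras))
}

# Backward pass from a gradient on the logits. Returns the gradient with
# respect to the output of layer `stop_after` (0 = the input), plus per-layer
# parameter gradients when `want_params`. `guided` switches every ReLU
# backward to the guided-backpropagation rule (gradient passed only where the
# forward activation AND the incoming gradient are positive).
#' @keywords internal
#' @noRd
cnn_backward <- function(model, cache, dlogits, stop_after = 0L,
                         guided = FALSE, want_params = FALSE) {
  layers <- model$layers
  grads <- if (want_params) vector("list", length(layers))
  d <- dlogits
  layer_input <- function(i) if (i == 1L) cache$input else cache$acts[[i - 1L]]
  for (i in rev(seq_along(layers))) {
    if (i <= stop_after) break
    layer <- layers[[i]]
    d <- switch(layer$type,
      dense = {
        v <- layer_input(i)
        if (want_params) grads[[i]] <- list(dW = outer(v, d), db = d)
        as.vector(layer$W %*% d)
      },
      flatten = array(d, dim = dim(layer_input(i))),
      relu = {
        gate <- layer_input(i) > 0
        if (guided) d * gate * (d > 0) else d * gate
      },
      pool = pool_backward(d, cache$extras[[i]]),
      conv = {
        xin <- layer_input(i)
        bw <- conv_backward(d, layer, cache$extras[[i]]$cols, dim(xin))
        if (want_params) grads[[i]] <- list(dW = bw$dW, db = bw$db)
        bw$dx
      }
    )
  }
  list(d = d, grads = grads)
}
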