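# Loop-based convolution oracles used by the relevance-map tests; written
# independently of the package's im2col/vectorised path.
# Conv weight column k = dj*3 + di + 1 multiplies input pixel (i+di-1, j+dj-1).

conv_oracle <- function(x, w9col, bias = 0) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(bias, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (dj in 0:2) for (di in 0:2) {
      ii <- i + di - 1L; jj <- j + dj - 1L
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + w9col[dj * 3 + di + 1] * x[ii, jj]
      }
    }
    out[i, j] <- out[i, j] + acc
  }
  out
}

conv_backward_oracle <- function(dout, w9col) {
  H <- nrow(dout); W <- ncol(dout)
  dx <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    for (dj in 0:2) for (di in 0:2) {
      ii <- i + di - 1L; jj <- j + dj - 1L
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        dx[ii, jj] <- dx[ii, jj] + dout[i, j] * w9col[dj * 3 + di + 1]
      }
    }
  }
  dx
}
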