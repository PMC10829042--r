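# Independent nested-loop oracle for the D-scSE equations: everything is
# computed with explicit scalar loops, no vectorisation shared with the
# implementation.

sigmoid_scalar <- function(z) 1 / (1 + exp(-z))

dscse_loop_oracle <- function(u, params) {
  d <- dim(u)
  C <- d[1]; H <- d[2]; W <- d[3]
  # spatial branch
  u_sse <- array(0, d)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      k <- params$spatial_bias
      for (cc in seq_len(C)) k <- k + params$spatial_kernel[cc] * u[cc, i, j]
      g <- sigmoid_scalar(k)
      for (cc in seq_len(C)) u_sse[cc, i, j] <- g * u[cc, i, j]
    }
  }
  # channel branch
  descr <- numeric(2 * C)
  for (cc in seq_len(C)) {
    s <- 0; mx <- -Inf
    for (i in seq_len(H)) for (j in seq_len(W)) {
      s <- s + u[cc, i, j]
      if (u[cc, i, j] > mx) mx <- u[cc, i, j]
    }
    descr[cc] <- s / (H * W)
    descr[C + cc] <- mx
  }
  r <- pmax(descr, 0)
  u_cse <- array(0, d)
  for (cc in seq_len(C)) {
    z <- params$channel_bias[cc]
    for (k in seq_len(2 * C)) z <- z + params$channel_weight[cc, k] * r[k]
    s <- sigmoid_scalar(z)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      u_cse[cc, i, j] <- s * u[cc, i, j]
    }
  }
  params$fusion$alpha * u_sse + params$fusion$beta * u_cse
}
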