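# D-scSE: dynamic concurrent spatial and channel squeeze-and-excitation.
#
# The spatial branch (sSE) squeezes channels with a 1x1 convolution and gates
# every pixel with a sigmoid; the channel branch (cSE) squeezes space with
# concatenated global average and max pooling, passes the ReLU-rectified
# descriptor through a single C x 2C affine layer, and gates every channel
# with a sigmoid. The two branch outputs are fused with learnable scalars
# alpha and beta, so the network decides per training run how much spatial
# versus channel recalibration it wants.

#' Spatial excitation (sSE)
#'
#' Squeezes the channel dimension with a 1x1 convolution
#' (`k[i,j] = sum_c kernel[c] * u[c,i,j] + bias`) and rescales every channel
#' of `u` by the per-pixel sigmoid gate `sigma(k)`.
#'
#' @param u numeric array `(C, H, W)`; a single feature map.
#' @param kernel numeric vector of length `C`: the 1x1 channel-squeeze
#'   convolution weights.
#' @param bias scalar bias of the squeeze convolution.
#' @return list with `output` (`(C, H, W)` array, same shape as `u`) and
#'   `gate` (`(H, W)` matrix with entries strictly inside (0, 1)).
#' @examples
#' u <- array(seq_len(8), c(2, 2, 2))
#' spatial_excite(u, kernel = c(1, -1))$gate
#' @export
spatial_excite <- function(u, kernel, bias = 0) {
  d <- dim(u)
  if (length(d) != 3L) stop("`u` must be a (C, H, W) array")
  if (length(kernel) != d[1]) {
    stop(sprintf("spatial kernel length (%d) must equal channel count (%d)",
                 length(kernel), d[1]))
  }
  um <- u
  dim(um) <- c(d[1], d[2] * d[3])
  k <- as.vector(kernel %*% um) + bias
  gate <- sigmoid(k)
  out <- um * rep(gate, each = d[1])
  dim(out) <- d
  list(output = out, gate = matrix(gate, d[2], d[3]))
}

#' Channel excitation (cSE)
#'
#' Builds the `2C` descriptor `x = concat(avgpool(u), maxpool(u))`, rectifies
#' it, applies the single affine layer `s = sigma(W relu(x) + b)` and rescales
#' channel `c` of `u` by `s[c]`.
#'
#' @param u numeric array `(C, H, W)`.
#' @param weight numeric matrix `C x 2C`: the fully connected layer.
#' @param bias numeric vector of length `C` (default zeros).
#' @return list with `output` (same shape as `u`), `gate` (length-`C` vector
#'   in (0, 1)) and `descriptor` (the pooled length-`2C` vector).
#' @export
channel_excite <- function(u, weight, bias = NULL) {
  d <- dim(u)
  if (length(d) != 3L) stop("`u` must be a (C, H, W) array")
  C <- d[1]
  if (!is.matrix(weight) || nrow(weight) != C || ncol(weight) != 2L * C) {
    stop(sprintf("channel weight must be %d x %d (C x 2C)", C, 2L * C))
  }
  if (is.null(bias)) bias <- numeric(C)
  um <- u
  dim(um) <- c(C, d[2] * d[3])
  descr <- c(rowMeans(um), apply(um, 1, max))
  s <- as.vector(sigmoid(weight %*% pmax(descr, 0) + bias))
  out <- um * s
  dim(out) <- d
  list(output = out, gate = s, descriptor = descr)
}

#' Fuse the two excitation branches
#'
#' Weighted elementwise sum `alpha * u_sse + beta * u_cse` with the learnable
#' fusion scalars.
#'
#' @param u_sse,u_cse arrays of identical shape (the two branch outputs).
#' @param weights list with scalar elements `alpha` and `beta` (see
#'   [init_fusion_weights()]).
#' @return array of the common input shape.
#' @export
fuse_excitations <- function(u_sse, u_cse, weights) {
  if (!identical(dim(u_sse), dim(u_cse))) {
    stop("branch outputs must share one shape")
  }
  weights$alpha * u_sse + weights$beta * u_cse
}

#' Initialise the fusion weights
#'
#' Draws `alpha` and `beta` i.i.d. from U(-sqrt(6/n), sqrt(6/n)), where `n`
#' is the number of input units of the fusion weight tensor (two branch
#' inputs by default).
#'
#' @param n positive integer; number of input units (default 2).
#' @param seed optional integer seed making the draw repeatable.
#' @return list with numeric scalars `alpha`, `beta` and the bound used.
#' @export
init_fusion_weights <- function(n = 2, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  bound <- sqrt(6 / n)
  draws <- stats::runif(2, -bound, bound)
  list(alpha = draws[1], beta = draws[2], bound = bound)
}

#' Parameter bundle for a D-scSE block
#'
#' Weights are Kaiming-uniform; biases start at zero so the bias-free
#' textbook formulas hold exactly at initialisation.
#'
#' @param channels channel count `C` of the feature maps the block will see.
#' @param seed optional seed fixing the draws.
#' @param n_init `n` passed to [init_fusion_weights()].
#' @return list with `spatial_kernel`, `spatial_bias`, `channel_weight`
#'   (`C x 2C`), `channel_bias` and `fusion`.
#' @export
dscse_params <- function(channels, seed = NULL, n_init = 2) {
  if (!is.null(seed)) set.seed(seed)
  list(
    spatial_kernel = as.vector(kaiming_uniform(c(1, channels))),
    spatial_bias = 0,
    channel_weight = matrix(kaiming_uniform(c(channels, 2 * channels)),
                            channels, 2 * channels),
    channel_bias = numeric(channels),
    fusion = init_fusion_weights(n = n_init)
  )
}

#' D-scSE forward pass (single feature map)
#'
#' Composes [spatial_excite()], [channel_excite()] and [fuse_excitations()].
#'
#' @param u numeric array `(C, H, W)`.
#' @param params a [dscse_params()] bundle dimensioned for `dim(u)[1]`
#'   channels.
#' @return array of the same shape as `u`.
#' @export
dscse_forward <- function(u, params) {
  sse <- spatial_excite(u, params$spatial_kernel, params$spatial_bias)
  cse <- channel_excite(u, params$channel_weight, params$channel_bias)
  fuse_excitations(sse$output, cse$output, params$fusion)
}

#' Closed-form parameter count of one D-scSE block
#'
#' `2C^2 + C` for the fully connected layer and its bias, `C + 1` for the
#' 1x1 squeeze convolution and its bias, plus the two fusion scalars:
#' `2C^2 + 2C + 3` in total.
#'
#' @param channels channel width `C`.
#' @return integer parameter count.
#' @export
dscse_param_count <- function(channels) {
  2 * channels^2 + 2 * channels + 3
}

# ---------------------------------------------------------------------------
# Trainable batched module

#' D-scSE attention module
#'
#' The trainable, batched version of [dscse_forward()] used inside the
#' network; operates on `(C, H, W, N)` arrays.
#'
#' @param channels channel count the block is dimensioned for.
#' @param n_init `n` of the fusion-weight initialisation.
#' @return an `nn_dscse` module.
#' @export
dscse_block <- function(channels, n_init = 2) {
  fw <- init_fusion_weights(n = n_init)
  new_module("nn_dscse",
             C = as.integer(channels),
             w_sp = nn_param(as.vector(kaiming_uniform(c(1, channels))), "dscse.spatial"),
             b_sp = nn_param(0, "dscse.spatial.bias"),
             W_ch = nn_param(matrix(kaiming_uniform(c(channels, 2 * channels)),
                                    channels, 2 * channels), "dscse.channel"),
             b_ch = nn_param(numeric(channels), "dscse.channel.bias"),
             alpha = nn_param(fw$alpha, "dscse.alpha"),
             beta = nn_param(fw$beta, "dscse.beta"),
             cache = NULL)
}

#' @export
nn_forward.nn_dscse <- function(m, x, training = FALSE) {
  d <- dim(x)
  C <- d[1]
  if (C != m$C) stop(sprintf("D-scSE sized for %d channels, got %d", m$C, C))
  HW <- d[2] * d[3]
  N <- d[4]
  xm <- x
  dim(xm) <- c(C, HW * N)
  # spatial branch
  k <- as.vector(m$w_sp$value %*% xm) + m$b_sp$value  # length HW*N
  g_sp <- sigmoid(k)
  u_sse <- xm * rep(g_sp, each = C)
  # channel branch: pooled descriptor per (channel, sample)
  xs <- x
  dim(xs) <- c(C, HW, N)
  xs_p <- aperm(xs, c(2, 1, 3))
  dim(xs_p) <- c(HW, C * N)
  avg <- colMeans(xs_p)
  amax_i <- max.col(t(xs_p), ties.method = "first")  # argmax over HW per (c,n)
  mx <- xs_p[cbind(amax_i, seq_len(C * N))]
  descr <- rbind(matrix(avg, C, N), matrix(mx, C, N))  # (2C, N)
  r <- pmax(descr, 0)
  z <- m$W_ch$value %*% r + m$b_ch$value               # (C, N)
  s <- sigmoid(z)
  s_full <- aperm(array(s, c(C, N, HW)), c(1, 3, 2))
  dim(s_full) <- c(C, HW * N)
  u_cse <- xm * s_full
  out <- m$alpha$value * u_sse + m$beta$value * u_cse
  dim(out) <- d
  if (training) {
    m$cache <- list(xm = xm, d = d, g_sp = g_sp, u_sse = u_sse,
                    s = s, s_full = s_full, u_cse = u_cse,
                    r = r, descr = descr, amax_i = amax_i)
  }
  out
}

#' @export
nn_backward.nn_dscse <- function(m, dy) {
  cc <- m$cache
  d <- cc$d
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  dym <- dy
  dim(dym) <- c(C, HW * N)
  # fusion scalars
  m$alpha$grad <- m$alpha$grad + sum(dym * cc$u_sse)
  m$beta$grad <- m$beta$grad + sum(dym * cc$u_cse)
  dy_sse <- m$alpha$value * dym
  dy_cse <- m$beta$value * dym
  # spatial branch: u_sse = g * x (g broadcast over channels)
  dx <- dy_sse * rep(cc$g_sp, each = C)
  dk <- colSums(dy_sse * cc$xm) * cc$g_sp * (1 - cc$g_sp)  # length HW*N
  dx <- dx + outer(m$w_sp$value, dk)
  m$w_sp$grad <- m$w_sp$grad + as.vector(cc$xm %*% dk)
  m$b_sp$grad <- m$b_sp$grad + sum(dk)
  # channel branch: u_cse = s * x (s broadcast over space)
  dx <- dx + dy_cse * cc$s_full
  prod_cs <- dy_cse * cc$xm
  dim(prod_cs) <- c(C, HW, N)
  pr <- aperm(prod_cs, c(2, 1, 3))
  dim(pr) <- c(HW, C * N)
  ds <- matrix(colSums(pr), C, N)
  dz <- ds * cc$s * (1 - cc$s)
  m$W_ch$grad <- m$W_ch$grad + dz %*% t(cc$r)
  m$b_ch$grad <- m$b_ch$grad + rowSums(dz)
  dr <- t(m$W_ch$value) %*% dz                  # (2C, N)
  ddescr <- dr * (cc$descr > 0)
  # avg-pool part spreads uniformly; max-pool part hits the argmax pixel
  davg <- ddescr[seq_len(C), , drop = FALSE] / HW
  dmax <- ddescr[C + seq_len(C), , drop = FALSE]
  # columns of the (HW, C*N) layout run over c fastest, then n
  dx_pool <- matrix(rep(as.vector(davg), each = HW), HW, C * N)
  dx_pool[cbind(cc$amax_i, seq_len(C * N))] <-
    dx_pool[cbind(cc$amax_i, seq_len(C * N))] + as.vector(dmax)
  dxp <- array(dx_pool, c(HW, C, N))
  dx <- dx + matrix(aperm(dxp, c(2, 1, 3)), C, HW * N)
  dim(dx) <- d
  dx
}

#' @export
nn_params.nn_dscse <- function(m) {
  list(m$w_sp, m$b_sp, m$W_ch, m$b_ch, m$alpha, m$beta)
}

#' @export
nn_trace.nn_dscse <- function(m, shape) {
  C <- shape[1]; HW <- shape[2] * shape[3]
  macs <- C * HW +            # 1x1 squeeze conv
    2 * C * C +               # C x 2C affine
    0
  extra <- HW +               # squeeze bias
    C +                       # affine bias
    C * HW * 2 +              # two gate rescalings
    C * HW * 3                # fusion: two scalar products and one add
  list(shape = shape, macs = macs, extra_flops = extra)
}
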