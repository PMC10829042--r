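# Layer zoo: convolution, batch norm, activations, pooling, bilinear
# resampling, linear. Every layer implements nn_forward / nn_backward /
# nn_params / nn_trace on (C, H, W, N) arrays. Convolutions use the
# kernel-position decomposition: one (C_out x C_in) matrix product per tap,
# which keeps everything inside BLAS without materialising im2col buffers.

conv_out_len <- function(n, k, stride, pad, dilation) {
  (n + 2L * pad - dilation * (k - 1L) - 1L) %/% stride + 1L
}

pad_spatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

#' 2-D convolution layer
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel_size square kernel side.
#' @param stride,padding,dilation usual convolution hyper-parameters.
#' @param bias include an additive bias (zero-initialised)?
#' @return an `nn_conv2d` module.
#' @keywords internal
#' @export
nn_conv2d <- function(in_channels, out_channels, kernel_size, stride = 1L,
                      padding = 0L, dilation = 1L, bias = TRUE,
                      name = "conv") {
  W <- nn_param(kaiming_uniform(c(out_channels, in_channels,
                                  kernel_size, kernel_size)), name)
  b <- if (bias) nn_param(numeric(out_channels), paste0(name, ".bias")) else NULL
  new_module("nn_conv2d",
             W = W, b = b, k = as.integer(kernel_size),
             stride = as.integer(stride), pad = as.integer(padding),
             dil = as.integer(dilation), cache = NULL)
}

#' @export
nn_forward.nn_conv2d <- function(m, x, training = FALSE) {
  d <- dim(x)
  Cin <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  stopifnot(Cin == dim(m$W$value)[2])
  k <- m$k; s <- m$stride; dl <- m$dil
  Ho <- conv_out_len(H, k, s, m$pad, dl)
  Wo <- conv_out_len(Wd, k, s, m$pad, dl)
  Co <- dim(m$W$value)[1]
  xp <- pad_spatial(x, m$pad)
  out <- matrix(0, Co, Ho * Wo * N)
  for (ki in seq_len(k)) {
    ri <- (seq_len(Ho) - 1L) * s + (ki - 1L) * dl + 1L
    for (kj in seq_len(k)) {
      ci <- (seq_len(Wo) - 1L) * s + (kj - 1L) * dl + 1L
      sl <- xp[, ri, ci, , drop = FALSE]
      dim(sl) <- c(Cin, Ho * Wo * N)
      out <- out + matrix(m$W$value[, , ki, kj], Co, Cin) %*% sl
    }
  }
  if (!is.null(m$b)) out <- out + m$b$value
  if (training) m$cache <- list(xp = xp, in_dim = d, out_dim = c(Co, Ho, Wo, N))
  dim(out) <- c(Co, Ho, Wo, N)
  out
}

#' @export
nn_backward.nn_conv2d <- function(m, dy) {
  cc <- m$cache
  Cin <- cc$in_dim[1]; N <- cc$in_dim[4]
  Ho <- cc$out_dim[2]; Wo <- cc$out_dim[3]; Co <- cc$out_dim[1]
  k <- m$k; s <- m$stride; dl <- m$dil
  dy_mat <- dy
  dim(dy_mat) <- c(Co, Ho * Wo * N)
  dxp <- array(0, dim = dim(cc$xp))
  for (ki in seq_len(k)) {
    ri <- (seq_len(Ho) - 1L) * s + (ki - 1L) * dl + 1L
    for (kj in seq_len(k)) {
      ci <- (seq_len(Wo) - 1L) * s + (kj - 1L) * dl + 1L
      sl <- cc$xp[, ri, ci, , drop = FALSE]
      dim(sl) <- c(Cin, Ho * Wo * N)
      m$W$grad[, , ki, kj] <- m$W$grad[, , ki, kj] +
        dy_mat %*% t(sl)
      dsl <- t(matrix(m$W$value[, , ki, kj], Co, Cin)) %*% dy_mat
      dim(dsl) <- c(Cin, Ho, Wo, N)
      dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] + dsl
    }
  }
  if (!is.null(m$b)) m$b$grad <- m$b$grad + rowSums(dy_mat)
  p <- m$pad
  if (p > 0L) {
    H <- cc$in_dim[2]; Wd <- cc$in_dim[3]
    dxp <- dxp[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE]
  }
  dxp
}

#' @export
nn_params.nn_conv2d <- function(m) {
  if (is.null(m$b)) list(m$W) else list(m$W, m$b)
}

#' @export
nn_trace.nn_conv2d <- function(m, shape) {
  Ho <- conv_out_len(shape[2], m$k, m$stride, m$pad, m$dil)
  Wo <- conv_out_len(shape[3], m$k, m$stride, m$pad, m$dil)
  Co <- dim(m$W$value)[1]
  macs <- as.numeric(Co) * shape[1] * m$k * m$k * Ho * Wo
  extra <- if (!is.null(m$b)) as.numeric(Co) * Ho * Wo else 0
  list(shape = c(Co, Ho, Wo), macs = macs, extra_flops = extra)
}

#' Batch normalisation over (H, W, N) per channel
#'
#' Training mode normalises with batch statistics (biased variance) and
#' updates running statistics with the given momentum; evaluation mode uses
#' the frozen running statistics, so repeated eval-mode forwards are
#' deterministic.
#' @keywords internal
nn_batchnorm2d <- function(channels, eps = 1e-5, momentum = 0.1,
                           name = "bn") {
  new_module("nn_batchnorm2d",
             gamma = nn_param(rep(1, channels), name),
             beta = nn_param(numeric(channels), paste0(name, ".beta")),
             run_mean = numeric(channels), run_var = rep(1, channels),
             eps = eps, momentum = momentum, C = as.integer(channels),
             cache = NULL)
}

#' @export
nn_forward.nn_batchnorm2d <- function(m, x, training = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], prod(d[-1]))
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    m$run_mean <- (1 - m$momentum) * m$run_mean + m$momentum * mu
    m$run_var <- (1 - m$momentum) * m$run_var + m$momentum * v
    ivar <- 1 / sqrt(v + m$eps)
    xhat <- xc * ivar
    m$cache <- list(xhat = xhat, ivar = ivar, d = d)
    y <- m$gamma$value * xhat + m$beta$value
  } else {
    ivar <- 1 / sqrt(m$run_var + m$eps)
    y <- m$gamma$value * ((xm - m$run_mean) * ivar) + m$beta$value
  }
  dim(y) <- d
  y
}

#' @export
nn_backward.nn_batchnorm2d <- function(m, dy) {
  cc <- m$cache
  d <- cc$d
  Mn <- prod(d[-1])
  dym <- dy
  dim(dym) <- c(d[1], Mn)
  m$gamma$grad <- m$gamma$grad + rowSums(dym * cc$xhat)
  m$beta$grad <- m$beta$grad + rowSums(dym)
  dxhat <- dym * m$gamma$value
  dx <- (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat)) * cc$ivar
  dim(dx) <- d
  dx
}

#' @export
nn_params.nn_batchnorm2d <- function(m) list(m$gamma, m$beta)

#' @export
nn_trace.nn_batchnorm2d <- function(m, shape) {
  list(shape = shape, macs = 0, extra_flops = 0)
}

#' ReLU activation
#' @keywords internal
nn_relu <- function() new_module("nn_relu", cache = NULL)

#' @export
nn_forward.nn_relu <- function(m, x, training = FALSE) {
  y <- pmax(x, 0)
  if (training) m$cache <- x > 0
  y
}

#' @export
nn_backward.nn_relu <- function(m, dy) dy * m$cache

#' @export
nn_params.nn_relu <- function(m) list()

#' @export
nn_trace.nn_relu <- function(m, shape) list(shape = shape, macs = 0, extra_flops = 0)

#' Max pooling (square kernel)
#' @keywords internal
nn_maxpool2d <- function(kernel_size = 3L, stride = 2L, padding = 1L) {
  new_module("nn_maxpool2d", k = as.integer(kernel_size),
             stride = as.integer(stride), pad = as.integer(padding),
             cache = NULL)
}

#' @export
nn_forward.nn_maxpool2d <- function(m, x, training = FALSE) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  k <- m$k; s <- m$stride; p <- m$pad
  Ho <- conv_out_len(H, k, s, p, 1L)
  Wo <- conv_out_len(Wd, k, s, p, 1L)
  Hp <- H + 2L * p; Wp <- Wd + 2L * p
  xp <- array(-Inf, c(C, Hp, Wp, N))
  xp[, p + seq_len(H), p + seq_len(Wd), ] <- x
  best <- array(-Inf, c(C, Ho, Wo, N))
  arg <- array(0L, c(C, Ho, Wo, N))   # linear index into padded array
  cidx <- seq_len(C)
  nidx <- seq_len(N)
  for (ki in seq_len(k)) {
    ri <- (seq_len(Ho) - 1L) * s + ki
    for (kj in seq_len(k)) {
      ci <- (seq_len(Wo) - 1L) * s + kj
      sl <- xp[, ri, ci, , drop = FALSE]
      # linear indices of the slice elements in xp
      lin <- outer(cidx, (ri - 1L) * C, "+")
      lin <- outer(as.vector(lin), (ci - 1L) * (C * Hp), "+")
      lin <- outer(as.vector(lin), (nidx - 1L) * (C * Hp * Wp), "+")
      dim(lin) <- c(C, Ho, Wo, N)
      upd <- sl > best
      best[upd] <- sl[upd]
      arg[upd] <- lin[upd]
    }
  }
  if (training) m$cache <- list(arg = arg, pdim = c(C, Hp, Wp, N), in_dim = d)
  best
}

#' @export
nn_backward.nn_maxpool2d <- function(m, dy) {
  cc <- m$cache
  dxp <- numeric(prod(cc$pdim))
  acc <- rowsum(as.vector(dy), group = as.vector(cc$arg))
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dim(dxp) <- cc$pdim
  p <- m$pad
  d <- cc$in_dim
  dxp[, p + seq_len(d[2]), p + seq_len(d[3]), , drop = FALSE]
}

#' @export
nn_params.nn_maxpool2d <- function(m) list()

#' @export
nn_trace.nn_maxpool2d <- function(m, shape) {
  Ho <- conv_out_len(shape[2], m$k, m$stride, m$pad, 1L)
  Wo <- conv_out_len(shape[3], m$k, m$stride, m$pad, 1L)
  list(shape = c(shape[1], Ho, Wo), macs = 0, extra_flops = 0)
}

# Adaptive average pooling to a fixed (g x g) grid, torch-style cell
# boundaries: cell i covers rows floor((i-1)H/g)+1 .. ceil(iH/g).
#' @keywords internal
nn_adaptive_avgpool <- function(out_size) {
  new_module("nn_adaptive_avgpool", g = as.integer(out_size), cache = NULL)
}

adaptive_bounds <- function(n, g) {
  i <- seq_len(g)
  list(from = floor((i - 1) * n / g) + 1L, to = ceiling(i * n / g))
}

#' @export
nn_forward.nn_adaptive_avgpool <- function(m, x, training = FALSE) {
  d <- dim(x)
  g <- m$g
  rb <- adaptive_bounds(d[2], g)
  cb <- adaptive_bounds(d[3], g)
  out <- array(0, c(d[1], g, g, d[4]))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    sl <- x[, rb$from[i]:rb$to[i], cb$from[j]:cb$to[j], , drop = FALSE]
    ds <- dim(sl)
    dim(sl) <- c(ds[1], ds[2] * ds[3], ds[4])
    out[, i, j, ] <- colMeans(aperm(sl, c(2, 1, 3)))
  }
  if (training) m$cache <- list(in_dim = d, rb = rb, cb = cb)
  out
}

#' @export
nn_backward.nn_adaptive_avgpool <- function(m, dy) {
  cc <- m$cache
  dx <- array(0, cc$in_dim)
  g <- m$g
  C <- cc$in_dim[1]; N <- cc$in_dim[4]
  for (i in seq_len(g)) for (j in seq_len(g)) {
    nr <- cc$rb$to[i] - cc$rb$from[i] + 1L
    ncl <- cc$cb$to[j] - cc$cb$from[j] + 1L
    contrib <- matrix(dy[, i, j, ], C, N) / (nr * ncl)
    blk <- aperm(array(contrib, c(C, N, nr, ncl)), c(1, 3, 4, 2))
    dx[, cc$rb$from[i]:cc$rb$to[i], cc$cb$from[j]:cc$cb$to[j], ] <-
      dx[, cc$rb$from[i]:cc$rb$to[i], cc$cb$from[j]:cc$cb$to[j], , drop = FALSE] + blk
  }
  dx
}

#' @export
nn_params.nn_adaptive_avgpool <- function(m) list()

#' @export
nn_trace.nn_adaptive_avgpool <- function(m, shape) {
  list(shape = c(shape[1], m$g, m$g), macs = 0, extra_flops = 0)
}

#' 1-D bilinear interpolation matrix (half-pixel-centre convention)
#' @keywords internal
interp_matrix <- function(n_in, n_out) {
  L <- matrix(0, n_out, n_in)
  if (n_in == 1L) { L[, 1] <- 1; return(L) }
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  w1 <- src - i0
  i0 <- as.integer(i0) + 1L
  i1 <- pmin(i0 + 1L, n_in)
  for (i in seq_len(n_out)) {
    L[i, i0[i]] <- L[i, i0[i]] + (1 - w1[i])
    L[i, i1[i]] <- L[i, i1[i]] + w1[i]
  }
  L
}

apply_rows <- function(x, L) {
  # multiply along the H dimension of (C, H, W, N)
  d <- dim(x)
  xp <- aperm(x, c(2, 1, 3, 4))
  dim(xp) <- c(d[2], d[1] * d[3] * d[4])
  y <- L %*% xp
  dim(y) <- c(nrow(L), d[1], d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

apply_cols <- function(x, L) {
  d <- dim(x)
  xp <- aperm(x, c(3, 1, 2, 4))
  dim(xp) <- c(d[3], d[1] * d[2] * d[4])
  y <- L %*% xp
  dim(y) <- c(nrow(L), d[1], d[2], d[4])
  aperm(y, c(2, 3, 1, 4))
}

#' Bilinear upsampling to a fixed spatial size
#' @keywords internal
nn_upsample_bilinear <- function(out_h, out_w) {
  new_module("nn_upsample_bilinear", out_h = as.integer(out_h),
             out_w = as.integer(out_w), Lh = NULL, Lw = NULL, cache = NULL)
}

#' @export
nn_forward.nn_upsample_bilinear <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (is.null(m$Lh) || ncol(m$Lh) != d[2]) m$Lh <- interp_matrix(d[2], m$out_h)
  if (is.null(m$Lw) || ncol(m$Lw) != d[3]) m$Lw <- interp_matrix(d[3], m$out_w)
  if (training) m$cache <- list(in_dim = d)
  apply_cols(apply_rows(x, m$Lh), m$Lw)
}

#' @export
nn_backward.nn_upsample_bilinear <- function(m, dy) {
  apply_rows(apply_cols(dy, t(m$Lw)), t(m$Lh))
}

#' @export
nn_params.nn_upsample_bilinear <- function(m) list()

#' @export
nn_trace.nn_upsample_bilinear <- function(m, shape) {
  list(shape = c(shape[1], m$out_h, m$out_w), macs = 0, extra_flops = 0)
}

#' Sequential container
#' @param ... modules, or a single list of modules.
#' @keywords internal
#' @export
nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) &&
      !inherits(mods[[1]], "nn_module")) mods <- mods[[1]]
  new_module("nn_sequential", mods = mods)
}

#' @export
nn_forward.nn_sequential <- function(m, x, training = FALSE) {
  for (mod in m$mods) x <- nn_forward(mod, x, training)
  x
}

#' @export
nn_backward.nn_sequential <- function(m, dy) {
  for (mod in rev(m$mods)) dy <- nn_backward(mod, dy)
  dy
}

#' @export
nn_params.nn_sequential <- function(m) {
  unlist(lapply(m$mods, nn_params), recursive = FALSE)
}

#' @export
nn_trace.nn_sequential <- function(m, shape) {
  macs <- 0; extra <- 0
  for (mod in m$mods) {
    tr <- nn_trace(mod, shape)
    shape <- tr$shape
    macs <- macs + tr$macs
    extra <- extra + tr$extra_flops
  }
  list(shape = shape, macs = macs, extra_flops = extra)
}
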