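#' @title Tensor layout and module protocol
#' @description
#' All activations flowing through the network are dense numeric arrays with
#' dimensions `(C, H, W, N)`: channels, rows, columns, batch. Modules are
#' environments carrying parameter slots and a cache for the backward pass;
#' the generics [nn_forward()], [nn_backward()], [nn_params()] and
#' [nn_trace()] define the protocol every layer implements.
#' @name nn-protocol
#' @keywords internal
NULL

#' Create a trainable parameter
#'
#' A parameter is an environment with a `value` array and a matching `grad`
#' accumulator, so optimizers can update weights in place.
#'
#' @param value numeric array holding the initial weights.
#' @param name optional label used in profiling reports.
#' @return an environment of class `nn_param`.
#' @keywords internal
nn_param <- function(value, name = NULL) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$vdim <- dim(value)   # NULL for plain vectors; restored after updates
  p$grad <- array(0, dim = if (is.null(dim(value))) length(value) else dim(value))
  p$name <- name
  class(p) <- "nn_param"
  p
}

n_elements <- function(p) length(p$value)

#' Zero all gradient accumulators
#' @param params list of `nn_param` objects.
#' @return `NULL`, invisibly.
#' @keywords internal
#' @export
zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

#' Forward pass through a module
#' @param m module environment.
#' @param x input array `(C, H, W, N)`.
#' @param training logical; `TRUE` enables batch statistics and caches for
#'   the backward pass.
#' @return output array.
#' @keywords internal
#' @export
nn_forward <- function(m, x, training = FALSE) UseMethod("nn_forward")

#' Backward pass through a module
#' @param m module environment (must have been run forward with
#'   `training = TRUE`).
#' @param dy gradient of the loss with respect to the module output.
#' @return gradient with respect to the module input.
#' @keywords internal
#' @export
nn_backward <- function(m, dy) UseMethod("nn_backward")

#' List the trainable parameters of a module
#' @param m module environment.
#' @return flat list of `nn_param` objects.
#' @keywords internal
#' @export
nn_params <- function(m) UseMethod("nn_params")

#' Shape/MAC trace of a module
#'
#' Propagates an input shape `(C, H, W)` through the module without computing
#' anything, returning the output shape and the multiply-accumulate count of
#' the parametric operations (convolutions, affine layers, attention
#' re-scalings). Batch normalisation and activations are not counted.
#'
#' @param m module environment.
#' @param shape integer vector `(C, H, W)`.
#' @return list with elements `shape` and `macs` (MACs) and `extra_flops`
#'   (non-MAC flops such as bias additions and gate multiplications).
#' @keywords internal
#' @export
nn_trace <- function(m, shape) UseMethod("nn_trace")

new_module <- function(class, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  class(m) <- c(class, "nn_module")
  m
}

#' Kaiming-uniform weight initialisation
#'
#' Draws from U(-sqrt(6/fan_in), sqrt(6/fan_in)), the standard scheme for
#' ReLU networks; biases are zero-initialised so that at initialisation the
#' layers realise their bias-free textbook formulas exactly.
#'
#' @param dims dimensions of the weight array; `fan_in` is the product of all
#'   but the first dimension.
#' @return numeric array of the requested shape.
#' @keywords internal
kaiming_uniform <- function(dims) {
  fan_in <- prod(dims[-1])
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' AdamW optimizer state
#'
#' Adam with decoupled weight decay: the decay term is applied directly to
#' the weights, outside the adaptive gradient rescaling.
#'
#' @param params list of `nn_param` objects to optimise.
#' @param lr learning rate (overridable per step).
#' @param betas exponential decay rates for the first and second moments.
#' @param eps numerical stabiliser added to the square-root denominator.
#' @param weight_decay decoupled weight-decay coefficient.
#' @return an environment of class `adamw` with an internal step counter.
#' @export
adamw <- function(params, lr = 1e-4, betas = c(0.9, 0.999), eps = 1e-8,
                  weight_decay = 1e-2) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$b1 <- betas[1]
  opt$b2 <- betas[2]
  opt$eps <- eps
  opt$wd <- weight_decay
  opt$t <- 0L
  opt$m <- lapply(params, function(p) array(0, dim = dim(p$grad)))
  opt$v <- lapply(params, function(p) array(0, dim = dim(p$grad)))
  class(opt) <- "adamw"
  opt
}

#' Apply one AdamW update
#' @param opt an [adamw()] optimizer.
#' @param lr learning rate for this step (e.g. from [cyclical_lr()]);
#'   defaults to the rate stored in the optimizer.
#' @return the optimizer, invisibly.
#' @export
adamw_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    newv <- p$value - lr * (mhat / (sqrt(vhat) + opt$eps) + opt$wd * p$value)
    dim(newv) <- p$vdim
    p$value <- newv
  }
  invisible(opt)
}

optimizer_state <- function(opt) {
  list(t = opt$t, m = opt$m, v = opt$v, lr = opt$lr,
       betas = c(opt$b1, opt$b2), eps = opt$eps, weight_decay = opt$wd)
}
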