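# Model profiler: trainable-parameter count, analytic FLOP estimate and
# parameter memory, plus attention-map extraction from the final backbone
# stage. The FLOP convention is fixed and printed in every report:
# 2 FLOPs per multiply-accumulate for convolutions, affine layers and
# attention re-scalings; batch norm and activations are not counted.

FLOP_CONVENTION <- paste(
  "2 FLOPs per MAC for convolutions, affine layers and attention ops;",
  "bias adds and gate multiplications counted once; BN/activations ignored")

#' Count trainable parameters
#' @param model any module.
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(nn_params(model), n_elements, numeric(1)))
}

#' Analytic FLOP estimate
#'
#' Propagates the input shape through the module graph and totals
#' multiply-accumulates without running the network.
#'
#' @param model any module.
#' @param input_shape `(C, H, W)` input shape (default `c(3, 512, 512)`).
#' @return list with `gflops`, `macs`, `extra_flops` and `convention`.
#' @export
estimate_flops <- function(model, input_shape = c(3, 512, 512)) {
  tr <- nn_trace(model, as.integer(input_shape))
  list(gflops = (2 * tr$macs + tr$extra_flops) / 1e9,
       flops = 2 * tr$macs + tr$extra_flops,
       macs = tr$macs, extra_flops = tr$extra_flops,
       out_shape = tr$shape, convention = FLOP_CONVENTION)
}

#' Parameter memory in MB
#'
#' The 32-bit storage formula `parameters * 4 / 1024^2`.
#'
#' @param n_params parameter count.
#' @return megabytes.
#' @export
parameter_memory_mb <- function(n_params) n_params * 4 / 1024^2

#' Profile a model
#'
#' Running the profiler never changes the model: weights and batch-norm
#' statistics are untouched.
#'
#' @param model an `nn_dsca_pspnet` (or any module).
#' @param input_shape `(C, H, W)` used for the FLOP estimate (and the timed
#'   forward, if requested).
#' @param measure_time also measure a single-image eval-mode forward (in
#'   milliseconds)? Informational only.
#' @return a `profile_report` list.
#' @export
profile_model <- function(model, input_shape = c(3, 512, 512),
                          measure_time = FALSE) {
  n <- count_parameters(model)
  fl <- estimate_flops(model, input_shape)
  tms <- NA_real_
  if (measure_time) {
    x <- array(0.5, c(input_shape, 1))
    t0 <- proc.time()[["elapsed"]]
    invisible(nn_forward(model, x, training = FALSE))
    tms <- (proc.time()[["elapsed"]] - t0) * 1000
  }
  structure(list(trainable_parameters = n,
                 parameters_millions = round(n / 1e6, 2),
                 gflops = fl$gflops,
                 flop_convention = FLOP_CONVENTION,
                 parameter_memory_mb = parameter_memory_mb(n),
                 forward_time_ms = tms,
                 input_shape = as.integer(input_shape)),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("parameters: %d (%.2f M)\n", x$trainable_parameters,
              x$parameters_millions))
  cat(sprintf("FLOPs at %s: %.2f G\n",
              paste(x$input_shape, collapse = "x"), x$gflops))
  cat(sprintf("  convention: %s\n", x$flop_convention))
  cat(sprintf("parameter memory: %.2f MB\n", x$parameter_memory_mb))
  if (is.finite(x$forward_time_ms)) {
    cat(sprintf("forward time: %.1f ms/image\n", x$forward_time_ms))
  }
  invisible(x)
}

#' Attention map from the final backbone stage
#'
#' Channel-wise mean of the final backbone output (after its D-scSE block),
#' min-max normalised to `[0, 1]`; constant maps normalise to all zeros.
#'
#' @param model an `nn_dsca_pspnet`.
#' @param image `H x W x 3` raster in `[0, 1]`.
#' @return list with `map` (backbone resolution, input/stride) and
#'   `upsampled` (input resolution, for overlays).
#' @export
attention_map <- function(model, image) {
  x <- raster_to_tensor(image)
  dim(x) <- c(dim(x), 1L)
  x <- (x - model$spec$norm_mean) / model$spec$norm_sd
  feat <- nn_forward(model$backbone, x, training = FALSE)
  d <- dim(feat)
  fm <- feat
  dim(fm) <- c(d[1], d[2] * d[3])
  amap <- matrix(colMeans(fm), d[2], d[3])
  rng <- max(amap) - min(amap)
  amap <- if (rng < 1e-12) matrix(0, d[2], d[3]) else (amap - min(amap)) / rng
  H <- dim(image)[1]; W <- dim(image)[2]
  up <- interp_matrix(d[2], H) %*% amap %*% t(interp_matrix(d[3], W))
  list(map = amap, upsampled = up)
}
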