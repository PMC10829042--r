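# Modified ResNet34 backbone: a convolutional stem, two standard residual
# stages, two dilated residual stages run at stride 1 (output stride 8 under
# the default spec), and a D-scSE attention block after every stage.

#' Backbone specification
#'
#' Defaults describe the dilated ResNet34 used at full scale: stem 7x7/2 +
#' max-pool/2, stages of (3, 4, 6, 3) basic blocks with (64, 128, 256, 512)
#' channels, stages 3-4 at stride 1 with dilations 2 and 4 (output stride 8),
#' and D-scSE after each stage.
#'
#' @param stage_block_counts residual blocks per stage.
#' @param stage_channels output channels per stage.
#' @param stage_strides stride of the first block of each stage.
#' @param dilations dilation factor used inside each stage.
#' @param dscse_after_stage logical per stage: insert a D-scSE block after it?
#' @param stem_channels,stem_kernel,stem_stride stem convolution geometry.
#' @param stem_pool apply the 3x3/2 max-pool after the stem?
#' @param in_channels input raster channels (RGB = 3).
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(stage_block_counts = c(3, 4, 6, 3),
                          stage_channels = c(64, 128, 256, 512),
                          stage_strides = c(1, 2, 1, 1),
                          dilations = c(1, 1, 2, 4),
                          dscse_after_stage = rep(TRUE, 4),
                          stem_channels = 64,
                          stem_kernel = 7,
                          stem_stride = 2,
                          stem_pool = TRUE,
                          in_channels = 3) {
  spec <- list(stage_block_counts = as.integer(stage_block_counts),
               stage_channels = as.integer(stage_channels),
               stage_strides = as.integer(stage_strides),
               dilations = as.integer(dilations),
               dscse_after_stage = as.logical(dscse_after_stage),
               stem_channels = as.integer(stem_channels),
               stem_kernel = as.integer(stem_kernel),
               stem_stride = as.integer(stem_stride),
               stem_pool = isTRUE(stem_pool),
               in_channels = as.integer(in_channels))
  validate_backbone_spec(spec)
  spec
}

validate_backbone_spec <- function(spec) {
  n <- length(spec$stage_block_counts)
  if (n != 4L) stop("backbone must have four stages")
  if (length(spec$stage_channels) != n || length(spec$stage_strides) != n ||
      length(spec$dilations) != n || length(spec$dscse_after_stage) != n) {
    stop("per-stage fields must all have length 4")
  }
  if (any(spec$dilations < 1L)) stop("dilation factors must be >= 1")
  if (any(spec$dilations[1:2] != 1L)) {
    stop("stages 1-2 are standard residual stages (dilation 1)")
  }
  if (any(spec$stage_block_counts < 1L)) stop("each stage needs >= 1 block")
  invisible(spec)
}

#' Basic residual block (two 3x3 convolutions)
#'
#' Standard block when `dilation = 1`, dilated block otherwise; the shortcut
#' is a 1x1 convolution + BN when the stride or channel count changes.
#' @keywords internal
#' @export
nn_basic_block <- function(in_channels, out_channels, stride = 1L,
                           dilation = 1L) {
  down <- (stride != 1L || in_channels != out_channels)
  new_module("nn_basic_block",
             conv1 = nn_conv2d(in_channels, out_channels, 3L, stride = stride,
                               padding = dilation, dilation = dilation,
                               bias = FALSE),
             bn1 = nn_batchnorm2d(out_channels),
             relu1 = nn_relu(),
             conv2 = nn_conv2d(out_channels, out_channels, 3L, stride = 1L,
                               padding = dilation, dilation = dilation,
                               bias = FALSE),
             bn2 = nn_batchnorm2d(out_channels),
             down_conv = if (down) nn_conv2d(in_channels, out_channels, 1L,
                                             stride = stride, bias = FALSE),
             down_bn = if (down) nn_batchnorm2d(out_channels),
             relu_out = nn_relu())
}

#' @export
nn_forward.nn_basic_block <- function(m, x, training = FALSE) {
  h <- nn_forward(m$conv1, x, training)
  h <- nn_forward(m$bn1, h, training)
  h <- nn_forward(m$relu1, h, training)
  h <- nn_forward(m$conv2, h, training)
  h <- nn_forward(m$bn2, h, training)
  sk <- if (!is.null(m$down_conv)) {
    nn_forward(m$down_bn, nn_forward(m$down_conv, x, training), training)
  } else x
  nn_forward(m$relu_out, h + sk, training)
}

#' @export
nn_backward.nn_basic_block <- function(m, dy) {
  dsum <- nn_backward(m$relu_out, dy)
  dh <- nn_backward(m$bn2, dsum)
  dh <- nn_backward(m$conv2, dh)
  dh <- nn_backward(m$relu1, dh)
  dh <- nn_backward(m$bn1, dh)
  dx <- nn_backward(m$conv1, dh)
  if (!is.null(m$down_conv)) {
    dx + nn_backward(m$down_conv, nn_backward(m$down_bn, dsum))
  } else {
    dx + dsum
  }
}

#' @export
nn_params.nn_basic_block <- function(m) {
  ps <- c(nn_params(m$conv1), nn_params(m$bn1),
          nn_params(m$conv2), nn_params(m$bn2))
  if (!is.null(m$down_conv)) {
    ps <- c(ps, nn_params(m$down_conv), nn_params(m$down_bn))
  }
  ps
}

#' @export
nn_trace.nn_basic_block <- function(m, shape) {
  t1 <- nn_trace(m$conv1, shape)
  t2 <- nn_trace(m$conv2, t1$shape)
  macs <- t1$macs + t2$macs
  extra <- t1$extra_flops + t2$extra_flops + prod(t2$shape)  # residual add
  if (!is.null(m$down_conv)) {
    td <- nn_trace(m$down_conv, shape)
    macs <- macs + td$macs
    extra <- extra + td$extra_flops
  }
  list(shape = t2$shape, macs = macs, extra_flops = extra)
}

#' Build the backbone
#'
#' Stem (`stem_kernel` conv + BN + ReLU, optional 3x3/2 max-pool), four
#' residual stages per the spec, and a D-scSE block after each stage where
#' enabled.
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed fixing all weight initialisation.
#' @return an `nn_backbone` module; its `out_channels` field gives the final
#'   channel width.
#' @export
build_backbone <- function(spec = backbone_spec(), seed = NULL) {
  validate_backbone_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  stem <- list(
    nn_conv2d(spec$in_channels, spec$stem_channels, spec$stem_kernel,
              stride = spec$stem_stride,
              padding = (spec$stem_kernel - 1L) %/% 2L, bias = FALSE),
    nn_batchnorm2d(spec$stem_channels),
    nn_relu())
  if (spec$stem_pool) stem <- c(stem, list(nn_maxpool2d(3L, 2L, 1L)))
  stem <- nn_sequential(stem)
  stages <- vector("list", 4L)
  dscse <- vector("list", 4L)
  in_ch <- spec$stem_channels
  for (s in 1:4) {
    blocks <- vector("list", spec$stage_block_counts[s])
    for (b in seq_len(spec$stage_block_counts[s])) {
      blocks[[b]] <- nn_basic_block(
        in_channels = if (b == 1L) in_ch else spec$stage_channels[s],
        out_channels = spec$stage_channels[s],
        stride = if (b == 1L) spec$stage_strides[s] else 1L,
        dilation = spec$dilations[s])
    }
    stages[[s]] <- nn_sequential(blocks)
    if (spec$dscse_after_stage[s]) {
      dscse[[s]] <- dscse_block(spec$stage_channels[s])
    }
    in_ch <- spec$stage_channels[s]
  }
  new_module("nn_backbone", stem = stem, stages = stages, dscse = dscse,
             spec = spec, out_channels = in_ch)
}

#' @export
nn_forward.nn_backbone <- function(m, x, training = FALSE) {
  h <- nn_forward(m$stem, x, training)
  for (s in 1:4) {
    h <- nn_forward(m$stages[[s]], h, training)
    if (!is.null(m$dscse[[s]])) h <- nn_forward(m$dscse[[s]], h, training)
  }
  h
}

#' @export
nn_backward.nn_backbone <- function(m, dy) {
  for (s in 4:1) {
    if (!is.null(m$dscse[[s]])) dy <- nn_backward(m$dscse[[s]], dy)
    dy <- nn_backward(m$stages[[s]], dy)
  }
  nn_backward(m$stem, dy)
}

#' @export
nn_params.nn_backbone <- function(m) {
  ps <- nn_params(m$stem)
  for (s in 1:4) {
    ps <- c(ps, nn_params(m$stages[[s]]))
    if (!is.null(m$dscse[[s]])) ps <- c(ps, nn_params(m$dscse[[s]]))
  }
  ps
}

#' @export
nn_trace.nn_backbone <- function(m, shape) {
  tr <- nn_trace(m$stem, shape)
  macs <- tr$macs; extra <- tr$extra_flops; shape <- tr$shape
  for (s in 1:4) {
    t2 <- nn_trace(m$stages[[s]], shape)
    shape <- t2$shape; macs <- macs + t2$macs; extra <- extra + t2$extra_flops
    if (!is.null(m$dscse[[s]])) {
      t3 <- nn_trace(m$dscse[[s]], shape)
      macs <- macs + t3$macs; extra <- extra + t3$extra_flops
    }
  }
  list(shape = shape, macs = macs, extra_flops = extra)
}

#' Per-stage output shapes of a backbone
#'
#' Propagates an input shape through stem and stages; useful for verifying
#' the output-stride plan.
#'
#' @param backbone an `nn_backbone`.
#' @param shape `(C, H, W)` input shape.
#' @return list of `(C, H, W)` shapes, one per stage.
#' @export
backbone_stage_shapes <- function(backbone, shape) {
  tr <- nn_trace(backbone$stem, shape)
  shape <- tr$shape
  out <- vector("list", 4L)
  for (s in 1:4) {
    shape <- nn_trace(backbone$stages[[s]], shape)$shape
    out[[s]] <- shape
  }
  out
}
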