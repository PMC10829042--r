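# DSCA-PSPNet assembly: backbone -> pyramid pooling -> D-scSE on the
# concatenated map -> 3x3 conv head -> 1x1 classifier -> bilinear upsample
# back to the input size.

#' Pyramid pooling specification
#'
#' Four parallel average-pooling branches at the classic bin sizes
#' (1, 2, 3, 6); each branch is reduced to `C/4` channels by a 1x1
#' convolution (+BN+ReLU) and bilinearly upsampled back, then concatenated
#' with the input, doubling the channel count.
#'
#' @param bin_sizes pooling grid sizes (exactly four).
#' @param reduced_channels channels per branch after the 1x1 convolution;
#'   `NULL` means input channels / 4.
#' @return a `pyramid_spec` list.
#' @export
pyramid_spec <- function(bin_sizes = c(1, 2, 3, 6), reduced_channels = NULL) {
  if (length(bin_sizes) != 4L) stop("the pyramid has exactly 4 branches")
  list(bin_sizes = as.integer(bin_sizes),
       reduced_channels = if (!is.null(reduced_channels)) as.integer(reduced_channels))
}

#' Pyramid pooling module
#' @param in_channels input channel count.
#' @param spec a [pyramid_spec()].
#' @keywords internal
#' @export
nn_pyramid_pool <- function(in_channels, spec = pyramid_spec()) {
  if (is.null(spec$reduced_channels) && in_channels %% 4L != 0L) {
    stop("input channels must be divisible by 4")
  }
  cr <- if (is.null(spec$reduced_channels)) in_channels %/% 4L else spec$reduced_channels
  branches <- lapply(spec$bin_sizes, function(g) {
    list(pool = nn_adaptive_avgpool(g),
         conv = nn_conv2d(in_channels, cr, 1L, bias = FALSE),
         bn = nn_batchnorm2d(cr),
         relu = nn_relu(),
         up = nn_upsample_bilinear(1L, 1L))
  })
  new_module("nn_pyramid_pool", branches = branches,
             in_channels = as.integer(in_channels), cr = as.integer(cr),
             bins = spec$bin_sizes,
             out_channels = as.integer(in_channels + 4L * cr))
}

set_upsample_size <- function(up, h, w) {
  if (up$out_h != h || up$out_w != w) {
    up$out_h <- as.integer(h)
    up$out_w <- as.integer(w)
    up$Lh <- NULL
    up$Lw <- NULL
  }
  invisible(up)
}

#' @export
nn_forward.nn_pyramid_pool <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (d[1] != m$in_channels) {
    stop(sprintf("pyramid sized for %d channels, got %d", m$in_channels, d[1]))
  }
  pieces <- vector("list", length(m$branches) + 1L)
  pieces[[1]] <- x
  for (i in seq_along(m$branches)) {
    br <- m$branches[[i]]
    h <- nn_forward(br$pool, x, training)
    h <- nn_forward(br$conv, h, training)
    h <- nn_forward(br$bn, h, training)
    h <- nn_forward(br$relu, h, training)
    set_upsample_size(br$up, d[2], d[3])
    pieces[[i + 1L]] <- nn_forward(br$up, h, training)
  }
  out <- array(0, c(m$out_channels, d[2], d[3], d[4]))
  at <- 0L
  for (p in pieces) {
    cc <- dim(p)[1]
    out[at + seq_len(cc), , , ] <- p
    at <- at + cc
  }
  out
}

#' @export
nn_backward.nn_pyramid_pool <- function(m, dy) {
  C <- m$in_channels
  dx <- dy[seq_len(C), , , , drop = FALSE]
  at <- C
  for (br in m$branches) {
    dp <- dy[at + seq_len(m$cr), , , , drop = FALSE]
    at <- at + m$cr
    dh <- nn_backward(br$up, dp)
    dh <- nn_backward(br$relu, dh)
    dh <- nn_backward(br$bn, dh)
    dh <- nn_backward(br$conv, dh)
    dx <- dx + nn_backward(br$pool, dh)
  }
  dx
}

#' @export
nn_params.nn_pyramid_pool <- function(m) {
  unlist(lapply(m$branches, function(br) {
    c(nn_params(br$conv), nn_params(br$bn))
  }), recursive = FALSE)
}

#' @export
nn_trace.nn_pyramid_pool <- function(m, shape) {
  macs <- 0; extra <- 0
  for (i in seq_along(m$branches)) {
    br <- m$branches[[i]]
    tp <- nn_trace(br$pool, shape)
    tc <- nn_trace(br$conv, tp$shape)
    macs <- macs + tc$macs
    extra <- extra + tc$extra_flops
  }
  list(shape = c(m$out_channels, shape[2], shape[3]), macs = macs,
       extra_flops = extra)
}

#' Model specification
#'
#' Pins the full DSCA-PSPNet: dilated ResNet34 backbone with D-scSE after
#' every stage, pyramid pooling, a D-scSE block on the concatenated map, and
#' a 3x3 (+BN+ReLU) / 1x1 prediction head, upsampled bilinearly to the input
#' size. Two output classes: sugarcane and background.
#'
#' @param backbone a [backbone_spec()].
#' @param pyramid a [pyramid_spec()].
#' @param head_channels width of the 3x3 head convolution.
#' @param num_classes output classes (2: background, sugarcane).
#' @param input_size expected raster side lengths `(H, W)`.
#' @param decoder_dscse insert the D-scSE block after the feature
#'   concatenation?
#' @param norm_mean,norm_sd per-channel input normalisation constants.
#' @return a `model_spec` list.
#' @export
model_spec <- function(backbone = backbone_spec(),
                       pyramid = pyramid_spec(),
                       head_channels = 512,
                       num_classes = 2,
                       input_size = c(512, 512),
                       decoder_dscse = TRUE,
                       norm_mean = c(0.5, 0.5, 0.5),
                       norm_sd = c(0.25, 0.25, 0.25)) {
  list(backbone = backbone, pyramid = pyramid,
       head_channels = as.integer(head_channels),
       num_classes = as.integer(num_classes),
       input_size = as.integer(input_size),
       decoder_dscse = isTRUE(decoder_dscse),
       norm_mean = norm_mean, norm_sd = norm_sd)
}

#' Reduced model specification for desk-scale work
#'
#' Same family (residual stages with the dilation motif, D-scSE insertions,
#' pyramid decoder) shrunk to widths that train in minutes on one CPU:
#' 3x3/2 stem without max-pool (output stride 2), one block per stage,
#' (8, 16, 24, 32) channels, a 32-channel head, 64 px tiles.
#'
#' @param input_size tile side length used at this scale.
#' @return a `model_spec` list.
#' @export
reduced_model_spec <- function(input_size = c(64, 64)) {
  model_spec(
    backbone = backbone_spec(stage_block_counts = c(1, 1, 1, 1),
                             stage_channels = c(8, 16, 24, 32),
                             stage_strides = c(1, 1, 1, 1),
                             dilations = c(1, 1, 2, 2),
                             stem_channels = 8, stem_kernel = 3,
                             stem_stride = 2, stem_pool = FALSE),
    pyramid = pyramid_spec(),
    head_channels = 32,
    input_size = input_size)
}

#' Build a DSCA-PSPNet
#'
#' @param spec a [model_spec()].
#' @param seed integer seed fixing all weight initialisation.
#' @return an `nn_dsca_pspnet` module.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  backbone <- build_backbone(spec$backbone, seed = NULL)
  psp <- nn_pyramid_pool(backbone$out_channels, spec$pyramid)
  dec_dscse <- if (spec$decoder_dscse) dscse_block(psp$out_channels)
  head <- nn_sequential(list(
    nn_conv2d(psp$out_channels, spec$head_channels, 3L, padding = 1L,
              bias = FALSE),
    nn_batchnorm2d(spec$head_channels),
    nn_relu(),
    nn_conv2d(spec$head_channels, spec$num_classes, 1L, bias = TRUE)))
  up <- nn_upsample_bilinear(spec$input_size[1], spec$input_size[2])
  new_module("nn_dsca_pspnet", backbone = backbone, psp = psp,
             dec_dscse = dec_dscse, head = head, up = up, spec = spec)
}

#' @export
nn_forward.nn_dsca_pspnet <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (d[1] != m$spec$backbone$in_channels) {
    stop(sprintf("expected %d input channels, got %d",
                 m$spec$backbone$in_channels, d[1]))
  }
  h <- nn_forward(m$backbone, x, training)
  h <- nn_forward(m$psp, h, training)
  if (!is.null(m$dec_dscse)) h <- nn_forward(m$dec_dscse, h, training)
  h <- nn_forward(m$head, h, training)
  set_upsample_size(m$up, d[2], d[3])
  nn_forward(m$up, h, training)
}

#' @export
nn_backward.nn_dsca_pspnet <- function(m, dy) {
  dy <- nn_backward(m$up, dy)
  dy <- nn_backward(m$head, dy)
  if (!is.null(m$dec_dscse)) dy <- nn_backward(m$dec_dscse, dy)
  dy <- nn_backward(m$psp, dy)
  nn_backward(m$backbone, dy)
}

#' @export
nn_params.nn_dsca_pspnet <- function(m) {
  ps <- c(nn_params(m$backbone), nn_params(m$psp))
  if (!is.null(m$dec_dscse)) ps <- c(ps, nn_params(m$dec_dscse))
  c(ps, nn_params(m$head))
}

#' @export
nn_trace.nn_dsca_pspnet <- function(m, shape) {
  tb <- nn_trace(m$backbone, shape)
  tp <- nn_trace(m$psp, tb$shape)
  macs <- tb$macs + tp$macs
  extra <- tb$extra_flops + tp$extra_flops
  sh <- tp$shape
  if (!is.null(m$dec_dscse)) {
    td <- nn_trace(m$dec_dscse, sh)
    macs <- macs + td$macs; extra <- extra + td$extra_flops
  }
  th <- nn_trace(m$head, sh)
  list(shape = c(th$shape[1], shape[2], shape[3]),
       macs = macs + th$macs, extra_flops = extra + th$extra_flops)
}

#' Run the model on a batch of rasters
#'
#' Normalises per channel with the spec's constants and returns logits at
#' the input resolution.
#'
#' @param model an `nn_dsca_pspnet`.
#' @param x array `(3, H, W, N)` of pixel values in `[0, 1]`, or `(3, H, W)`
#'   for a single image.
#' @param training run in training mode (batch statistics, caches)?
#' @param normalize apply the spec's per-channel normalisation?
#' @return logits array `(num_classes, H, W, N)`.
#' @export
model_forward <- function(model, x, training = FALSE, normalize = TRUE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != model$spec$backbone$in_channels) {
    stop(sprintf("expected %d input channels, got %d",
                 model$spec$backbone$in_channels, dim(x)[1]))
  }
  if (normalize) {
    x <- (x - model$spec$norm_mean) / model$spec$norm_sd
  }
  nn_forward(model, x, training)
}

# ---------------------------------------------------------------------------
# State capture: every trainable parameter plus batch-norm running statistics,
# in deterministic traversal order.

nn_children <- function(m) UseMethod("nn_children")

#' @export
nn_children.default <- function(m) list()

#' @export
nn_children.nn_sequential <- function(m) m$mods

#' @export
nn_children.nn_basic_block <- function(m) {
  Filter(Negate(is.null), list(m$conv1, m$bn1, m$relu1, m$conv2, m$bn2,
                               m$down_conv, m$down_bn, m$relu_out))
}

#' @export
nn_children.nn_backbone <- function(m) {
  c(list(m$stem), m$stages, Filter(Negate(is.null), m$dscse))
}

#' @export
nn_children.nn_pyramid_pool <- function(m) {
  unlist(lapply(m$branches, function(br) list(br$pool, br$conv, br$bn,
                                              br$relu, br$up)),
         recursive = FALSE)
}

#' @export
nn_children.nn_dsca_pspnet <- function(m) {
  Filter(Negate(is.null), list(m$backbone, m$psp, m$dec_dscse, m$head, m$up))
}

flatten_modules <- function(m) {
  kids <- nn_children(m)
  c(list(m), unlist(lapply(kids, flatten_modules), recursive = FALSE))
}

#' Capture model state (weights + batch-norm running statistics)
#' @param model any module.
#' @return a serialisable list.
#' @export
model_state <- function(model) {
  mods <- flatten_modules(model)
  bns <- Filter(function(x) inherits(x, "nn_batchnorm2d"), mods)
  list(params = lapply(nn_params(model), function(p) p$value),
       bn = lapply(bns, function(b) list(mean = b$run_mean, var = b$run_var)))
}

#' Load captured state into a structurally identical model
#' @param model target module (built from the same spec).
#' @param state a [model_state()] list.
#' @return the model, invisibly.
#' @export
load_model_state <- function(model, state) {
  ps <- nn_params(model)
  if (length(ps) != length(state$params)) {
    stop("state does not match the model structure")
  }
  for (i in seq_along(ps)) ps[[i]]$value <- state$params[[i]]
  mods <- flatten_modules(model)
  bns <- Filter(function(x) inherits(x, "nn_batchnorm2d"), mods)
  if (length(bns) != length(state$bn)) stop("batch-norm count mismatch")
  for (i in seq_along(bns)) {
    bns[[i]]$run_mean <- state$bn[[i]]$mean
    bns[[i]]$run_var <- state$bn[[i]]$var
  }
  invisible(model)
}

#' Save a checkpoint
#'
#' Stores the model spec, full state, optional optimizer state and training
#' history; [load_checkpoint()] rebuilds the model so that eval-mode
#' forwards reproduce the pre-save outputs bit for bit.
#'
#' @param model an `nn_dsca_pspnet`.
#' @param path file to write (RDS).
#' @param optimizer optional [adamw()] optimizer whose state to include.
#' @param history optional training history data frame.
#' @param extra optional named list of additional metadata.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, optimizer = NULL, history = NULL,
                            extra = list()) {
  ck <- list(spec = model$spec, state = model_state(model),
             optimizer = if (!is.null(optimizer)) optimizer_state(optimizer),
             history = history, extra = extra,
             format_version = 1L)
  saveRDS(ck, path)
  invisible(path)
}

#' Load a checkpoint
#' @param path file written by [save_checkpoint()].
#' @return list with `model`, `history`, `optimizer`, `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$spec, seed = 0L)
  load_model_state(model, ck$state)
  list(model = model, history = ck$history, optimizer = ck$optimizer,
       extra = ck$extra)
}
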