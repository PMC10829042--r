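# Training-set augmentation: every augmented sample applies the full
# transform list simultaneously — rotation, horizontal/vertical flips,
# random scaling, brightness/contrast, Gaussian noise, Gaussian blur and
# HSV shifts — with independently drawn, seed-reproducible parameters.
# Geometric transforms hit image and mask identically (mask resampled
# nearest-neighbour); photometric transforms hit the image only.

#' Augmentation specification
#'
#' Parameter ranges are configuration, not contract: the pipeline's
#' guarantees are about counts, determinism and image/mask congruence.
#'
#' @param rotation_limit max |rotation| in degrees.
#' @param scale_range random-scaling factor range.
#' @param brightness_limit,contrast_limit additive / multiplicative photo
#'   limits on the `[0, 1]` scale.
#' @param noise_var Gaussian noise variance range on the 8-bit scale.
#' @param blur_kernels odd Gaussian-blur kernel sizes to draw from (mapped
#'   to sigma by the usual 0.3*((k-1)/2 - 1) + 0.8 rule).
#' @param hsv_shift max shifts of hue (degrees), saturation and value (8-bit
#'   counts).
#' @param copies_per_original augmented variants per original tile.
#' @param seed master augmentation seed.
#' @return an `aug_spec` list.
#' @export
aug_spec <- function(rotation_limit = 45, scale_range = c(0.9, 1.1),
                     brightness_limit = 0.2, contrast_limit = 0.2,
                     noise_var = c(10, 50), blur_kernels = c(3, 5, 7),
                     hsv_shift = c(20, 30, 20), copies_per_original = 5,
                     seed = 1L) {
  if (copies_per_original < 0) stop("copies_per_original must be >= 0")
  list(rotation_limit = rotation_limit, scale_range = scale_range,
       brightness_limit = brightness_limit, contrast_limit = contrast_limit,
       noise_var = noise_var, blur_kernels = blur_kernels,
       hsv_shift = hsv_shift,
       copies_per_original = as.integer(copies_per_original),
       seed = as.integer(seed))
}

#' Draw one set of augmentation parameters
#' @param spec an [aug_spec()].
#' @param seed integer seed fixing the draw.
#' @return named list of transform parameters.
#' @export
draw_aug_params <- function(spec, seed) {
  set.seed(seed)
  k <- spec$blur_kernels[sample.int(length(spec$blur_kernels), 1)]
  list(angle = stats::runif(1, -spec$rotation_limit, spec$rotation_limit),
       hflip = stats::runif(1) < 0.5,
       vflip = stats::runif(1) < 0.5,
       scale = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
       brightness = stats::runif(1, -spec$brightness_limit, spec$brightness_limit),
       contrast = stats::runif(1, -spec$contrast_limit, spec$contrast_limit),
       noise_sd = sqrt(stats::runif(1, spec$noise_var[1], spec$noise_var[2])) / 255,
       noise_seed = sample.int(.Machine$integer.max, 1),
       blur_sigma = 0.3 * ((k - 1) / 2 - 1) + 0.8,
       hue = stats::runif(1, -spec$hsv_shift[1], spec$hsv_shift[1]),
       sat = stats::runif(1, -spec$hsv_shift[2], spec$hsv_shift[2]) / 255,
       val = stats::runif(1, -spec$hsv_shift[3], spec$hsv_shift[3]) / 255)
}

reflect_pad <- function(x, pad) {
  ri <- c((pad + 1L):2L, seq_len(nrow(x)), (nrow(x) - 1L):(nrow(x) - pad))
  ci <- c((pad + 1L):2L, seq_len(ncol(x)), (ncol(x) - 1L):(ncol(x) - pad))
  if (length(dim(x)) == 3L) x[ri, ci, , drop = FALSE] else x[ri, ci]
}

zero_pad <- function(x, pad) {
  if (length(dim(x)) == 3L) {
    out <- array(0, dim(x) + c(2L * pad, 2L * pad, 0L))
    out[pad + seq_len(nrow(x)), pad + seq_len(ncol(x)), ] <- x
  } else {
    out <- matrix(0, nrow(x) + 2L * pad, ncol(x) + 2L * pad)
    out[pad + seq_len(nrow(x)), pad + seq_len(ncol(x))] <- x
  }
  out
}

# rotate about the centre then rescale on an already-padded square canvas;
# returns an array of the input size (centre-cropped or centre-zero-padded
# after the resize). EBImage does the resampling.
warp_raster <- function(x, angle, scale, bilinear = TRUE) {
  is_rgb <- length(dim(x)) == 3L
  Hp <- nrow(x)
  filt <- if (bilinear) "bilinear" else "none"
  eb <- EBImage::Image(if (is_rgb) aperm(x, c(2, 1, 3)) else t(x),
                       colormode = if (is_rgb) "Color" else "Grayscale")
  eb <- EBImage::rotate(eb, angle, filter = filt, output.dim = c(Hp, Hp),
                        bg.col = "black")
  side <- round(Hp * scale)
  if (side != Hp) eb <- EBImage::resize(eb, w = side, h = side, filter = filt)
  y <- EBImage::imageData(eb)
  y <- if (is_rgb) aperm(y, c(2, 1, 3)) else t(y)
  if (side >= Hp) {
    o <- (side - Hp) %/% 2L
    if (is_rgb) y[o + seq_len(Hp), o + seq_len(Hp), , drop = FALSE]
    else y[o + seq_len(Hp), o + seq_len(Hp)]
  } else {
    o <- (Hp - side) %/% 2L
    out <- if (is_rgb) array(0, c(Hp, Hp, dim(x)[3])) else matrix(0, Hp, Hp)
    if (is_rgb) out[o + seq_len(side), o + seq_len(side), ] <- y
    else out[o + seq_len(side), o + seq_len(side)] <- y
    out
  }
}

rgb_hsv_shift <- function(img, hue, sat, val) {
  d <- dim(img)
  m <- matrix(img, d[1] * d[2], 3L)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + hue / 360) %% 1
  hsv[2, ] <- pmin(pmax(hsv[2, ] + sat, 0), 1)
  hsv[3, ] <- pmin(pmax(hsv[3, ] + val, 0), 1)
  out <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255
  array(t(out), d)
}

#' Apply one augmentation draw to an image/mask pair
#'
#' Geometric order: flips, rotation (+ reflection-padded borders for the
#' image, zero borders for the mask), scaling, centre crop; photometric
#' order: brightness/contrast, Gaussian noise, Gaussian blur, HSV shift.
#' The mask is resampled nearest-neighbour and stays strictly binary.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask integer `H x W` matrix in \{0, 1\}.
#' @param params a [draw_aug_params()] list.
#' @return list with augmented `image` and `mask`.
#' @export
augment_pair <- function(image, mask, params) {
  if (params$hflip) { image <- image[, ncol(image):1, , drop = FALSE]
                      mask <- mask[, ncol(mask):1] }
  if (params$vflip) { image <- image[nrow(image):1, , , drop = FALSE]
                      mask <- mask[nrow(mask):1, ] }
  # the 0.3 pad keeps the kept crop inside real (reflected) content for any
  # rotation up to 45 degrees combined with a 0.9 downscale
  pad <- max(16L, ceiling(nrow(image) * 0.3))
  img_p <- reflect_pad(image, pad)
  msk_p <- zero_pad(mask, pad)
  img_w <- warp_raster(img_p, params$angle, params$scale, bilinear = TRUE)
  msk_w <- warp_raster(msk_p, params$angle, params$scale, bilinear = FALSE)
  H <- nrow(image); W <- ncol(image)
  image <- img_w[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
  mask <- matrix(as.integer(msk_w[pad + seq_len(H), pad + seq_len(W)] >= 0.5),
                 H, W)
  # photometric chain (image only)
  image <- image * (1 + params$contrast) + params$brightness
  set.seed(params$noise_seed)
  image <- image + stats::rnorm(length(image), 0, params$noise_sd)
  image <- pmin(pmax(image, 0), 1)
  eb <- EBImage::gblur(EBImage::Image(aperm(image, c(2, 1, 3)),
                                      colormode = "Color"),
                       sigma = params$blur_sigma)
  image <- aperm(EBImage::imageData(eb), c(2, 1, 3))
  image <- pmin(pmax(image, 0), 1)
  image <- rgb_hsv_shift(image, params$hue, params$sat, params$val)
  if (!all(mask %in% c(0L, 1L))) {
    stop("internal consistency error: mask not binary after augmentation")
  }
  list(image = image, mask = mask)
}

aug_record_seed <- function(spec, scene_id, row, col, copy) {
  derive_seed(spec$seed, sprintf("aug-%s-r%d-c%d-k%d", scene_id, row, col, copy))
}

#' Expand the training split with augmented records
#'
#' Returns the original training records plus `copies_per_original`
#' augmented variants per original. Augmented records are lazy: each carries
#' a derived seed that fully determines its raster; [materialize_augmented()]
#' (or train-time loading) renders them. Validation and test tiles are never
#' augmented.
#'
#' @param manifest tile manifest with split labels.
#' @param spec an [aug_spec()].
#' @param out_dir directory augmented rasters will live in (paths are
#'   planned here; files appear on materialisation).
#' @param write materialise all augmented rasters now (the eager CLI path)?
#' @return manifest of the training set: originals plus augmented records.
#' @export
augment_training_set <- function(manifest, spec = aug_spec(),
                                 out_dir = dirname(manifest$image_path[1]),
                                 write = FALSE) {
  train <- manifest[manifest$split == "train" & manifest$aug_index == 0L, ]
  if (spec$copies_per_original == 0L) return(train)
  out <- vector("list", nrow(train) * spec$copies_per_original)
  k <- 0L
  for (i in seq_len(nrow(train))) {
    r <- train[i, ]
    for (copy in seq_len(spec$copies_per_original)) {
      k <- k + 1L
      rec <- r
      rec$aug_index <- copy
      rec$image_path <- file.path(out_dir,
        sprintf("%s_r%02d_c%02d_aug%d_image.png", r$scene_id, r$row, r$col, copy))
      rec$mask_path <- file.path(out_dir,
        sprintf("%s_r%02d_c%02d_aug%d_mask.png", r$scene_id, r$row, r$col, copy))
      out[[k]] <- rec
    }
  }
  aug <- do.call(rbind, out)
  combined <- rbind(train, aug)
  rownames(combined) <- NULL
  if (write) materialize_augmented(combined, manifest, spec)
  combined
}

#' Materialise augmented rasters
#'
#' Renders (a subset of) the augmented records produced by
#' [augment_training_set()] to disk; bit-identical across runs for the same
#' spec seed.
#'
#' @param aug_manifest manifest containing augmented records.
#' @param source_manifest manifest with the original tiles (aug_index 0).
#' @param spec the [aug_spec()] used to create the records.
#' @param rows which rows of `aug_manifest` to render (default: all
#'   augmented ones).
#' @return the rendered rows, invisibly.
#' @export
materialize_augmented <- function(aug_manifest, source_manifest, spec,
                                  rows = which(aug_manifest$aug_index > 0L)) {
  src <- source_manifest[source_manifest$aug_index == 0L, ]
  key <- function(m) paste(m$scene_id, m$row, m$col)
  src_idx <- stats::setNames(seq_len(nrow(src)), key(src))
  for (i in rows) {
    rec <- aug_manifest[i, ]
    if (rec$aug_index == 0L) next
    s <- src[src_idx[[paste(rec$scene_id, rec$row, rec$col)]], ]
    img <- read_image(s$image_path)
    msk <- read_mask(s$mask_path)
    pars <- draw_aug_params(spec, aug_record_seed(spec, rec$scene_id,
                                                  rec$row, rec$col,
                                                  rec$aug_index))
    a <- augment_pair(img, msk, pars)
    write_image(a$image, rec$image_path)
    write_mask(a$mask, rec$mask_path)
  }
  invisible(aug_manifest[rows, ])
}

#' Load the raster pair behind a manifest record
#'
#' Originals are read from disk; lazy augmented records are rendered from
#' their source tile and derived seed (and read from disk when already
#' materialised).
#'
#' @param rec one manifest row.
#' @param source_manifest manifest holding the original tiles.
#' @param spec the [aug_spec()] (needed for augmented records).
#' @return list with `image` and `mask`.
#' @export
load_tile <- function(rec, source_manifest = NULL, spec = NULL) {
  if (rec$aug_index == 0L || file.exists(rec$image_path)) {
    return(list(image = read_image(rec$image_path),
                mask = read_mask(rec$mask_path)))
  }
  if (is.null(source_manifest) || is.null(spec)) {
    stop("augmented record not materialised; need source manifest and aug spec")
  }
  src <- source_manifest[source_manifest$aug_index == 0L &
                         source_manifest$scene_id == rec$scene_id &
                         source_manifest$row == rec$row &
                         source_manifest$col == rec$col, ]
  img <- read_image(src$image_path[1])
  msk <- read_mask(src$mask_path[1])
  pars <- draw_aug_params(spec, aug_record_seed(spec, rec$scene_id, rec$row,
                                                rec$col, rec$aug_index))
  augment_pair(img, msk, pars)
}
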