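# Raster I/O: 8-bit RGB images (PNG or TIFF) and single-channel binary masks
# (PNG, {0, 255} on disk, {0, 1} in memory). Arrays are H x W x 3 (images)
# or H x W (masks) with values in [0, 1] / {0, 1}.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported raster format '%s' (use png or tiff)", ext))
}

#' Read an RGB raster
#' @param path PNG or TIFF file.
#' @return numeric `H x W x 3` array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster not found: %s", path))
  x <- switch(img_format(path),
              png = png::readPNG(path),
              tiff = tiff::readTIFF(path))
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x
}

#' Write an RGB raster
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path output file; the extension selects PNG or TIFF.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  switch(img_format(path),
         png = png::writePNG(image, path),
         tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L))
  invisible(path)
}

#' Read a binary mask
#' @param path single-channel PNG/TIFF with on-disk values \{0, 255\}.
#' @return integer `H x W` matrix with values \{0, 1\}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask not found: %s", path))
  x <- switch(img_format(path),
              png = png::readPNG(path),
              tiff = tiff::readTIFF(path))
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(x >= 0.5), nrow(x), ncol(x))
  m
}

#' Write a binary mask
#' @param mask integer/logical `H x W` matrix in \{0, 1\}.
#' @param path output file (values stored as \{0, 255\}).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  v <- as.numeric(mask)
  if (!all(v %in% c(0, 1))) stop("mask values must be in {0, 1}")
  m <- matrix(v, nrow(mask), ncol(mask))
  switch(img_format(path),
         png = png::writePNG(m, path),
         tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L))
  invisible(path)
}

# raster (H, W, 3) <-> network tensor (3, H, W)
raster_to_tensor <- function(image) aperm(image, c(3, 1, 2))
tensor_to_raster <- function(x) aperm(x, c(2, 3, 1))
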