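# Shared fixtures: tiny tile corpora written to the test temp dir, and a
# micro model spec small enough for gradient-level assertions.

micro_model_spec <- function(input_size = c(16, 16)) {
  model_spec(
    backbone = backbone_spec(stage_block_counts = c(1, 1, 1, 1),
                             stage_channels = c(4, 4, 8, 8),
                             stage_strides = c(1, 1, 1, 1),
                             dilations = c(1, 1, 2, 2),
                             stem_channels = 4, stem_kernel = 3,
                             stem_stride = 1, stem_pool = FALSE),
    pyramid = pyramid_spec(),
    head_channels = 8,
    input_size = input_size)
}

# writes n_tiles tile rasters cut from one synthetic scene and returns a
# manifest with every tile in the requested split
make_tile_corpus <- function(dir, n_tiles = 8, tile = 64, split = "train",
                             seed = 11, min_frac = 0.2, max_frac = 0.8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- generate_scene(scene_spec(size = c(512, 512), seed = seed))
  tiles <- tile_scene(sc$image, sc$mask, tile)
  fr <- vapply(tiles, function(t) mean(t$mask), numeric(1))
  sel <- which(fr > min_frac & fr < max_frac)
  stopifnot(length(sel) >= n_tiles)
  sel <- sel[seq_len(n_tiles)]
  rows <- vector("list", n_tiles)
  for (i in seq_along(sel)) {
    t <- tiles[[sel[i]]]
    ip <- file.path(dir, sprintf("t%02d_image.png", i))
    mp <- file.path(dir, sprintf("t%02d_mask.png", i))
    write_image(t$image, ip)
    write_mask(t$mask, mp)
    rows[[i]] <- data.frame(scene_id = "s1", row = t$row, col = t$col,
                            split = split, aug_index = 0L,
                            image_path = ip, mask_path = mp,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
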