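# Scene -> tile pipeline: non-overlapping 512 x 512 grids, per-scene
# 70/15/15 allocation by largest remainder with a global correction pass,
# and manifest bookkeeping. Coordinates are 0-based, row-major, half-open
# pixel boxes [r*tile, (r+1)*tile).

#' Tile a scene into non-overlapping square tiles
#'
#' @param image `H x W x 3` array.
#' @param mask integer `H x W` matrix in \{0, 1\} (optional).
#' @param tile_size tile side length (default 512).
#' @return list of tile records, row-major; each has `row`, `col` (0-based),
#'   `image` and `mask`.
#' @export
tile_scene <- function(image, mask = NULL, tile_size = 512) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (H %% tile_size != 0L || W %% tile_size != 0L) {
    stop(sprintf("scene %dx%d is not divisible by tile size %d (no partial tiles)",
                 H, W, tile_size))
  }
  if (!is.null(mask) && !identical(dim(mask), c(H, W))) {
    stop("mask dimensions must match the image")
  }
  nr <- H %/% tile_size
  nc <- W %/% tile_size
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (r in 0:(nr - 1L)) {
    for (cc in 0:(nc - 1L)) {
      k <- k + 1L
      ri <- r * tile_size + seq_len(tile_size)
      ci <- cc * tile_size + seq_len(tile_size)
      tiles[[k]] <- list(row = r, col = cc,
                         image = image[ri, ci, , drop = FALSE],
                         mask = if (!is.null(mask)) mask[ri, ci])
    }
  }
  tiles
}

#' Reassemble tiles into the source scene
#'
#' Inverse of [tile_scene()]; the round trip is bit-exact.
#'
#' @param tiles list returned by [tile_scene()].
#' @param tile_size tile side length.
#' @return list with `image` and (if present) `mask`.
#' @export
stitch_tiles <- function(tiles, tile_size = 512) {
  nr <- max(vapply(tiles, `[[`, 0L, "row")) + 1L
  nc <- max(vapply(tiles, `[[`, 0L, "col")) + 1L
  image <- array(0, c(nr * tile_size, nc * tile_size, dim(tiles[[1]]$image)[3]))
  mask <- if (!is.null(tiles[[1]]$mask)) matrix(0L, nr * tile_size, nc * tile_size)
  for (t in tiles) {
    ri <- t$row * tile_size + seq_len(tile_size)
    ci <- t$col * tile_size + seq_len(tile_size)
    image[ri, ci, ] <- t$image
    if (!is.null(mask)) mask[ri, ci] <- t$mask
  }
  list(image = image, mask = mask)
}

#' Tile every scene of a corpus to disk
#'
#' @param corpus data frame from [generate_corpus()] (columns `scene_id`,
#'   `image_path`, `mask_path`), or a directory containing `corpus.csv`.
#' @param out_dir directory for the tile rasters and manifest.
#' @param tile_size tile side length.
#' @return tile manifest data frame with columns `scene_id`, `row`, `col`,
#'   `split` (`NA` until allocated), `aug_index` (0 = original), `image_path`,
#'   `mask_path`.
#' @export
tile_corpus <- function(corpus, out_dir, tile_size = 512) {
  if (is.character(corpus)) {
    corpus <- utils::read.csv(file.path(corpus, "corpus.csv"),
                              stringsAsFactors = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    img <- read_image(corpus$image_path[i])
    msk <- read_mask(corpus$mask_path[i])
    tiles <- tile_scene(img, msk, tile_size)
    sid <- corpus$scene_id[i]
    recs <- vector("list", length(tiles))
    for (k in seq_along(tiles)) {
      t <- tiles[[k]]
      ip <- file.path(out_dir, sprintf("%s_r%02d_c%02d_image.png", sid, t$row, t$col))
      mp <- file.path(out_dir, sprintf("%s_r%02d_c%02d_mask.png", sid, t$row, t$col))
      write_image(t$image, ip)
      write_mask(t$mask, mp)
      recs[[k]] <- data.frame(scene_id = sid, row = t$row, col = t$col,
                              split = NA_character_, aug_index = 0L,
                              image_path = ip, mask_path = mp,
                              stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, recs)
    rm(img, msk, tiles); gc(verbose = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "tiles.csv"))
  manifest
}

#' Write / read a tile manifest
#' @param manifest manifest data frame.
#' @param path CSV path.
#' @return the path / the manifest.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

largest_remainder <- function(n, fractions) {
  q <- fractions * n
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    # ties broken by split order: train before val before test
    ord <- order(-(q - base), seq_along(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Allocate tiles to train/validation/test splits
#'
#' Per scene, target counts are `fraction x tiles`, rounded by largest
#' remainder with ties broken train > val > test. Because 70% of 64 is not
#' an integer, per-scene rounding overshoots globally; a deterministic
#' correction pass (scene order seeded) then moves single tiles between
#' scenes until the global totals equal `round(fraction x total)`.
#'
#' @param tiles_per_scene integer vector: tile count of each scene.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed for the correction pass.
#' @return a `split_plan` list: `per_scene` (matrix scenes x 3), `totals`,
#'   `fractions`, `tiles_per_scene`.
#' @export
allocate_split <- function(tiles_per_scene, fractions = c(0.7, 0.15, 0.15),
                           seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (length(fractions) != 3L) stop("need three fractions (train, val, test)")
  ns <- length(tiles_per_scene)
  per <- t(vapply(tiles_per_scene, largest_remainder, integer(3),
                  fractions = fractions))
  colnames(per) <- c("train", "val", "test")
  total <- sum(tiles_per_scene)
  target <- largest_remainder(total, fractions)
  # global correction: move single tiles between splits, one move per scene
  # per sweep, visiting scenes in a seeded order
  set.seed(seed)
  sweep_order <- sample(ns)
  guard <- 0L
  while (any(colSums(per) != target) && guard < 100L) {
    guard <- guard + 1L
    diffs <- colSums(per) - target
    for (sc in sweep_order) {
      diffs <- colSums(per) - target
      if (all(diffs == 0L)) break
      over <- which(diffs > 0L & per[sc, ] > 0L)
      under <- which(diffs < 0L)
      if (length(over) == 0L || length(under) == 0L) next
      o <- over[which.max(diffs[over])]
      u <- under[which.min(diffs[under])]
      per[sc, o] <- per[sc, o] - 1L
      per[sc, u] <- per[sc, u] + 1L
    }
  }
  if (any(colSums(per) != target)) {
    stop("split correction did not converge; check fractions and tile counts")
  }
  structure(list(per_scene = per, totals = colSums(per),
                 fractions = fractions,
                 tiles_per_scene = as.integer(tiles_per_scene)),
            class = "split_plan")
}

#' Assign split labels to a tile manifest
#'
#' Applies an [allocate_split()] plan: within each scene the tiles are
#' shuffled with a seed derived from the master seed and the scene id, then
#' assigned to train/val/test in the plan's counts.
#'
#' @param manifest tile manifest (original tiles, `aug_index == 0`).
#' @param fractions split fractions (train, val, test).
#' @param seed master seed.
#' @return list with the updated `manifest` and the `plan`.
#' @export
split_manifest <- function(manifest, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(all(manifest$aug_index == 0L))
  scenes <- unique(manifest$scene_id)
  counts <- vapply(scenes, function(s) sum(manifest$scene_id == s), integer(1))
  plan <- allocate_split(counts, fractions, seed = derive_seed(seed, "split-correction"))
  for (i in seq_along(scenes)) {
    idx <- which(manifest$scene_id == scenes[i])
    set.seed(derive_seed(seed, paste0("split-", scenes[i])))
    idx <- idx[sample(length(idx))]
    n <- plan$per_scene[i, ]
    lab <- rep(c("train", "val", "test"), times = n)
    manifest$split[idx] <- lab
  }
  list(manifest = manifest, plan = plan)
}
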