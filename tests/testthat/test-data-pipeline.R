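test_that("tiling produces the row-major grid and is exactly invertible", {
  sc <- generate_scene(scene_spec(size = c(1024, 1536), seed = 2,
                                  foreground_fraction_range = c(0.2, 0.4)))
  tiles <- tile_scene(sc$image, sc$mask, 512)
  expect_length(tiles, 6L)
  expect_equal(max(vapply(tiles, `[[`, 0L, "row")) + 1L, 2L)
  expect_equal(max(vapply(tiles, `[[`, 0L, "col")) + 1L, 3L)
  st <- stitch_tiles(tiles, 512)
  expect_identical(st$image, sc$image)
  expect_identical(st$mask, sc$mask)

  one <- tile_scene(sc$image[1:512, 1:512, , drop = FALSE],
                    sc$mask[1:512, 1:512], 512)
  expect_length(one, 1L)
  expect_identical(one[[1]]$image, sc$image[1:512, 1:512, , drop = FALSE])
  expect_error(tile_scene(sc$image[1:700, 1:512, , drop = FALSE],
                          sc$mask[1:700, 1:512], 512), "not divisible")
})

test_that("largest-remainder split allocation reproduces the study counts", {
  p1 <- allocate_split(64)
  expect_equal(unname(p1$per_scene[1, ]), c(45L, 10L, 9L))

  p20 <- allocate_split(rep(64, 20))
  expect_equal(unname(p20$totals), c(896L, 192L, 192L))
  expect_true(all(rowSums(p20$per_scene) == 64L))

  expect_equal(unname(allocate_split(rep(10, 3), fractions = c(1, 0, 0))$totals),
               c(30L, 0L, 0L))
  expect_error(allocate_split(64, fractions = c(0.5, 0.2, 0.2)), "sum to 1")

  # same seed: identical plan; different seed: identical totals
  a <- allocate_split(rep(64, 20), seed = 7)
  b <- allocate_split(rep(64, 20), seed = 7)
  c3 <- allocate_split(rep(64, 20), seed = 8)
  expect_identical(a, b)
  expect_equal(unname(c3$totals), unname(a$totals))
})

test_that("split assignment conserves tiles and never mixes splits", {
  dir <- file.path(tempdir(), "split-corpus")
  man <- rbind(make_tile_corpus(dir, n_tiles = 10, tile = 64, split = NA,
                                seed = 3, min_frac = 0, max_frac = 1),
               within(make_tile_corpus(dir, n_tiles = 10, tile = 64,
                                       split = NA, seed = 4,
                                       min_frac = 0, max_frac = 1),
                      scene_id <- "s2"))
  sp <- split_manifest(man, seed = 5)
  m <- sp$manifest
  expect_false(any(is.na(m$split)))
  expect_equal(nrow(m), 20L)
  expect_equal(sum(table(m$split)), 20L)
  for (i in 1:2) {
    sid <- c("s1", "s2")[i]
    cnt <- table(factor(m$split[m$scene_id == sid],
                        levels = c("train", "val", "test")))
    expect_equal(as.integer(cnt), unname(sp$plan$per_scene[i, ]))
  }
  sp2 <- split_manifest(man, seed = 5)
  expect_identical(sp$manifest, sp2$manifest)
})

test_that("augmentation expands only the training split, deterministically", {
  dir <- file.path(tempdir(), "aug-corpus")
  man <- make_tile_corpus(dir, n_tiles = 4, tile = 64, split = "train", seed = 6)
  man$split[4] <- "val"
  spec <- aug_spec(copies_per_original = 5, seed = 9)
  aug <- augment_training_set(man, spec, out_dir = dir)
  expect_equal(nrow(aug), 3L * 6L)           # originals + 5 copies each
  expect_equal(sum(aug$aug_index == 0L), 3L)
  expect_equal(sum(aug$aug_index > 0L), 15L)
  expect_true(all(aug$split == "train"))

  none <- augment_training_set(man, aug_spec(copies_per_original = 0, seed = 9))
  expect_identical(none, man[man$split == "train" & man$aug_index == 0L, ])

  # bit-identical rasters across two materialisation runs
  r1 <- materialize_augmented(aug, man, spec, rows = which(aug$aug_index == 1L)[1])
  img1 <- read_image(r1$image_path[1]); msk1 <- read_mask(r1$mask_path[1])
  file.remove(r1$image_path[1], r1$mask_path[1])
  r2 <- materialize_augmented(aug, man, spec, rows = which(aug$aug_index == 1L)[1])
  expect_identical(read_image(r2$image_path[1]), img1)
  expect_identical(read_mask(r2$mask_path[1]), msk1)
  expect_true(all(msk1 %in% c(0L, 1L)))
})

test_that("geometric transforms keep image and mask congruent", {
  dir <- file.path(tempdir(), "cong-corpus")
  man <- make_tile_corpus(dir, n_tiles = 1, tile = 64, seed = 8)
  img <- read_image(man$image_path[1]); msk <- read_mask(man$mask_path[1])
  # flips alone preserve the foreground pixel count exactly
  p <- draw_aug_params(aug_spec(rotation_limit = 0, scale_range = c(1, 1),
                                seed = 2), seed = 31)
  stopifnot(p$hflip || p$vflip || TRUE)
  a <- augment_pair(img, msk, p)
  expect_equal(sum(a$mask), sum(msk))
  expect_true(all(a$mask %in% c(0L, 1L)))
  # a 90-degree rotation (no scaling) also preserves the count
  p90 <- p; p90$angle <- 90; p90$hflip <- FALSE; p90$vflip <- FALSE
  a90 <- augment_pair(img, msk, p90)
  expect_equal(sum(a90$mask), sum(msk))
})
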