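# Synthetic satellite-like scenes: textured polygonal crop fields (striped,
# row-crop look) over a heterogeneous background with non-field distractors
# (a river ribbon, bright building blocks), plus a congruent binary mask.
# Everything is seeded, so scenes are byte-reproducible.

#' Scene specification
#'
#' @param size scene side lengths `(H, W)`; 4096 at corpus scale, 512 for
#'   quick work.
#' @param n_fields nominal number of crop-field polygons placed before the
#'   coverage top-up; `0` produces an all-background scene with an empty
#'   mask.
#' @param field_period stripe period range in pixels (row-crop texture).
#' @param field_amp stripe contrast amplitude.
#' @param field_noise_sd per-pixel texture noise standard deviation.
#' @param field_radius radius range of field polygons, as a fraction of the
#'   scene side.
#' @param foreground_fraction_range target interval for the mask coverage;
#'   fields are added until the drawn target inside this interval is
#'   reached.
#' @param style scene class: `"farmland"`, `"river"` (adds a water ribbon)
#'   or `"resident"` (adds bright building blocks).
#' @param seed integer seed; fixes the scene exactly.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(size = c(4096, 4096), n_fields = 12,
                       field_period = c(8, 24), field_amp = 0.18,
                       field_noise_sd = 0.03,
                       field_radius = c(0.06, 0.13),
                       foreground_fraction_range = c(0.3, 0.5),
                       style = c("farmland", "river", "resident"),
                       seed = 1L) {
  style <- match.arg(style)
  list(size = as.integer(size), n_fields = as.integer(n_fields),
       field_period = field_period, field_amp = field_amp,
       field_noise_sd = field_noise_sd, field_radius = field_radius,
       foreground_fraction_range = foreground_fraction_range,
       style = style, seed = as.integer(seed))
}

# convex polygon from the hull of random points in a jittered disc
random_convex_polygon <- function(cx, cy, radius) {
  n <- 12L
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- radius * stats::runif(n, 0.55, 1)
  px <- cx + r * cos(ang)
  py <- cy + r * sin(ang)
  h <- grDevices::chull(px, py)
  list(x = px[h], y = py[h])
}

# even-odd scanline rasterisation of a polygon onto the pixel grid,
# restricted to its bounding box; returns row/col index ranges and the
# inside matrix. A convex polygon crosses each scan row exactly twice, so
# the fill is one run per row.
rasterize_polygon <- function(px, py, H, W) {
  r0 <- max(1L, floor(min(py))); r1 <- min(H, ceiling(max(py)))
  c0 <- max(1L, floor(min(px))); c1 <- min(W, ceiling(max(px)))
  if (r0 > r1 || c0 > c1) return(NULL)
  ys <- r0:r1
  xs <- c0:c1
  nr <- length(ys); nc <- length(xs)
  lo <- rep(Inf, nr); hi <- rep(-Inf, nr)
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    y1 <- py[j]; y2 <- py[i]; x1 <- px[j]; x2 <- px[i]
    j <- i
    cross <- (y1 <= ys) != (y2 <= ys)
    if (any(cross)) {
      xi <- x1 + (ys[cross] - y1) * (x2 - x1) / (y2 - y1)
      lo[cross] <- pmin(lo[cross], xi)
      hi[cross] <- pmax(hi[cross], xi)
    }
  }
  # clamp runs to the bounding box and mark them
  inside <- matrix(FALSE, nr, nc)
  from <- pmax(ceiling(lo), c0)
  to <- pmin(floor(hi), c1)
  rows_with <- which(from <= to)
  if (length(rows_with)) {
    lens <- to[rows_with] - from[rows_with] + 1L
    ridx <- rep.int(rows_with, lens)
    cidx <- unlist(lapply(seq_along(rows_with), function(k) {
      seq.int(from[rows_with[k]], to[rows_with[k]])
    })) - c0 + 1L
    inside[cbind(ridx, cidx)] <- TRUE
  }
  list(rows = ys, cols = xs, inside = inside)
}

smooth_noise_layer <- function(H, W, coarse = 24L, lo = -1, hi = 1) {
  g <- matrix(stats::runif(coarse * coarse, lo, hi), coarse, coarse)
  Lh <- interp_matrix(coarse, H)
  Lw <- interp_matrix(coarse, W)
  Lh %*% g %*% t(Lw)
}

#' Generate one synthetic scene
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`H x W x 3` in `[0, 1]`), `mask`
#'   (integer `H x W` in \{0, 1\}), `fields` (polygon list) and
#'   `foreground_fraction`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  set.seed(spec$seed)
  H <- spec$size[1]; W <- spec$size[2]
  # heterogeneous earth-tone background: one low-frequency relief layer with
  # per-channel weights, plus one shared fine-grain noise layer
  base <- c(0.42, 0.40, 0.30)
  relief_w <- c(0.10, 0.09, 0.07)
  grain <- stats::rnorm(H * W, 0, 0.015)
  relief <- smooth_noise_layer(H, W)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + relief_w[ch] * relief + grain
  }
  rm(grain, relief)
  if (spec$style == "river") {
    # sinuous water ribbon crossing the scene left to right (run fill per
    # column)
    xs <- seq_len(W)
    centre <- H * (0.35 + 0.3 * stats::runif(1)) +
      H * 0.08 * sin(2 * pi * xs / W * stats::runif(1, 1, 2.5) +
                     stats::runif(1, 0, 2 * pi))
    width <- H * stats::runif(1, 0.015, 0.04)
    from <- pmax(1L, ceiling(centre - width))
    to <- pmin(H, floor(centre + width))
    keep <- which(from <= to)
    lens <- to[keep] - from[keep] + 1L
    ridx <- unlist(lapply(seq_along(keep), function(k) {
      seq.int(from[keep[k]], to[keep[k]])
    }))
    cidx <- rep.int(keep, lens)
    water <- c(0.18, 0.28, 0.38)
    for (ch in 1:3) img[cbind(ridx, cidx, ch)] <- water[ch]
  }
  if (spec$style == "resident") {
    for (b in seq_len(8L)) {
      bh <- sample(round(H * 0.01):round(H * 0.03), 1)
      bw <- sample(round(W * 0.01):round(W * 0.03), 1)
      r0 <- sample(seq_len(H - bh), 1); c0 <- sample(seq_len(W - bw), 1)
      shade <- stats::runif(1, 0.75, 0.95)
      img[r0:(r0 + bh), c0:(c0 + bw), ] <- shade
    }
  }
  mask <- matrix(0L, H, W)
  fields <- list()
  covered <- 0
  if (spec$n_fields > 0L) {
    lo <- spec$foreground_fraction_range[1]
    hi <- spec$foreground_fraction_range[2]
    target <- stats::runif(1, lo, hi)
    attempts <- 0L
    while ((length(fields) < spec$n_fields || covered / (H * W) < target) &&
           attempts < 400L) {
      attempts <- attempts + 1L
      rad <- stats::runif(1, spec$field_radius[1], spec$field_radius[2]) *
        min(H, W)
      cx <- stats::runif(1, rad, W - rad)
      cy <- stats::runif(1, rad, H - rad)
      poly <- random_convex_polygon(cx, cy, rad)
      ras <- rasterize_polygon(poly$x, poly$y, H, W)
      if (is.null(ras)) next
      # striped row-crop texture
      period <- stats::runif(1, spec$field_period[1], spec$field_period[2])
      theta <- stats::runif(1, 0, pi)
      base_rgb <- c(stats::runif(1, 0.25, 0.45), stats::runif(1, 0.45, 0.65),
                    stats::runif(1, 0.15, 0.30))
      gr <- outer(ras$rows, ras$cols, function(r, cc) {
        sin(2 * pi * (cos(theta) * cc + sin(theta) * r) / period)
      })
      stripe <- 0.5 + 0.5 * tanh(4 * gr)
      idx <- ras$inside
      tex_noise <- stats::rnorm(length(stripe), 0, spec$field_noise_sd)
      for (ch in 1:3) {
        layer <- img[ras$rows, ras$cols, ch]
        tex <- base_rgb[ch] * (1 - spec$field_amp + 2 * spec$field_amp * stripe) +
          tex_noise
        layer[idx] <- tex[idx]
        img[ras$rows, ras$cols, ch] <- layer
      }
      sub <- mask[ras$rows, ras$cols]
      covered <- covered + sum(idx & sub == 0L)
      sub[idx] <- 1L
      mask[ras$rows, ras$cols] <- sub
      fields[[length(fields) + 1L]] <- poly
      if (length(fields) >= spec$n_fields && covered / (H * W) >= target) break
    }
    if (covered / (H * W) < lo - 0.05) {
      stop(sprintf("coverage %.3f below the feasible range after %d attempts",
                   covered / (H * W), attempts))
    }
  }
  # clip and quantise to the 8-bit grid so in-memory values match the PNG
  # round trip
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  list(image = img, mask = mask, fields = fields,
       foreground_fraction = mean(mask))
}

#' Generate a seeded scene corpus
#'
#' Writes `n_scenes` scenes (image + mask PNGs) cycling through the
#' river / resident / farmland styles, together with a corpus manifest.
#'
#' @param out_dir output directory (created if missing).
#' @param n_scenes number of scenes (20 at study scale).
#' @param template a [scene_spec()] supplying everything but style and seed.
#' @param seed master seed; per-scene seeds are derived from it.
#' @return data frame with columns `scene_id`, `style`, `image_path`,
#'   `mask_path`, `foreground_fraction`.
#' @export
generate_corpus <- function(out_dir, n_scenes = 20, template = scene_spec(),
                            seed = 1L) {
  if (n_scenes < 1L) stop("`n_scenes` must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need_bytes <- as.numeric(n_scenes) * prod(template$size) * 3.2
  check_disk_space(out_dir, need_bytes)
  styles <- rep(c("river", "resident", "farmland"), length.out = n_scenes)
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- template
    sp$style <- styles[i]
    sp$seed <- derive_seed(seed, sprintf("scene-%03d", i))
    sc <- generate_scene(sp)
    sid <- sprintf("scene_%03d", i)
    ip <- file.path(out_dir, paste0(sid, "_image.png"))
    mp <- file.path(out_dir, paste0(sid, "_mask.png"))
    write_image(sc$image, ip)
    write_mask(sc$mask, mp)
    rows[[i]] <- data.frame(scene_id = sid, style = styles[i],
                            image_path = ip, mask_path = mp,
                            foreground_fraction = sc$foreground_fraction,
                            stringsAsFactors = FALSE)
    rm(sc); gc(verbose = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "corpus.csv"),
                   row.names = FALSE)
  manifest
}

check_disk_space <- function(dir, need_bytes) {
  # best effort: df may be unavailable on some systems
  free <- tryCatch({
    out <- system2("df", c("-kP", shQuote(dir)), stdout = TRUE, stderr = FALSE)
    as.numeric(strsplit(trimws(out[2]), "\\s+")[[1]][4]) * 1024
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  if (is.finite(free) && free < need_bytes) {
    stop(sprintf("not enough disk space in %s: need ~%.0f MB, have %.0f MB",
                 dir, need_bytes / 2^20, free / 2^20))
  }
  invisible(TRUE)
}
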