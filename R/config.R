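# Run configuration: one nested YAML config mirrors the module options; a
# single global seed feeds stable per-module derived seeds so every stage is
# independently reproducible. Unknown keys are rejected by name.

#' Derive a per-module seed from the global seed
#'
#' Stable string hash folded with the global seed, kept inside the 32-bit
#' integer range.
#'
#' @param seed global integer seed.
#' @param label module/stage label.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629 + 1)
}

#' Default run configuration
#'
#' The `data` section pins the study-scale regime: 20 scenes of 4096 px,
#' 512 px tiles, 70/15/15 per-scene allocation, 5 augmented copies per
#' training original.
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "dsca_run",
    data = list(scenes = 20L, scene_size = 4096L, tile_size = 512L,
                fractions = c(0.7, 0.15, 0.15), copies_per_original = 5L,
                materialize_augmented = TRUE,
                foreground_fraction_range = c(0.3, 0.5), n_fields = 12L),
    model = list(preset = "full", head_channels = 512L, input_size = 512L,
                 dscse = TRUE),
    train = list(epochs = 100L, batch_size = 16L, base_lr = 1e-4,
                 max_lr = 1e-3, weight_decay = 1e-2, cycle_epochs = 10L,
                 max_steps = NULL),
    eval = list(split = "test", checkpoint = NULL),
    predict = list(checkpoint = NULL, image = NULL, out = NULL),
    profile = list(input_size = 512L, measure_time = FALSE)
  )
}

config_error <- function(msg) {
  stop(structure(class = c("dsca_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

check_known_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(ref)) {
      config_error(sprintf("unknown configuration key: '%s'", full))
    }
    if (is.list(cfg[[nm]]) && is.list(ref[[nm]]) &&
        !is.null(names(ref[[nm]]))) {
      check_known_keys(cfg[[nm]], ref[[nm]], full)
    }
  }
  invisible(TRUE)
}

deep_merge <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(base[[nm]]) && is.list(upd[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' @param path YAML file (or `NULL` for pure defaults).
#' @param overrides character vector of `section.key=value` overrides.
#' @return resolved configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = character()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    check_known_keys(user, cfg)
    cfg <- deep_merge(cfg, user)
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) config_error(sprintf("bad override '%s'", ov))
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    ref <- cfg
    for (k in keys[-length(keys)]) {
      if (!k %in% names(ref)) config_error(sprintf("unknown configuration key: '%s'", kv[1]))
      ref <- ref[[k]]
    }
    leaf <- keys[length(keys)]
    if (!leaf %in% names(ref)) config_error(sprintf("unknown configuration key: '%s'", kv[1]))
    val <- if (grepl(",", kv[2], fixed = TRUE)) {
      utils::type.convert(strsplit(kv[2], ",", fixed = TRUE)[[1]], as.is = TRUE)
    } else {
      utils::type.convert(kv[2], as.is = TRUE)
    }
    cfg[[keys]] <- val
  }
  cfg
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483629
  sprintf("%08x", h)
}

write_resolved_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(dir, "config_used.yaml"))
  invisible(cfg)
}

build_model_from_config <- function(mcfg, seed) {
  if (identical(mcfg$preset, "reduced")) {
    sp <- reduced_model_spec(input_size = rep(as.integer(mcfg$input_size), 2))
    sp$backbone$dscse_after_stage <- rep(isTRUE(mcfg$dscse), 4)
    sp$decoder_dscse <- isTRUE(mcfg$dscse)
  } else {
    sp <- model_spec(
      backbone = backbone_spec(dscse_after_stage = rep(isTRUE(mcfg$dscse), 4)),
      head_channels = as.integer(mcfg$head_channels),
      input_size = rep(as.integer(mcfg$input_size), 2),
      decoder_dscse = isTRUE(mcfg$dscse))
  }
  build_model(sp, seed = seed)
}
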