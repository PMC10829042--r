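# Training recipe: unweighted 2-class pixel cross-entropy, AdamW with
# decoupled weight decay, and a triangular cyclical learning rate between
# the base and maximum rates.

#' Mean pixel-wise two-class cross-entropy
#'
#' @param logits array `(2, H, W, N)` (or `(2, H, W)`).
#' @param mask integer array `(H, W, N)` (or `(H, W)`) with values \{0, 1\};
#'   class 1 is sugarcane.
#' @return nonnegative scalar loss; zero only in the limit of perfectly
#'   confident correct prediction.
#' @examples
#' segmentation_loss(array(0, c(2, 4, 4)), matrix(0, 4, 4))  # log(2)
#' @export
segmentation_loss <- function(logits, mask) {
  segmentation_loss_grad(logits, mask, want_grad = FALSE)$loss
}

segmentation_loss_grad <- function(logits, mask, want_grad = TRUE) {
  if (length(dim(logits)) == 3L) dim(logits) <- c(dim(logits), 1L)
  d <- dim(logits)
  if (d[1] != 2L) stop("logits must have two class channels")
  mv <- as.vector(mask)
  if (!all(mv %in% c(0, 1))) stop("mask values must be in {0, 1}")
  npix <- prod(d[-1])
  if (length(mv) != npix) stop("mask shape does not match logits")
  lm <- logits
  dim(lm) <- c(2L, npix)
  mx <- pmax(lm[1, ], lm[2, ])
  lse <- mx + log(exp(lm[1, ] - mx) + exp(lm[2, ] - mx))
  ltrue <- ifelse(mv == 1, lm[2, ], lm[1, ])
  loss <- mean(lse - ltrue)
  if (!want_grad) return(list(loss = loss))
  p1 <- exp(lm[2, ] - lse)
  g <- rbind((1 - p1) - (1 - mv), p1 - mv) / npix
  dim(g) <- d
  list(loss = loss, grad = g)
}

#' Triangular cyclical learning rate
#'
#' Linear rise from `base_lr` to `max_lr` over the first half cycle, linear
#' fall back over the second; periodic in `steps_per_cycle`.
#'
#' @param step 0-based optimizer step.
#' @param steps_per_cycle steps per full triangle (>= 2).
#' @param base_lr,max_lr learning-rate bounds (`base_lr < max_lr`).
#' @return learning rate for the step (vectorised over `step`).
#' @export
cyclical_lr <- function(step, steps_per_cycle, base_lr = 1e-4, max_lr = 1e-3) {
  if (base_lr >= max_lr) stop("base_lr must be below max_lr")
  if (steps_per_cycle < 2) stop("steps_per_cycle must be >= 2")
  pos <- (step %% steps_per_cycle) / steps_per_cycle
  base_lr + (max_lr - base_lr) * (1 - abs(2 * pos - 1))
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: 100 epochs, batch 16, AdamW with
#' base rate 1e-4 cycling to 1e-3 (one triangle per 10 epochs), weight decay
#' 1e-2.
#'
#' @param epochs training epochs.
#' @param batch_size tiles per optimizer step.
#' @param base_lr,max_lr cyclical learning-rate bounds.
#' @param weight_decay AdamW decoupled weight decay.
#' @param cycle_epochs epochs per learning-rate triangle.
#' @param max_steps optional hard cap on optimizer steps (desk-scale runs).
#' @param eval_every evaluate the validation metrics every this many epochs
#'   (the final epoch is always evaluated).
#' @param seed seed for shuffling and any stochastic parts of the loop.
#' @param normalize_from_data estimate per-channel input mean/sd from the
#'   training tiles (stored in the model spec and checkpoint)?
#' @param device informational label; computation is CPU.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100, batch_size = 16, base_lr = 1e-4,
                         max_lr = 1e-3, weight_decay = 1e-2,
                         cycle_epochs = 10, max_steps = NULL, seed = 1L,
                         eval_every = 1L, normalize_from_data = TRUE,
                         device = "cpu") {
  if (epochs < 1) stop("epochs must be >= 1")
  if (base_lr >= max_lr) stop("base_lr must be below max_lr")
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       base_lr = base_lr, max_lr = max_lr, weight_decay = weight_decay,
       cycle_epochs = cycle_epochs,
       max_steps = if (!is.null(max_steps)) as.integer(max_steps),
       seed = as.integer(seed), eval_every = as.integer(eval_every),
       normalize_from_data = isTRUE(normalize_from_data), device = device)
}

load_split_tensors <- function(manifest, split, source_manifest, spec) {
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0L) return(NULL)
  first <- load_tile(rows[1, ], source_manifest, spec)
  H <- nrow(first$mask); W <- ncol(first$mask)
  x <- array(0, c(3, H, W, nrow(rows)))
  y <- array(0L, c(H, W, nrow(rows)))
  x[, , , 1] <- raster_to_tensor(first$image)
  y[, , 1] <- first$mask
  if (nrow(rows) > 1L) {
    for (i in 2:nrow(rows)) {
      t <- load_tile(rows[i, ], source_manifest, spec)
      x[, , , i] <- raster_to_tensor(t$image)
      y[, , i] <- t$mask
    }
  }
  list(x = x, y = y, n = nrow(rows))
}

eval_iou <- function(model, x, y, batch_size = 8L) {
  n <- dim(x)[4]
  counts <- confusion_counts()
  loss_sum <- 0
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    logits <- model_forward(model, x[, , , idx, drop = FALSE],
                            training = FALSE)
    loss_sum <- loss_sum + segmentation_loss(logits,
                                             y[, , idx, drop = FALSE]) * length(idx)
    pred <- apply_argmax(logits)
    counts <- accumulate_confusion(pred, y[, , idx, drop = FALSE], counts)
  }
  rep <- segmentation_metrics(counts, as_percent = FALSE)
  list(loss = loss_sum / n, iou = rep$iou, counts = counts)
}

#' Train a model
#'
#' Full-batch-shuffled mini-batch loop with AdamW and the triangular
#' cyclical learning rate; keeps the checkpoint with the best validation
#' IoU (training IoU when no validation split exists). All randomness is
#' governed by `cfg$seed`, so runs are reproducible on a fixed device.
#'
#' @param model an `nn_dsca_pspnet` (modified in place).
#' @param manifest tile manifest including split labels; may contain lazy
#'   augmented records.
#' @param cfg a [train_config()].
#' @param out_dir optional directory for the best checkpoint and a
#'   line-oriented JSON training log.
#' @param source_manifest,spec_aug source tiles and [aug_spec()] needed to
#'   render lazy augmented records.
#' @return list with `history` (one row per epoch), `lr_trace`,
#'   `best` (epoch/IoU), `steps`, `checkpoint` (path or state).
#' @export
train_model <- function(model, manifest, cfg = train_config(),
                        out_dir = NULL, source_manifest = NULL,
                        spec_aug = NULL) {
  set.seed(cfg$seed)
  train <- load_split_tensors(manifest, "train", source_manifest, spec_aug)
  if (is.null(train)) stop("training split is empty")
  val <- load_split_tensors(manifest, "val", source_manifest, spec_aug)
  if (cfg$normalize_from_data) {
    ss <- seq_len(min(train$n, 64L))
    px <- train$x[, , , ss, drop = FALSE]
    dim(px) <- c(3, length(px) / 3)
    model$spec$norm_mean <- rowMeans(px)
    model$spec$norm_sd <- pmax(apply(px, 1, stats::sd), 1e-3)
  }
  params <- nn_params(model)
  opt <- adamw(params, lr = cfg$base_lr, weight_decay = cfg$weight_decay)
  steps_per_epoch <- max(1L, ceiling(train$n / cfg$batch_size))
  steps_per_cycle <- max(2L, round(cfg$cycle_epochs * steps_per_epoch))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- if (!is.null(out_dir)) file.path(out_dir, "train_log.jsonl")
  history <- vector("list", cfg$epochs)
  lr_trace <- numeric(0)
  best <- list(iou = -Inf, epoch = NA_integer_, state = NULL)
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(train$n)
    ep_loss <- 0; ep_n <- 0L
    for (at in seq(1L, train$n, by = cfg$batch_size)) {
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) { done <- TRUE; break }
      idx <- ord[at:min(at + cfg$batch_size - 1L, train$n)]
      xb <- train$x[, , , idx, drop = FALSE]
      yb <- train$y[, , idx, drop = FALSE]
      logits <- model_forward(model, xb, training = TRUE)
      lg <- segmentation_loss_grad(logits, yb)
      if (!is.finite(lg$loss)) {
        stop(sprintf("divergence: non-finite loss at epoch %d (step %d)",
                     epoch, step))
      }
      zero_grads(params)
      nn_backward(model, lg$grad)
      lr <- cyclical_lr(step, steps_per_cycle, cfg$base_lr, cfg$max_lr)
      adamw_step(opt, lr = lr)
      lr_trace <- c(lr_trace, lr)
      ep_loss <- ep_loss + lg$loss * length(idx)
      ep_n <- ep_n + length(idx)
      step <- step + 1L
    }
    do_eval <- done || epoch %% cfg$eval_every == 0L || epoch == cfg$epochs
    ev <- if (!do_eval) list(loss = NA_real_, iou = NA_real_)
          else if (!is.null(val)) eval_iou(model, val$x, val$y)
          else eval_iou(model, train$x, train$y)
    row <- data.frame(epoch = epoch,
                      train_loss = if (ep_n > 0L) ep_loss / ep_n else NA_real_,
                      val_loss = ev$loss, val_iou = ev$iou,
                      lr_last = if (length(lr_trace)) lr_trace[length(lr_trace)] else NA_real_)
    history[[epoch]] <- row
    if (!is.null(log_path)) {
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), "\n",
          file = log_path, append = TRUE, sep = "")
    }
    if (is.finite(ev$iou) && ev$iou > best$iou) {
      best <- list(iou = ev$iou, epoch = epoch, state = model_state(model))
    }
    if (done) break
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  ck_path <- NULL
  if (!is.null(best$state)) {
    # restore and persist the best weights
    final_state <- model_state(model)
    load_model_state(model, best$state)
    if (!is.null(out_dir)) {
      ck_path <- file.path(out_dir, "checkpoint_best.rds")
      save_checkpoint(model, ck_path, optimizer = opt, history = history,
                      extra = list(best_epoch = best$epoch, config = cfg))
    }
    load_model_state(model, final_state)
  }
  list(history = history, lr_trace = lr_trace,
       best = list(epoch = best$epoch, iou = best$iou, state = best$state),
       steps = step, checkpoint = ck_path)
}
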