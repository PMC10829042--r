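# Pixel-confusion evaluation: IoU, accuracy, precision, recall and F1 from
# accumulated TP/FP/FN/TN tallies. The default dataset protocol pools one
# global confusion matrix over all tiles (micro average) — the only protocol
# under which the five formulas are applied verbatim — and reports the
# per-tile macro average alongside.

#' Create (or seed) a confusion-count accumulator
#' @param tp,fp,fn,tn nonnegative pixel tallies; positive class = sugarcane.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be >= 0")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Accumulate pixel confusion counts
#' @param pred,truth binary arrays of identical shape.
#' @param counts accumulator to add to (fresh one by default).
#' @return updated `confusion_counts`.
#' @export
accumulate_confusion <- function(pred, truth, counts = confusion_counts()) {
  if (!identical(dim(pred), dim(truth)) &&
      !(is.null(dim(pred)) && is.null(dim(truth)) &&
        length(pred) == length(truth))) {
    stop("pred and truth must have identical shape")
  }
  p <- as.vector(pred); t <- as.vector(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1))) {
    stop("masks must be binary")
  }
  counts$tp <- counts$tp + sum(p == 1 & t == 1)
  counts$fp <- counts$fp + sum(p == 1 & t == 0)
  counts$fn <- counts$fn + sum(p == 0 & t == 1)
  counts$tn <- counts$tn + sum(p == 0 & t == 0)
  counts
}

#' Segmentation metrics from confusion counts
#'
#' IoU = TP/(TP+FP+FN), Accuracy = (TP+TN)/total, Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), F1 = 2PR/(P+R). Ratios whose denominator is zero
#' (with TP = 0) are defined as 0 and flagged in `zero_denominator`.
#'
#' @param counts a `confusion_counts`.
#' @param as_percent report on the percent scale (default)?
#' @return a `metrics_report` list with `iou`, `accuracy`, `precision`,
#'   `recall`, `f1`, plus `counts` and `zero_denominator` flags.
#' @export
segmentation_metrics <- function(counts, as_percent = TRUE) {
  tot <- counts$tp + counts$fp + counts$fn + counts$tn
  if (tot == 0) stop("empty evaluation: no pixels counted")
  sdiv <- function(num, den) if (den == 0) 0 else num / den
  iou <- sdiv(counts$tp, counts$tp + counts$fp + counts$fn)
  acc <- (counts$tp + counts$tn) / tot
  prec <- sdiv(counts$tp, counts$tp + counts$fp)
  rec <- sdiv(counts$tp, counts$tp + counts$fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  flags <- c(iou = counts$tp + counts$fp + counts$fn == 0,
             precision = counts$tp + counts$fp == 0,
             recall = counts$tp + counts$fn == 0,
             f1 = prec + rec == 0)
  s <- if (as_percent) 100 else 1
  structure(list(iou = iou * s, accuracy = acc * s, precision = prec * s,
                 recall = rec * s, f1 = f1 * s, percent = as_percent,
                 counts = counts, zero_denominator = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  u <- if (x$percent) "%" else ""
  cat(sprintf("IoU %.2f%s  Acc %.2f%s  Prec %.2f%s  Rec %.2f%s  F1 %.2f%s\n",
              x$iou, u, x$accuracy, u, x$precision, u, x$recall, u, x$f1, u))
  invisible(x)
}

apply_argmax <- function(logits) {
  # per-pixel argmax over the two class channels; ties go to class 0
  d <- dim(logits)
  pred <- array(as.integer(logits[2, , , , drop = FALSE] >
                           logits[1, , , , drop = FALSE]), d[-1])
  pred
}

#' Predict a binary mask for one raster
#' @param model an `nn_dsca_pspnet`.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @return integer `H x W` matrix in \{0, 1\}.
#' @export
predict_mask <- function(model, image) {
  logits <- model_forward(model, raster_to_tensor(image), training = FALSE)
  matrix(apply_argmax(logits), dim(image)[1], dim(image)[2])
}

#' Evaluate a model over a manifest split
#'
#' Accumulates one global confusion matrix (micro average) and also emits
#' per-tile reports with their macro average.
#'
#' @param model an `nn_dsca_pspnet` (evaluation mode is used throughout).
#' @param manifest tile manifest with split labels.
#' @param split split to evaluate (default `"test"`).
#' @param source_manifest,spec_aug needed only when the split contains lazy
#'   augmented records.
#' @return list with `micro` (a `metrics_report`), `macro` (named means of
#'   the per-tile metrics), and `per_tile` (data frame).
#' @export
evaluate_dataset <- function(model, manifest, split = "test",
                             source_manifest = NULL, spec_aug = NULL) {
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0L) stop(sprintf("split '%s' is empty", split))
  missing <- rows$image_path[!file.exists(rows$image_path) & rows$aug_index == 0L]
  if (length(missing)) {
    stop(sprintf("missing rasters: %s", paste(missing, collapse = ", ")))
  }
  global <- confusion_counts()
  per <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    t <- load_tile(rows[i, ], source_manifest, spec_aug)
    pred <- predict_mask(model, t$image)
    cnt <- accumulate_confusion(pred, t$mask)
    global <- accumulate_confusion(pred, t$mask, global)
    rep <- segmentation_metrics(cnt)
    per[[i]] <- data.frame(image_path = rows$image_path[i], iou = rep$iou,
                           accuracy = rep$accuracy, precision = rep$precision,
                           recall = rep$recall, f1 = rep$f1)
  }
  per <- do.call(rbind, per)
  macro <- colMeans(per[, c("iou", "accuracy", "precision", "recall", "f1")])
  list(micro = segmentation_metrics(global), macro = as.list(macro),
       per_tile = per)
}
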