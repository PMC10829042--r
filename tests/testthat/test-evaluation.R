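test_that("confusion accumulation counts the four cells correctly", {
  set.seed(1)
  t <- matrix(rbinom(36, 1, 0.4), 6, 6)
  same <- accumulate_confusion(t, t)
  expect_equal(same$fp, 0); expect_equal(same$fn, 0)
  expect_equal(same$tp + same$tn, 36)

  inv <- accumulate_confusion(1 - t, t)
  expect_equal(inv$tp, 0); expect_equal(inv$tn, 0)

  pred <- matrix(c(1, 0, 1, 0), 2, 2)
  truth <- matrix(c(1, 0, 0, 0), 2, 2)
  cc <- accumulate_confusion(pred, truth)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 0, tn = 2))

  expect_error(accumulate_confusion(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
  expect_error(accumulate_confusion(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")

  # accumulation across calls adds up
  two <- accumulate_confusion(pred, truth, cc)
  expect_equal(two$tp, 2 * cc$tp)
})

test_that("metrics reproduce the hand-computed confusion example", {
  rep <- segmentation_metrics(confusion_counts(tp = 50, fp = 10, fn = 15, tn = 25))
  expect_equal(rep$iou, 100 * 50 / 75, tolerance = 1e-9)        # 66.67
  expect_equal(rep$accuracy, 75, tolerance = 1e-9)
  expect_equal(rep$precision, 100 * 50 / 60, tolerance = 1e-9)  # 83.33
  expect_equal(rep$recall, 100 * 50 / 65, tolerance = 1e-9)     # 76.92
  expect_equal(rep$f1, 80, tolerance = 1e-9)

  perfect <- segmentation_metrics(confusion_counts(tp = 40, tn = 60))
  expect_equal(unlist(perfect[c("iou", "accuracy", "precision", "recall", "f1")]),
               c(iou = 100, accuracy = 100, precision = 100, recall = 100,
                 f1 = 100))

  zero <- segmentation_metrics(confusion_counts(fp = 5, fn = 5, tn = 10))
  expect_equal(zero$iou, 0); expect_equal(zero$f1, 0)
  expect_error(segmentation_metrics(confusion_counts()), "empty")
})

test_that("F1 equals 2*IoU/(1+IoU) for every single confusion matrix", {
  set.seed(7)
  for (i in 1:50) {
    cc <- confusion_counts(tp = rpois(1, 40) + 1, fp = rpois(1, 15),
                           fn = rpois(1, 15), tn = rpois(1, 40))
    r <- segmentation_metrics(cc, as_percent = FALSE)
    expect_equal(r$f1, 2 * r$iou / (1 + r$iou), tolerance = 1e-12)
    expect_lte(r$iou, r$precision + 1e-12)
    expect_lte(r$iou, r$recall + 1e-12)
  }
})

test_that("swapping FP and FN swaps precision and recall", {
  cc <- confusion_counts(tp = 30, fp = 12, fn = 5, tn = 50)
  sw <- confusion_counts(tp = 30, fp = 5, fn = 12, tn = 50)
  a <- segmentation_metrics(cc); b <- segmentation_metrics(sw)
  expect_equal(a$precision, b$recall, tolerance = 1e-12)
  expect_equal(a$recall, b$precision, tolerance = 1e-12)
  expect_equal(a$iou, b$iou); expect_equal(a$f1, b$f1)
})

test_that("converting one false positive to a true negative never hurts", {
  set.seed(5)
  for (i in 1:25) {
    cc <- confusion_counts(tp = rpois(1, 30) + 1, fp = rpois(1, 10) + 1,
                           fn = rpois(1, 10), tn = rpois(1, 30))
    before <- segmentation_metrics(cc)
    after <- segmentation_metrics(confusion_counts(cc$tp, cc$fp - 1, cc$fn,
                                                   cc$tn + 1))
    for (m in c("iou", "accuracy", "precision", "recall", "f1")) {
      expect_gte(after[[m]], before[[m]] - 1e-12)
    }
  }
})

test_that("argmax prediction breaks ties toward the background class", {
  logits <- array(0, c(2, 1, 1, 1))
  logits[, 1, 1, 1] <- c(0.2, 0.1)
  expect_equal(as.vector(dscapsp:::apply_argmax(logits)), 0L)
  logits[, 1, 1, 1] <- c(0.3, 0.3)
  expect_equal(as.vector(dscapsp:::apply_argmax(logits)), 0L)
  logits[, 1, 1, 1] <- c(0.1, 0.2)
  expect_equal(as.vector(dscapsp:::apply_argmax(logits)), 1L)
})

test_that("dataset evaluation pools micro counts and reports macro means", {
  dir <- file.path(tempdir(), "eval-corpus")
  man <- make_tile_corpus(dir, n_tiles = 2, tile = 32, split = "test", seed = 21,
                          min_frac = 0.2, max_frac = 0.8)
  model <- build_model(micro_model_spec(input_size = c(32, 32)), seed = 2)
  r <- evaluate_dataset(model, man, split = "test")
  expect_s3_class(r$micro, "metrics_report")
  expect_equal(nrow(r$per_tile), 2L)
  expect_true(all(unlist(r$macro) >= 0 & unlist(r$macro) <= 100))

  # identical per-tile counts make micro equal macro: duplicate one tile
  man2 <- man[c(1, 1), ]
  r2 <- evaluate_dataset(model, man2, split = "test")
  expect_equal(r2$micro$iou, r2$macro$iou, tolerance = 1e-9)

  bad <- man
  bad$image_path[2] <- file.path(dir, "missing.png")
  expect_error(evaluate_dataset(model, bad, split = "test"), "missing.png")
  expect_error(evaluate_dataset(model, man, split = "val"), "empty")
})

test_that("pooled counts give 50% accuracy for one perfect and one inverted tile", {
  truth <- matrix(rbinom(64, 1, 0.5), 8, 8)
  cc <- accumulate_confusion(truth, truth)
  cc <- accumulate_confusion(1 - truth, truth, cc)
  expect_equal(segmentation_metrics(cc)$accuracy, 50)
})
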