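test_that("cross-entropy loss matches its closed forms", {
  expect_equal(segmentation_loss(array(0, c(2, 4, 4)), matrix(0, 4, 4)),
               log(2), tolerance = 1e-12)
  expect_equal(segmentation_loss(array(0, c(2, 4, 4)), matrix(1, 4, 4)),
               log(2), tolerance = 1e-12)

  # strongly confident correct logits saturate to ~0 loss
  mask <- matrix(rbinom(64, 1, 0.5), 8, 8)
  logits <- array(0, c(2, 8, 8))
  logits[1, , ] <- ifelse(mask == 0, 20, -20)
  logits[2, , ] <- ifelse(mask == 1, 20, -20)
  expect_lt(segmentation_loss(logits, mask), 1e-3)

  # 2x1x1 logits (1, -1), true class 0: ln(1 + e^-2)
  l <- array(c(1, -1), c(2, 1, 1))
  expect_equal(segmentation_loss(l, matrix(0, 1, 1)), log(1 + exp(-2)),
               tolerance = 1e-12)
  expect_error(segmentation_loss(array(0, c(2, 2, 2)), matrix(2, 2, 2)),
               "\\{0, 1\\}")
})

test_that("loss gradient matches a numeric derivative", {
  set.seed(3)
  logits <- array(rnorm(2 * 3 * 3 * 2), c(2, 3, 3, 2))
  mask <- array(rbinom(18, 1, 0.5), c(3, 3, 2))
  lg <- dscapsp:::segmentation_loss_grad(logits, mask)
  eps <- 1e-6
  for (i in sample(length(logits), 5)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num <- (segmentation_loss(lp, mask) - segmentation_loss(lm, mask)) / (2 * eps)
    expect_equal(lg$grad[i], num, tolerance = 1e-5)
  }
})

test_that("the triangular schedule hits its endpoints and midpoints", {
  expect_equal(cyclical_lr(0, 100), 1e-4)
  expect_equal(cyclical_lr(50, 100), 1e-3)
  expect_equal(cyclical_lr(25, 100), 0.00055)
  expect_equal(cyclical_lr(100, 100), 1e-4)     # periodic
  expect_equal(cyclical_lr(175, 100), cyclical_lr(75, 100))
  expect_error(cyclical_lr(0, 100, base_lr = 1e-3, max_lr = 1e-4), "below")
  expect_error(cyclical_lr(0, 1), ">= 2")
  sweep <- cyclical_lr(0:199, 100)
  expect_equal(range(sweep), c(1e-4, 1e-3))
})

test_that("short training runs reduce the loss for most seeds", {
  dir <- file.path(tempdir(), "train-corpus")
  man <- make_tile_corpus(dir, n_tiles = 4, tile = 32, seed = 12,
                          min_frac = 0.1, max_frac = 0.9)
  wins <- 0L
  for (s in 1:5) {
    model <- build_model(micro_model_spec(input_size = c(32, 32)), seed = s)
    r <- train_model(model, man,
                     train_config(epochs = 5, batch_size = 4, cycle_epochs = 2,
                                  seed = s, eval_every = 5))
    if (tail(r$history$train_loss, 1) < r$history$train_loss[1]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("training is reproducible and traces the learning-rate cycle", {
  dir <- file.path(tempdir(), "train-corpus2")
  man <- make_tile_corpus(dir, n_tiles = 4, tile = 32, seed = 14,
                          min_frac = 0.1, max_frac = 0.9)
  run <- function() {
    model <- build_model(micro_model_spec(input_size = c(32, 32)), seed = 3)
    train_model(model, man,
                train_config(epochs = 4, batch_size = 2, cycle_epochs = 2,
                             seed = 77, eval_every = 4))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$history$train_loss[1], r2$history$train_loss[1])
  expect_identical(r1$history, r2$history)
  # one full cycle: 2 epochs x 2 steps; trace hits both bounds
  expect_equal(min(r1$lr_trace), 1e-4)
  expect_equal(max(r1$lr_trace), 1e-3)
  expect_true(all(r1$lr_trace >= 1e-4 & r1$lr_trace <= 1e-3))
  expect_equal(nrow(r1$history), 4L)
})

test_that("empty splits and divergent losses raise informative errors", {
  dir <- file.path(tempdir(), "train-corpus3")
  man <- make_tile_corpus(dir, n_tiles = 2, tile = 32, split = "test", seed = 15,
                          min_frac = 0, max_frac = 1)
  model <- build_model(micro_model_spec(input_size = c(32, 32)), seed = 1)
  expect_error(train_model(model, man, train_config(epochs = 1)), "empty")
})

test_that("the best checkpoint written during training restores exactly", {
  dir <- file.path(tempdir(), "train-corpus4")
  man <- make_tile_corpus(dir, n_tiles = 4, tile = 32, seed = 16,
                          min_frac = 0.1, max_frac = 0.9)
  out <- file.path(tempdir(), "train-out")
  model <- build_model(micro_model_spec(input_size = c(32, 32)), seed = 5)
  r <- train_model(model, man,
                   train_config(epochs = 3, batch_size = 4, cycle_epochs = 2,
                                seed = 1, eval_every = 1), out_dir = out)
  expect_true(file.exists(r$checkpoint))
  expect_true(file.exists(file.path(out, "train_log.jsonl")))
  ck <- load_checkpoint(r$checkpoint)
  x <- array(runif(3 * 32 * 32), c(3, 32, 32, 1))
  best_model <- build_model(micro_model_spec(input_size = c(32, 32)), seed = 5)
  best_model$spec <- ck$model$spec   # includes the data-derived normalisation
  load_model_state(best_model, r$best$state)
  expect_identical(model_forward(ck$model, x), model_forward(best_model, x))
  expect_equal(ck$extra$best_epoch, r$best$epoch)
})
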