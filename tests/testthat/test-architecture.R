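test_that("the full-scale backbone follows the output-stride-8 plan", {
  bb <- build_backbone(backbone_spec(), seed = 1)
  sh <- backbone_stage_shapes(bb, c(3, 512, 512))
  expect_equal(sh[[1]], c(64, 128, 128))
  expect_equal(sh[[2]], c(128, 64, 64))
  expect_equal(sh[[3]], c(256, 64, 64))
  expect_equal(sh[[4]], c(512, 64, 64))
  expect_equal(vapply(sh, function(s) s[1], numeric(1)), c(64, 128, 256, 512))
})

test_that("backbone spec validation rejects malformed plans", {
  expect_error(backbone_spec(dilations = c(2, 1, 2, 4)), "standard residual")
  expect_error(backbone_spec(dilations = c(1, 1, 0, 4)), ">= 1")
  expect_error(backbone_spec(stage_block_counts = c(3, 4, 6)), "four stages")
})

test_that("pyramid pooling doubles the channel count", {
  # channel arithmetic at the pinned width, via shape tracing
  psp <- nn_pyramid_pool(512)
  tr <- nn_trace(psp, c(512, 64, 64))
  expect_equal(tr$shape, c(1024, 64, 64))
  expect_error(nn_pyramid_pool(6), "divisible by 4")

  # numeric forward at a small width
  set.seed(3)
  psp8 <- nn_pyramid_pool(8)
  x <- array(rnorm(8 * 12 * 12 * 2), c(8, 12, 12, 2))
  y <- nn_forward(psp8, x)
  expect_equal(dim(y), c(16, 12, 12, 2))
  expect_equal(y[1:8, , , ], x)   # identity part of the concatenation

  # bin-1 branch of a constant map is constant per channel
  xc <- array(rep(seq_len(8), 5 * 5), c(8, 5, 5, 1))
  yc <- nn_forward(psp8, xc)
  branch1 <- yc[9:10, , , 1]
  expect_equal(max(abs(sweep(branch1, 1, branch1[, 1, 1]))), 0, tolerance = 1e-12)

  # degenerate 1x1 spatial case passes through shape 2C x 1 x 1
  psp4 <- nn_pyramid_pool(4, pyramid_spec(bin_sizes = c(1, 1, 1, 1)))
  y1 <- nn_forward(psp4, array(rnorm(4), c(4, 1, 1, 1)))
  expect_equal(dim(y1), c(8, 1, 1, 1))
})

test_that("the end-to-end shape contract holds across input sizes", {
  # pinned full-channel spec at the smaller sizes
  for (side in c(64, 128)) {
    m <- build_model(model_spec(input_size = c(side, side)), seed = 1)
    x <- array(runif(3 * side * side), c(3, side, side, 1))
    y <- model_forward(m, x)
    expect_equal(dim(y), c(2, side, side, 1))
    rm(m); gc(verbose = FALSE)
  }
  # reduced-width spec with the same stride plan at the larger sizes
  for (side in c(256, 512)) {
    sp <- model_spec(
      backbone = backbone_spec(stage_block_counts = c(1, 1, 1, 1),
                               stage_channels = c(8, 8, 8, 8)),
      head_channels = 8, input_size = c(side, side))
    m <- build_model(sp, seed = 1)
    x <- array(runif(3 * side * side), c(3, side, side, 1))
    y <- model_forward(m, x)
    expect_equal(dim(y), c(2, side, side, 1))
    rm(m, x, y); gc(verbose = FALSE)
  }
})

test_that("a batch of two yields two logit maps and eval mode is deterministic", {
  m <- build_model(micro_model_spec(), seed = 2)
  x <- array(runif(3 * 16 * 16 * 2), c(3, 16, 16, 2))
  y1 <- model_forward(m, x)
  y2 <- model_forward(m, x)
  expect_equal(dim(y1), c(2, 16, 16, 2))
  expect_identical(y1, y2)
  expect_error(model_forward(m, array(0.1, c(4, 16, 16, 1))), "channels")
})

test_that("removing the D-scSE blocks frees exactly the closed-form budget", {
  sp_on <- micro_model_spec()
  sp_off <- micro_model_spec()
  sp_off$backbone$dscse_after_stage <- rep(FALSE, 4)
  sp_off$decoder_dscse <- FALSE
  m_on <- build_model(sp_on, seed = 1)
  m_off <- build_model(sp_off, seed = 1)
  widths <- c(sp_on$backbone$stage_channels, 2 * sp_on$backbone$stage_channels[4])
  expect_equal(count_parameters(m_on) - count_parameters(m_off),
               sum(vapply(widths, dscse_param_count, numeric(1))))
})

test_that("gradient reaches the stem and one optimizer step reduces the loss", {
  set.seed(6)
  m <- build_model(micro_model_spec(), seed = 9)
  x <- array(runif(3 * 16 * 16 * 2), c(3, 16, 16, 2))
  mask <- array(rbinom(16 * 16 * 2, 1, 0.4), c(16, 16, 2))
  params <- nn_params(m)
  logits <- model_forward(m, x, training = TRUE)
  lg <- dscapsp:::segmentation_loss_grad(logits, mask)
  zero_grads(params)
  nn_backward(m, lg$grad)
  stem_conv <- m$backbone$stem$mods[[1]]
  expect_gt(max(abs(stem_conv$W$grad)), 0)
  expect_true(all(vapply(params, function(p) any(p$grad != 0) || all(p$value == 0),
                         logical(1))))
  opt <- adamw(params, lr = 1e-3)
  adamw_step(opt)
  l2 <- segmentation_loss(model_forward(m, x, training = TRUE), mask)
  expect_lt(l2, lg$loss)
})

test_that("checkpoints round-trip bit for bit in eval mode", {
  m <- build_model(micro_model_spec(), seed = 13)
  # push the model away from its deterministic init before saving
  x <- array(runif(3 * 16 * 16 * 2), c(3, 16, 16, 2))
  invisible(model_forward(m, x, training = TRUE))  # update BN running stats
  y_ref <- model_forward(m, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)$model
  expect_identical(model_forward(m2, x), y_ref)
})
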