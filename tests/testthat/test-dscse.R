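test_that("spatial excitation matches the hand-evaluated gate", {
  u <- array(0, c(2, 2, 2))
  u[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  u[2, , ] <- matrix(c(5, 6, 7, 8), 2, 2, byrow = TRUE)
  se <- spatial_excite(u, kernel = c(1, -1), bias = 0)
  # k = u1 - u2 = -4 at every pixel
  expect_equal(as.vector(se$gate), rep(1 / (1 + exp(4)), 4), tolerance = 1e-6)
  expect_equal(se$output, u * (1 / (1 + exp(4))), tolerance = 1e-9)

  se0 <- spatial_excite(u, kernel = c(0, 0), bias = 0)
  expect_equal(se0$output, 0.5 * u)
  expect_equal(spatial_excite(array(0, c(2, 3, 3)), c(2, -1))$output,
               array(0, c(2, 3, 3)))
  expect_error(spatial_excite(u, kernel = c(1, 2, 3)), "channel count")
})

test_that("channel excitation matches the hand-evaluated descriptor path", {
  # channel 1 constant 1; channel 2 alternates 0/2: avg (1, 1), max (1, 2)
  u <- array(0, c(2, 2, 2))
  u[1, , ] <- 1
  u[2, , ] <- matrix(c(0, 2, 0, 2), 2, 2)
  W <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  ce <- channel_excite(u, W)
  expect_equal(ce$descriptor, c(1, 1, 1, 2))
  expect_equal(ce$gate, c(plogis(1), plogis(2)), tolerance = 1e-6)
  expect_equal(ce$output[1, , ], u[1, , ] * plogis(1), tolerance = 1e-9)
  expect_equal(ce$output[2, , ], u[2, , ] * plogis(2), tolerance = 1e-9)

  ce0 <- channel_excite(u, matrix(0, 2, 4))
  expect_equal(ce0$output, 0.5 * u)
  # all-negative pooled descriptor dies in the ReLU: gates 0.5
  un <- array(-abs(rnorm(2 * 3 * 3)) - 0.1, c(2, 3, 3))
  cen <- channel_excite(un, matrix(rnorm(8), 2, 4))
  expect_equal(cen$gate, c(0.5, 0.5))
  expect_error(channel_excite(u, matrix(0, 2, 3)), "C x 2C")
})

test_that("fusion is the weighted branch sum and is linear", {
  u1 <- array(2, c(3, 2, 2)); u2 <- array(10, c(3, 2, 2))
  expect_equal(fuse_excitations(u1, u2, list(alpha = 1, beta = 0)), u1)
  expect_equal(fuse_excitations(u1, u2, list(alpha = 0, beta = 0)),
               array(0, c(3, 2, 2)))
  expect_equal(fuse_excitations(u1, u2, list(alpha = 0.3, beta = 0.7)),
               array(7.6, c(3, 2, 2)))
  expect_error(fuse_excitations(u1, array(1, c(3, 2, 3)),
                                list(alpha = 1, beta = 1)), "shape")
  set.seed(4)
  a <- rnorm(1)
  w <- list(alpha = rnorm(1), beta = rnorm(1))
  x1 <- array(rnorm(12), c(3, 2, 2)); x2 <- array(rnorm(12), c(3, 2, 2))
  expect_equal(fuse_excitations(a * x1, a * x2, w),
               a * fuse_excitations(x1, x2, w), tolerance = 1e-12)
})

test_that("fusion-weight initialisation follows the stated uniform law", {
  w <- init_fusion_weights(n = 6, seed = 42)
  expect_true(abs(w$alpha) <= 1 && abs(w$beta) <= 1)  # sqrt(6/6) = 1
  w2 <- init_fusion_weights(n = 6, seed = 42)
  expect_identical(w[c("alpha", "beta")], w2[c("alpha", "beta")])
  expect_error(init_fusion_weights(n = 0), "positive")

  set.seed(9)
  draws <- replicate(5000, unlist(init_fusion_weights(n = 6)[c("alpha", "beta")]))
  expect_lt(abs(mean(draws)), 0.03)
  expect_true(min(draws) >= -1 && max(draws) <= 1)
})

test_that("dscse_forward equals the composition and preserves shape/gates", {
  set.seed(2)
  for (trial in 1:12) {
    C <- sample(1:8, 1); H <- sample(1:8, 1); W <- sample(1:8, 1)
    u <- array(rnorm(C * H * W), c(C, H, W))
    p <- dscse_params(C, seed = trial)
    out <- dscse_forward(u, p)
    expect_identical(dim(out), dim(u))
    g_sp <- spatial_excite(u, p$spatial_kernel, p$spatial_bias)$gate
    g_ch <- channel_excite(u, p$channel_weight, p$channel_bias)$gate
    expect_true(all(g_sp > 0 & g_sp < 1))
    expect_true(all(g_ch > 0 & g_ch < 1))
  }
})

test_that("all-zero squeeze weights with unit fusion reproduce the input", {
  set.seed(5)
  u <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  p <- list(spatial_kernel = rep(0, 3), spatial_bias = 0,
            channel_weight = matrix(0, 3, 6), channel_bias = rep(0, 3),
            fusion = list(alpha = 1, beta = 1))
  expect_equal(dscse_forward(u, p), u, tolerance = 1e-12)  # 0.5 U + 0.5 U
})

test_that("the closed-form parameter budget matches a built block", {
  expect_identical(dscse_param_count(64), 8323)
  blk <- dscse_block(16)
  expect_identical(count_parameters(blk), as.numeric(dscse_param_count(16)))
})

test_that("fusion weights receive gradient and move under optimization", {
  set.seed(8)
  blk <- dscse_block(4)
  a0 <- blk$alpha$value; b0 <- blk$beta$value
  x <- array(rnorm(4 * 6 * 6 * 2), c(4, 6, 6, 2))
  target <- spatial_excite(x[, , , 1], blk$w_sp$value, blk$b_sp$value)$output
  params <- nn_params(blk)
  opt <- adamw(params, lr = 1e-2)
  for (i in 1:3) {
    y <- nn_forward(blk, x, training = TRUE)
    dy <- y
    dy[, , , 1] <- y[, , , 1] - target   # pull toward the spatial branch
    zero_grads(params)
    nn_backward(blk, dy)
    adamw_step(opt)
  }
  expect_gt(abs(blk$alpha$value - a0), 1e-6)
  expect_gt(abs(blk$beta$value - b0), 1e-6)
})
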