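test_that("the landmark partition is a greedy schema-order split", {
  sch <- landmark_schema()
  p5 <- partition_landmarks(sch, 5)
  expect_length(p5, 5L)
  expect_equal(unname(vapply(p5, length, integer(1))), c(5L, 5L, 5L, 5L, 1L))
  expect_identical(unname(unlist(p5)), sch$abbrev)

  p3 <- partition_landmarks(sch, 3)
  expect_length(p3, 7L)
  expect_true(all(vapply(p3, length, integer(1)) <= 3))

  p21 <- partition_landmarks(sch, 21)
  expect_length(p21, 1L)
  expect_length(p21[[1]], 21L)
})

test_that("invalid network configurations are rejected", {
  expect_error(flatnet_config(dilation_rates = c(1, 2, 4)), "5 dilation rates")
  expect_error(flatnet_config(dilation_rates = c(0, 1, 2, 3, 4)), "positive")
  expect_error(flatnet_config(filters = c(f1 = 0, f2 = 2, f4 = 2, f5 = 2, f6 = 2)),
               ">= 1")
  expect_error(flatnet_config(filters = c(a = 1)), "named")
  expect_error(flatnet_config(kernel_l1_l2 = 8), "odd")
})

test_that("parameter counts equal the closed-form layer sum", {
  # toy config from the hand-derived formula
  cfg <- flatnet_config(filters = c(f1 = 2L, f2 = 2L, f4 = 4L, f5 = 4L, f6 = 4L))
  net <- build_flatnet(cfg, n_outputs = 1, seed = 1)
  hand <- 5 * (81 * 3 * 2 + 2 + 81 * 2 * 2 + 2) +
    (25 * 5 * 2 * 4 + 4) + (4 * 4 + 4) + (4 * 4 + 4) + (4 * 1 + 1)
  expect_equal(count_parameters(net), hand)
  expect_equal(flatnet_param_formula(cfg, 1), hand)

  # arbitrary configs: formula == built network, exactly
  set.seed(11)
  for (i in 1:4) {
    f <- setNames(sample(1:9, 5, replace = TRUE), c("f1", "f2", "f4", "f5", "f6"))
    cfg_i <- flatnet_config(dilation_rates = sample(1:6, 5, replace = TRUE),
                            filters = f)
    K <- sample(1:5, 1)
    expect_equal(count_parameters(build_flatnet(cfg_i, K)),
                 flatnet_param_formula(cfg_i, K))
  }

  # finite difference of the formula in f4
  f0 <- c(f1 = 3L, f2 = 4L, f4 = 6L, f5 = 5L, f6 = 4L)
  f1 <- f0; f1["f4"] <- f0["f4"] + 2L
  d <- flatnet_param_formula(flatnet_config(filters = f1), 2) -
    flatnet_param_formula(flatnet_config(filters = f0), 2)
  expect_equal(d, 25 * 5 * 4 * 2 + 2 + 2 * 5)  # k4^2*nb*f2*df4 + df4 + df4*f5
})

test_that("the architecture audit finds only stride-1 same-padded conv layers", {
  net <- build_flatnet(tiny_flat_config(), 5, seed = 2)
  layers <- network_layers(net)
  expect_false(any(layers$type %in% c("pool", "fc", "dense", "upsample",
                                      "downsample")))
  expect_true(all(layers$type %in% c("conv", "concat")))
  expect_true(all(layers$stride == 1L))
  expect_true(all(layers$padding == "same"))
  conv <- layers[layers$type == "conv", ]
  expect_true(all(conv$activation[conv$layer != "L7"] == "relu"))
  expect_identical(conv$activation[conv$layer == "L7"], "tanh")
  expect_equal(sum(layers$layer == "L1"), 5L)  # five dilated branches
  expect_equal(sort(unique(conv$kernel)), c(1L, 5L, 9L))
  # channel bookkeeping: concat carries all branch outputs
  expect_equal(layers$in_channels[layers$layer == "L3"], 5L * 2L)
})

test_that("the network preserves spatial dimensions and the tanh output range", {
  net <- build_flatnet(tiny_flat_config(), 5, seed = 3)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  out <- flatnet_forward(net, img)
  expect_equal(dim(out), c(64L, 64L, 5L))
  expect_true(all(out > -1 & out < 1))
  z <- flatnet_forward(net, matrix(0, 32, 48))
  expect_equal(dim(z), c(32L, 48L, 5L))
})

test_that("the fully-convolutional stack is translation-equivariant in the interior", {
  cfg <- flatnet_config(dilation_rates = c(1L, 1L, 2L, 2L, 3L),
                        filters = c(f1 = 2L, f2 = 2L, f4 = 3L, f5 = 3L, f6 = 3L))
  net <- build_flatnet(cfg, 2, seed = 4)
  set.seed(5)
  H <- 96
  img <- matrix(runif(H * H, 0, 255), H, H)
  dx <- 5L; dy <- 3L
  shifted <- matrix(0, H, H)
  shifted[(1 + dy):H, (1 + dx):H] <- img[1:(H - dy), 1:(H - dx)]

  out <- flatnet_forward(net, img)
  out_sh <- flatnet_forward(net, shifted)
  # receptive-field radius: two 9x9 convs at dilation <= 3 plus one 5x5
  margin <- 2 * 4 * 3 + 2 + max(dx, dy)
  rows <- (margin + 1):(H - margin)
  cols <- (margin + 1):(H - margin)
  for (ch in 1:2) {
    expect_equal(out_sh[rows + dy, cols + dx, ch], out[rows, cols, ch],
                 tolerance = 1e-4)
  }
})

test_that("gradients agree with central finite differences on a tiny net", {
  cfg <- flatnet_config(dilation_rates = c(1L, 2L, 3L, 4L, 5L),
                        filters = c(f1 = 2L, f2 = 3L, f4 = 4L, f5 = 4L, f6 = 3L))
  net <- build_flatnet(cfg, 2, seed = 5)
  set.seed(1)
  H <- 12L; W <- 10L
  X <- matrix(runif(H * W * 3), H * W, 3)
  Tg <- matrix(runif(H * W * 2), H * W, 2)
  st <- flatnet:::fn_step(net$weights, list(X), list(Tg), H, W,
                          cfg$dilation_rates, 9, 5)
  loss_of <- function(w) mean(abs(flatnet:::fn_forward(
    w, X, H, W, cfg$dilation_rates, 9, 5) - Tg))
  rel_err <- c()
  for (wi in c(1L, 3L, 21L, 23L, 25L, 27L)) {
    for (ix in sample(length(net$weights[[wi]]), 3)) {
      e <- 5e-3
      wp <- net$weights; wp[[wi]][ix] <- wp[[wi]][ix] + e
      wm <- net$weights; wm[[wi]][ix] <- wm[[wi]][ix] - e
      fd <- (loss_of(wp) - loss_of(wm)) / (2 * e)
      an <- st$grads[[wi]][ix]
      rel_err <- c(rel_err, abs(fd - an) / max(1e-6, abs(fd) + abs(an)))
    }
  }
  # fp32 forward + the MAE kink make single probes noisy; the bulk must agree
  expect_lt(median(rel_err), 1e-3)
  expect_lt(max(rel_err), 0.1)
})
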