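# Preprocessing, augmentation, model construction, the masked/weighted loss
# and the training loop (freezing, determinism, capacity).

test_that("preprocess crops, resizes and standardizes with a leakage guard", {
  spec224 <- backbone_spec("resnet50")
  rgb <- array(runif(640 * 480 * 3, 0, 255), c(480, 640, 3))
  out <- preprocess(rgb, "rgb", spec224)
  expect_equal(dim(out), c(224, 224, 3))
  expect_true(all(out >= 0 & out <= 1))

  tiny <- backbone_spec("tiny_test_cnn")
  ms <- array(runif(64 * 64 * 6), c(64, 64, 6))
  stats <- ms_train_stats(list(ms))
  flat <- ms; for (c in 1:6) flat[, , c] <- stats$mean[c]
  std <- preprocess(flat, "ms", tiny, stats)
  expect_equal(max(abs(std)), 0, tolerance = 1e-9)

  expect_error(preprocess(ms, "ms", tiny), "statistics")
  leaky <- ms_train_stats(list(ms), source = "val")
  expect_error(preprocess(ms, "ms", tiny, leaky), "leak")
})

test_that("augment is a seeded involution with fair flip rates", {
  x <- array(1:36, c(3, 3, 4))
  # find seeds forcing each flip combination
  both_seed <- NULL
  for (s in 1:100) {
    set.seed(s); f <- runif(2) < 0.5
    if (all(f)) { both_seed <- s; break }
  }
  rot180 <- x[3:1, 3:1, , drop = FALSE]
  expect_equal(augment(x, both_seed), rot180)
  expect_equal(augment(augment(x, both_seed), both_seed), x)

  rates <- matrix(0, 10000, 2)
  for (s in seq_len(10000)) { set.seed(s); rates[s, ] <- runif(2) < 0.5 }
  expect_equal(colMeans(rates), c(0.5, 0.5), tolerance = 0.02)
})

test_that("build_model wires the adapter, heads and errors", {
  m6 <- build_model(head = head_spec("single_linear"), in_channels = 6)
  expect_equal(dim(m6$params$adapter_w), c(1, 1, 6, 3))
  x1 <- array(rnorm(64 * 64 * 6), c(64, 64, 6, 1))
  h <- conv_fw(x1, m6$params$adapter_w, m6$params$adapter_b, 1L, 0L)
  expect_equal(dim(h), c(64, 64, 3, 1))

  msoft <- build_model(head = head_spec("multi_softmax"), in_channels = 6)
  t0 <- Sys.time()
  out <- nn_forward(msoft, array(rnorm(64 * 64 * 6 * 4), c(64, 64, 6, 4)))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 1)
  expect_true(all(is.finite(out)))
  expect_equal(rowSums(out), rep(1, 4), tolerance = 1e-6)
  expect_true(all(out >= 0))

  m3 <- build_model(head = head_spec("single_linear"), in_channels = 3)
  expect_null(m3$params$adapter_w)
  expect_error(build_model(in_channels = 5), "3 or 6")
  expect_error(build_model(backbone_spec("efficientnet_b4"),
                           in_channels = 3), "pretrained")
  expect_error(head_spec("single_linear", n_outputs = 4), "1 output")
})

test_that("masked weighted MSE matches direct arithmetic", {
  hd_mask <- head_spec("multi_linear", organ_weights = c(1, 1, 1, 1))
  yt <- matrix(c(2, 0, 3, 1), 1)
  yp <- matrix(c(1, 5, 3, 1), 1)
  # included terms: (2-1)^2, (3-3)^2, (1-1)^2 -> 1/3
  expect_equal(masked_weighted_mse(yt, yp, hd_mask), 1 / 3)

  yt2 <- matrix(c(2, 0, 3), 1); yp2 <- matrix(c(1, 5, 3), 1)
  hd3 <- head_spec("multi_linear", n_outputs = 4)
  hd3$organ_weights <- rep(1, 3); hd3$n_outputs <- 3L
  expect_equal(masked_weighted_mse(yt2, yp2, hd3), 0.5)

  # x20 flag-leaf weight with the count (not weight) denominator
  hd_w <- head_spec("multi_softmax")  # weights 1,1,20,1, no masking
  e <- 0.3
  yt3 <- matrix(c(.4, .3, .2, .1), 1)
  yp3 <- yt3; yp3[3] <- yt3[3] + e
  expect_equal(masked_weighted_mse(yt3, yp3, hd_w), 20 * e^2 / 4)

  expect_equal(masked_weighted_mse(yt3, yt3, hd_w), 0)
  expect_warning(l0 <- masked_weighted_mse(matrix(0, 2, 4),
                                           matrix(1, 2, 4), hd_mask),
                 "masked")
  expect_equal(l0, 0)
})

test_that("loss gradient is exact and zero at masked entries", {
  set.seed(31)
  hd <- head_spec("multi_linear")  # masking on, unit weights
  yt <- matrix(rexp(20), 5, 4)
  yt[sample(20, 6)] <- 0
  yp <- matrix(rnorm(20), 5, 4)
  g <- masked_weighted_mse(yt, yp, hd, return_grad = TRUE)$grad
  eps <- 1e-6
  for (i in seq_len(20)) {
    ypp <- yp; ypp[i] <- yp[i] + eps
    ypm <- yp; ypm[i] <- yp[i] - eps
    fd <- (masked_weighted_mse(yt, ypp, hd) -
             masked_weighted_mse(yt, ypm, hd)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
    if (yt[i] == 0) expect_identical(g[i], 0)
  }
})

make_training_set <- function(n, seed = 1, size = 64) {
  set.seed(seed)
  cfg <- render_config("image", image_size = size)
  dms <- runif(n, 1, 22)
  lais <- runif(n, 0.5, 6)
  imgs <- lapply(seq_len(n), function(i)
    render_canopy(make_traits(dm = dms[i], lai = lais[i]), cfg,
                  seed = seed * 1000 + i)$ms)
  stats <- ms_train_stats(imgs)
  x <- stack_tensor(lapply(imgs, preprocess, kind = "ms",
                           spec = backbone_spec("tiny_test_cnn"),
                           train_stats = stats))
  list(x = x, y = matrix(dms, ncol = 1))
}

test_that("training honors freezing scopes and zero learning rate", {
  d <- make_training_set(12, seed = 2)
  m0 <- build_model(head = head_spec("single_linear"), in_channels = 6,
                    seed = 5)
  ph <- list(train_phase("transfer", epochs = 2))
  m1 <- train_model(m0, d$x, d$y, ph, seed = 1)
  frozen <- setdiff(names(m0$params),
                    wheatcanopy:::scope_params(m0, "head_only"))
  for (nm in frozen) expect_identical(m1$params[[nm]], m0$params[[nm]])
  expect_false(identical(m1$params$dense_w, m0$params$dense_w))

  ph0 <- list(train_phase("transfer", epochs = 2, learning_rate = 0,
                          trainable_scope = "all"))
  mz <- train_model(m0, d$x, d$y, ph0, seed = 1)
  expect_identical(mz$params, m0$params)

  expect_error(train_model(m0, d$x[, , , 0, drop = FALSE],
                           d$y[0, , drop = FALSE], ph, seed = 1), "empty")
})

test_that("training loss decreases and the net can overfit", {
  # median-of-3-seeds loss curve over the first epochs, all layers trained
  d <- make_training_set(200, seed = 3)
  curves <- sapply(1:3, function(s) {
    m <- build_model(head = head_spec("single_linear"), in_channels = 6,
                     seed = s)
    ph <- list(train_phase("transfer", epochs = 5, trainable_scope = "all"))
    train_model(m, d$x, d$y, ph, seed = s)$history$train_loss
  })
  med <- apply(curves, 1, median)
  expect_true(all(diff(med) < 0))

  # capacity: training MSE below 10% of target variance (deterministic
  # evaluation pass, augmentation off)
  d2 <- make_training_set(50, seed = 4)
  m <- build_model(head = head_spec("single_linear"), in_channels = 6,
                   seed = 11)
  ph <- list(train_phase("transfer", epochs = 200,
                         trainable_scope = "all"))
  m <- train_model(m, d2$x, d2$y, ph, seed = 7, augment_flips = FALSE)
  pred <- nn_forward(m, d2$x)
  mse <- mean((pred - d2$y)^2)
  expect_lt(mse, 0.1 * var(drop(d2$y)))
})
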