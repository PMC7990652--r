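test_that("architecture follows the encoder/dual-decoder contract", {
  spec <- network_spec(base_width = 8L)
  expect_equal(spec$widths, c(8L, 16L, 32L, 64L, 64L))
  model <- build_fcnn(spec, seed = 1)
  conv_names <- grep("\\.w$", names(model$params), value = TRUE)
  enc <- grep("^enc", conv_names, value = TRUE)
  expect_length(enc, 10L) # ten 3x3 encoder convolutions
  for (dec in c("img", "seg")) {
    convs <- grep(sprintf("^%s\\.(conv|out)", dec), conv_names, value = TRUE)
    expect_length(convs, 9L) # nine convolutions per decoder
    ups <- grep(sprintf("^%s\\.up", dec), conv_names, value = TRUE)
    expect_length(ups, 4L)
  }
  # decoders are structurally identical
  img_shapes <- lapply(model$params[grep("^img", names(model$params))], dim)
  seg_shapes <- lapply(model$params[grep("^seg", names(model$params))], dim)
  names(seg_shapes) <- sub("^seg", "img", names(seg_shapes))
  expect_identical(img_shapes, seg_shapes[names(img_shapes)])
  # initialization is reproducible and does not disturb the caller RNG
  set.seed(99); before <- runif(1)
  m2 <- build_fcnn(spec, seed = 1)
  set.seed(99); expect_identical(runif(1), before)
  expect_identical(model$params, m2$params)
})

test_that("input variants map to the documented configurations", {
  m32 <- build_fcnn(network_spec(input_channels = 32L, base_width = 4L))
  expect_equal(dim(m32$params[["enc1a.w"]])[3], 32L)
  m1 <- build_fcnn(network_spec(input_channels = 1L, n_decoders = 1L,
                                base_width = 4L))
  expect_equal(dim(m1$params[["enc1a.w"]])[3], 1L)
  expect_false(any(grepl("^img", names(m1$params))))
  x <- array(rnorm(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  pred <- infer(m1, x)
  expect_null(pred$d)
  expect_equal(dim(pred$s_p), c(32L, 32L, 2L))
})

test_that("inference is shape-preserving, bounded and order-preserving", {
  model <- build_fcnn(network_spec(base_width = 2L), seed = 5)
  x <- array(rnorm(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  pred <- infer(model, x)
  expect_equal(dim(pred$d), c(32L, 32L, 3L))
  expect_true(all(pred$s_p > 0 & pred$s_p < 1))
  expect_true(all(is.finite(pred$d)))
  # batch results equal per-example results, in order
  p1 <- infer(model, x[, , , 1])
  expect_equal(unclass(p1$d), pred$d[, , 1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(infer(model, array(0, c(32, 32, 5, 1))), "channels")
  expect_error(infer(model, array(0, c(30, 30, 2, 1))), "divisible")
})

test_that("losses match their closed forms", {
  d <- matrix(runif(64), 8, 8)
  expect_equal(l1_loss(d, d), 0)
  expect_equal(l1_loss(d + 0.1, d), 0.1, tolerance = 1e-12)
  e <- matrix(runif(64), 8, 8)
  expect_equal(l1_loss(d, e), mean(abs(d - e)))
  expect_error(l1_loss(d, matrix(0, 2, 2)), "mismatch")

  s_t <- matrix(0, 8, 8); s_t[3:5, 3:5] <- 1
  expect_equal(dsc_loss(s_t, s_t), 0, tolerance = 1e-6)
  expect_equal(dsc_loss(s_t * 0, s_t), 1, tolerance = 1e-6)
  expect_equal(dsc_loss(0.5 * s_t, s_t), 1 / 3, tolerance = 1e-6)
  expect_equal(total_loss(d, e, 0.5 * s_t, s_t),
               l1_loss(d, e) + 1 / 3, tolerance = 1e-6)
})

test_that("backprop matches finite differences on a tiny model", {
  model <- build_fcnn(network_spec(base_width = 2L), seed = 3)
  set.seed(3)
  x <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  e <- array(runif(16 * 16 * 2), c(16, 16, 2))
  s <- array(rbinom(16 * 16 * 2, 1, 0.2), c(16, 16, 2))
  loss_fn <- function(m) {
    fw <- pwnet:::fcnn_forward(m, x, training = TRUE)
    l1_loss(array(fw$heads$img, dim(e)), e) +
      dsc_loss(array(fw$heads$seg, dim(s)), s)
  }
  fw <- pwnet:::fcnn_forward(model, x, training = TRUE)
  nb <- 2; npix <- 256
  ghead <- list(img = sign(fw$heads$img - array(e, dim(fw$heads$img))) /
                  (nb * npix),
                seg = array(0, dim(fw$heads$seg)))
  sm <- 1e-6
  for (i in 1:nb) {
    p <- fw$heads$seg[, , 1, i]; tt <- s[, , i]
    sden <- sum(p) + sum(tt) + sm
    snum <- 2 * sum(p * tt) + sm
    ghead$seg[, , 1, i] <- -(2 * tt * sden - snum) / (sden^2 * nb)
  }
  gr <- pwnet:::fcnn_backward(model, fw$cache, ghead)
  h <- 1e-4
  for (nm in c("enc1a.w", "enc3b.gamma", "img.up4.w", "img.conv2a.w",
               "seg.out.w")) {
    k <- min(3, length(model$params[[nm]]))
    m1 <- model; m1$params[[nm]][k] <- m1$params[[nm]][k] + h
    m2 <- model; m2$params[[nm]][k] <- m2$params[[nm]][k] - h
    g_num <- (loss_fn(m1) - loss_fn(m2)) / (2 * h)
    expect_equal(gr[[nm]][k], g_num, tolerance = 2e-2,
                 label = sprintf("gradient of %s", nm))
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(7)
  n <- 8L
  x <- array(rnorm(32 * 32 * 2 * n), c(32, 32, 2, n))
  s <- array(0, c(32, 32, n))
  for (i in 1:n) s[8:20, 8:20, i] <- (x[8:20, 8:20, 1, i] > 0) * 0 + 1
  e <- array(runif(32 * 32 * n) * 0.5, c(32, 32, n))
  data <- list(x = x, e = e, s = s)
  model <- build_fcnn(network_spec(base_width = 2L), seed = 2)
  cfg <- train_config(epochs = 30, batch_size = 8, learning_rate = 2e-3,
                      seed = 4)
  m <- train(model, data, cfg)
  sm <- stats::filter(m$log$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  # smoothed training loss decreases monotonically over epochs
  expect_true(all(diff(sm) < 0))
  expect_lt(tail(sm, 1), 0.9 * sm[1])
  # determinism under the same seed
  m2 <- train(build_fcnn(network_spec(base_width = 2L), seed = 2),
              data, cfg)
  expect_equal(m$log$loss, m2$log$loss, tolerance = 1e-12)
  expect_error(train(model, list(x = NULL, s = s), cfg), "empty")
})

test_that("iteration caps equalize training across regimes", {
  set.seed(8)
  x <- array(rnorm(16 * 16 * 2 * 6), c(16, 16, 2, 6))
  e <- array(runif(16 * 16 * 6), c(16, 16, 6))
  s <- array(rbinom(16 * 16 * 6, 1, 0.2), c(16, 16, 6))
  model <- build_fcnn(network_spec(base_width = 2L), seed = 2)
  # half-size dataset with doubled epochs reaches the same cap
  full <- train(model, list(x = x, e = e, s = s),
                train_config(epochs = 4, batch_size = 2, seed = 1,
                             max_iterations = 8L))
  half <- train(model, list(x = x[, , , 1:3, drop = FALSE],
                            e = e[, , 1:3, drop = FALSE],
                            s = s[, , 1:3, drop = FALSE]),
                train_config(epochs = 8, batch_size = 2, seed = 1,
                             max_iterations = 8L))
  expect_identical(full$iterations, 8L)
  expect_identical(half$iterations, 8L)
})

test_that("checkpoints round-trip with a JSON sidecar", {
  d <- withr::local_tempdir()
  model <- build_fcnn(network_spec(base_width = 2L), seed = 2)
  p <- save_model(model, file.path(d, "m.rds"))
  m2 <- load_model(p)
  expect_identical(m2$params, model$params)
  side <- jsonlite::read_json(file.path(d, "m.json"))
  expect_equal(side$spec$base_width, 2L)
  expect_equal(side$seed, 2L)
})
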