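test_that("demodulation turns in-band tones into constant baseband", {
  probe <- fix_probe()
  fs <- probe$sampling_frequency
  fd <- probe$center_frequency
  n <- 2048L
  t <- (0:(n - 1)) / fs
  raw <- structure(list(samples = matrix(cos(2 * pi * fd * t), n, 4),
                        sampling_frequency = fs, t_start = 0,
                        probe = probe, sound_speed = 1540),
                   class = "pw_raw")
  bb <- demodulate(raw)
  mid <- 200:1800 # away from filter edge effects
  expect_lt(sd(Mod(bb$values[mid, 1])), 1e-3)
  expect_equal(mean(Mod(bb$values[mid, 1])), 1, tolerance = 1e-3)
  # zero in, zero out
  raw$samples[] <- 0
  expect_true(all(demodulate(raw)$values == 0))
})

test_that("baseband envelope matches the analytic envelope", {
  ex <- fix_example()
  bb <- demodulate(ex$raw)
  ch <- 64L
  env_bb <- Mod(bb$values[, ch])
  env_hil <- hilbert_envelope(ex$raw$samples[, ch])
  # same peak sample within one sample, similar magnitude
  expect_lt(abs(which.max(env_bb) - which.max(env_hil)), 2)
  sel <- env_hil > 0.1 * max(env_hil)
  rms_rel <- sqrt(mean((env_bb[sel] - env_hil[sel])^2)) /
    sqrt(mean(env_hil[sel]^2))
  expect_lt(rms_rel, 0.02)
})

test_that("time-to-depth interpolation maps c*t/2 onto grid rows", {
  probe <- fix_probe()
  grid <- fix_grid()
  fs <- probe$sampling_frequency
  n <- 6000L
  mkbb <- function(values) structure(
    list(values = values, sampling_frequency = fs, t_start = 0,
         f_demod = probe$center_frequency, probe = probe,
         sound_speed = 1500), class = "pw_baseband")
  # constant and linear-ramp lines survive linear interpolation
  bb <- mkbb(matrix(7 + 0i, n, 128))
  g <- downsample_to_grid(bb, grid, 1500)
  expect_true(all(abs(g$values[, , 1] - 7) < 1e-12))
  ramp <- matrix(rep(seq_len(n) + 0i, 128), n, 128)
  g2 <- downsample_to_grid(mkbb(ramp), grid, 1500)
  expect_equal(g2$values[, 1, 1],
               2 * grid$depth_mm * 1e-3 / 1500 * fs + 1, tolerance = 1e-9)
  # an impulse at t = 40 us with c = 1500 lands on the 30 mm row
  imp <- matrix(0 + 0i, n, 128)
  imp[round(40e-6 * fs) + 1, ] <- 1
  g3 <- downsample_to_grid(mkbb(imp), grid, 1500)
  expect_equal(which.max(Mod(g3$values[, 1, 1])),
               which.min(abs(grid$depth_mm - 30)))
  # depth span beyond the record errors
  expect_error(downsample_to_grid(mkbb(matrix(0i, 100, 128)), grid, 1500),
               "exceeds")
})

test_that("input normalization is a sign-preserving max rescale", {
  g <- fix_example()$ex$i_d
  expect_true(g$normalized)
  expect_equal(max(abs(g$values)), 1)
  expect_true(all(g$values >= -1 & g$values <= 1))
  # idempotent
  g2 <- normalize_input(g)
  expect_identical(g2$values, g$values)
  # sign pattern preserved
  raw5 <- g; raw5$values <- g$values * 5; raw5$normalized <- FALSE
  expect_identical(sign(normalize_input(raw5)$values), sign(g$values))
  zero <- g; zero$values[] <- 0
  expect_error(normalize_input(zero), "all-zero")
})

test_that("das_beamform matches the brute-force delay-and-sum oracle", {
  toy <- fix_toy()
  img <- das_beamform(toy$bb, toy$grid, 1540)
  ref <- das_bruteforce(toy$bb, toy$grid, 1540)
  expect_lt(max(Mod(img - ref)) / max(Mod(ref)), 1e-9)
})

test_that("beamforming is flip-equivariant and linear", {
  ex <- fix_example()
  grid <- fix_grid()
  bb <- demodulate(ex$raw)
  img <- das_beamform(bb, grid)
  bbf <- demodulate(flip_lr(ex$raw))
  imgf <- das_beamform(bbf, grid)
  expect_equal(Mod(imgf), Mod(img)[, rev(seq_len(ncol(img)))],
               tolerance = 1e-9)
  # linearity in the channel data
  bb2 <- bb; bb2$values <- bb$values * 2
  expect_equal(das_beamform(bb2, grid), 2 * img, tolerance = 1e-12)
})

test_that("point targets focus at their true position", {
  probe <- fix_probe()
  grid <- image_grid(probe, d = 256L) # full-resolution grid
  f <- make_phantom(phantom_spec(2, 0, 55, 1540, seed = 1,
                                 n_scatterers = 1))
  f$x_mm <- -5; f$z_mm <- 52; f$amplitude <- 1
  raw <- simulate_plane_wave(f, probe)
  img <- das_beamform(demodulate(raw), grid)
  pk <- which(Mod(img) == max(Mod(img)), arr.ind = TRUE)
  # envelope argmax within one grid cell of the scatterer
  expect_lt(abs(grid$depth_mm[pk[1]] - 52), 1.5 * diff(grid$depth_mm[1:2]))
  expect_lt(abs(grid$line_mm[pk[2]] - (-5)), 1.5 * diff(grid$line_mm[1:2]))
})

test_that("focused stack sums to the DAS image and aligns point targets", {
  toy <- fix_toy()
  stack <- apply_receive_delays(toy$bb, toy$grid, 1540)
  expect_identical(das_from_stack(stack), das_beamform(toy$bb, toy$grid, 1540))
  # single retained channel equals that channel's slice
  one <- stack
  one$values <- stack$values[, , 3, drop = FALSE]
  expect_identical(das_from_stack(one), stack$values[, , 3])
  # point-target alignment across channels after delays
  probe <- fix_probe(); grid <- fix_grid()
  f <- make_phantom(phantom_spec(2, 0, 55, 1540, seed = 1,
                                 n_scatterers = 1))
  f$x_mm <- 0; f$z_mm <- 55; f$amplitude <- 1
  st <- apply_receive_delays(demodulate(simulate_plane_wave(f, probe)),
                             grid)
  line <- which.min(abs(grid$line_mm))
  rows <- apply(Mod(st$values[, line, c(16, 48, 64, 80, 112)]), 2,
                which.max)
  expect_true(all(abs(rows - which.min(abs(grid$depth_mm - 55))) <= 1))
})

test_that("subaperture beamforming groups 128 channels into 32 features", {
  toy <- fix_toy()
  stack <- apply_receive_delays(toy$bb, toy$grid, 1540)
  expect_error(subaperture_images(stack, 3), "divisible")
  subs <- subaperture_images(stack, 4) # 8 channels -> 4 groups of 2
  expect_equal(dim(subs), c(16L, 16L, 4L))
  full <- das_from_stack(stack)
  expect_equal(rowSums(subs, dims = 2), full, tolerance = 1e-12)
  # full-size example: 16 subapertures of 8 elements -> 32 channels
  ex <- fix_example()
  st <- apply_receive_delays(demodulate(ex$raw), fix_grid())
  iq <- subaperture_beamform(st)
  expect_equal(dim(iq$values)[3], 32L)
  sub16 <- subaperture_images(st)
  expect_equal(dim(sub16)[3], 16L)
  expect_equal(rowSums(sub16, dims = 2), das_from_stack(st),
               tolerance = 1e-9)
})

test_that("log compression and display scaling follow the 60 dB map", {
  img <- matrix(c(1, 0.1, 1e-3, 1e-5), 2, 2)
  db <- envelope_log_compress(img)
  expect_equal(db[1, 1], 0)
  expect_equal(db[2, 1], -20)
  expect_equal(db[1, 2], -60)
  expect_equal(db[2, 2], -60) # clipped at the floor
  expect_error(envelope_log_compress(matrix(0, 2, 2)), "all-zero")
  i_n <- normalize_log(db)
  expect_equal(unclass(i_n)[, 1], c(1, 2 / 3))
  expect_equal(normalize_log(matrix(-30, 1, 1))[1, 1], 0.5)
  expect_error(normalize_log(matrix(-61, 1, 1)), "dynamic_range")
  # round trip: inverse of the display map recovers the dB image
  expect_equal(60 * (unclass(i_n) - 1), unclass(db), ignore_attr = TRUE)
})

test_that("enhancement zeroes the cyst and preserves tissue", {
  ex <- fix_example()$ex
  expect_true(all(unclass(ex$e)[ex$s_t == 1] == 0))
  expect_identical(unclass(ex$e)[ex$s_t == 0], unclass(ex$i_n)[ex$s_t == 0])
  empty <- ex$s_t * 0L
  expect_equal(unclass(enhance(ex$i_n, empty)), unclass(ex$i_n),
               ignore_attr = TRUE)
  ones <- ex$s_t * 0L + 1L
  expect_true(all(unclass(enhance(ex$i_n, ones)) == 0))
  expect_error(enhance(ex$i_n, matrix(0L, 2, 2)), "match")
})
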