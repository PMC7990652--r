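test_that("probe invariants are enforced", {
  expect_s3_class(probe_config(), "pw_probe")
  expect_error(probe_config(kerf_mm = 0.10), "kerf")
  expect_error(probe_config(sampling_frequency = 20e6), "sampling_frequency")
  p <- probe_config()
  expect_equal(p$aperture_mm, 38.4)
  expect_equal(length(element_positions(p)), 128L)
  # element centers symmetric about x = 0
  expect_equal(element_positions(p), -rev(element_positions(p)))
})

test_that("phantom specs reject invalid geometry", {
  expect_error(phantom_spec(0.5, 0, 55), "radius")     # below range
  expect_error(phantom_spec(1e-9, 0, 55), "radius")    # degenerate r -> 0
  expect_error(phantom_spec(4, -18, 55), "bounds")     # clips lateral edge
  expect_error(phantom_spec(4, 0, 79), "bounds")       # clips axial edge
  expect_error(phantom_spec(4, 0, 55, sound_speed = 1700), "sound speed")
  # out-of-range radius allowed when the training-range guard is off
  expect_s3_class(phantom_spec(10, 0, 55, training_range = FALSE),
                  "pw_phantom_spec")
})

test_that("make_phantom zeroes anechoic scatterers and is deterministic", {
  spec <- phantom_spec(4, -8, 55, 1540, seed = 3, echogenicity_scale = 0,
                       n_scatterers = 5000)
  f1 <- make_phantom(spec)
  f2 <- make_phantom(spec)
  expect_identical(f1, f2) # bitwise reproducible
  inside <- (f1$x_mm - spec$x_mm)^2 + (f1$z_mm - spec$z_mm)^2 <= spec$r_mm^2
  expect_true(all(f1$amplitude[inside] == 0))
  expect_true(all(f1$amplitude[!inside] != 0))
  expect_equal(length(f1$x_mm), 5000L)
  expect_true(all(f1$x_mm >= -20 & f1$x_mm <= 20))
  expect_true(all(f1$z_mm >= 30 & f1$z_mm <= 80))
  # scaled echogenicity multiplies the same base amplitudes
  f05 <- make_phantom(modifyList(spec, list(echogenicity_scale = 0.5)))
  expect_equal(f05$amplitude[inside] * 2,
               make_phantom(modifyList(spec, list(echogenicity_scale = 1))
                            )$amplitude[inside])
})

test_that("single scatterer arrives at the round-trip time", {
  probe <- fix_probe()
  spec <- phantom_spec(2, 0, 55, 1500, seed = 1, n_scatterers = 1)
  field <- make_phantom(spec)
  field$x_mm <- 0; field$z_mm <- 30; field$amplitude <- 1
  raw <- simulate_plane_wave(field, probe, sound_speed = 1500)
  # channel nearest the axis: t = z/c + dist/c ~ 2*0.030/1500 = 40 us
  ch <- which.min(abs(element_positions(probe)))
  env <- hilbert_envelope(raw$samples[, ch])
  t_peak <- (which.max(env) - 1) / raw$sampling_frequency
  d_elem <- sqrt((element_positions(probe)[ch] * 1e-3)^2 + 0.030^2)
  t_true <- 0.030 / 1500 + d_elem / 1500
  expect_lt(abs(t_peak - t_true), 1.5 / raw$sampling_frequency)
})

test_that("mirrored fields give channel-reversed data", {
  probe <- fix_probe()
  spec <- phantom_spec(3, -6, 50, 1540, seed = 21, n_scatterers = 2000)
  f <- make_phantom(spec)
  raw <- simulate_plane_wave(f, probe)
  fm <- f
  fm$x_mm <- -f$x_mm
  raw_m <- simulate_plane_wave(fm, probe)
  expect_equal(raw_m$samples,
               raw$samples[, rev(seq_len(128)), drop = FALSE],
               tolerance = 1e-12)
  # an on-axis symmetric field is flip-invariant
  # construct an exactly symmetric field: mirror every scatterer
  fs <- f
  fs$x_mm <- c(f$x_mm, -f$x_mm)
  fs$z_mm <- c(f$z_mm, f$z_mm)
  fs$amplitude <- c(f$amplitude, f$amplitude)
  raw_s <- simulate_plane_wave(fs, probe)
  expect_equal(raw_s$samples,
               raw_s$samples[, rev(seq_len(128)), drop = FALSE],
               tolerance = 1e-10)
})

test_that("flip_lr is an involution and mirrors the spec", {
  raw <- fix_example()$raw
  f2 <- flip_lr(flip_lr(raw))
  expect_identical(f2$samples, raw$samples)
  expect_equal(flip_lr(raw)$spec$x_mm, -raw$spec$x_mm)
})

test_that("channel data is linear in the scatterer field", {
  probe <- fix_probe()
  spec <- phantom_spec(3, -6, 50, 1540, seed = 31, n_scatterers = 1000)
  f <- make_phantom(spec)
  idx <- seq_len(500)
  fa <- f; fa$x_mm <- f$x_mm[idx]; fa$z_mm <- f$z_mm[idx]
  fa$amplitude <- f$amplitude[idx]
  fb <- f; fb$x_mm <- f$x_mm[-idx]; fb$z_mm <- f$z_mm[-idx]
  fb$amplitude <- f$amplitude[-idx]
  s_all <- simulate_plane_wave(f, probe)$samples
  s_sum <- simulate_plane_wave(fa, probe)$samples +
    simulate_plane_wave(fb, probe)$samples
  expect_equal(s_all, s_sum, tolerance = 1e-10)
})

test_that("attenuation and spreading follow the closed-form ratio", {
  probe <- fix_probe()
  att <- 0.5
  mk <- function(z_mm) {
    f <- make_phantom(phantom_spec(2, 0, 55, 1500, seed = 1,
                                   n_scatterers = 1))
    f$x_mm <- 0; f$z_mm <- z_mm; f$amplitude <- 1
    f$spec$attenuation <- att
    f
  }
  ch <- which.min(abs(element_positions(probe)))
  peak <- function(z_mm) {
    raw <- simulate_plane_wave(mk(z_mm), probe, sound_speed = 1500)
    max(hilbert_envelope(raw$samples[, ch]))
  }
  xe <- element_positions(probe)[ch] * 1e-3
  closed_form <- function(z_mm) {
    z <- z_mm * 1e-3
    d <- sqrt(xe^2 + z^2)
    (1 / d) * 10^(-att * 4 * (z + d) * 100 / 20)
  }
  measured <- peak(60) / peak(30)
  expected <- closed_form(60) / closed_form(30)
  expect_equal(measured, expected, tolerance = 0.03)
})

test_that("ground-truth masks follow the cyst disc", {
  grid <- fix_grid()
  spec <- phantom_spec(8, -4, 55, 1540, seed = 1)
  m <- ground_truth_mask(spec, grid)
  # area matches pi r^2 within 5 % in physical units
  px_area <- diff(grid$depth_mm[1:2]) * diff(grid$line_mm[1:2])
  expect_equal(sum(m) * px_area, pi * 64, tolerance = 0.05)
  # mirrored spec gives the mirrored mask (symmetric grid)
  mf <- ground_truth_mask(flip_spec(spec), grid)
  expect_identical(mf, m[, rev(seq_len(ncol(m)))])
  # a cyst outside the imaged span yields an all-zero mask
  shallow <- image_grid(fix_probe(), d = 32L, depth_mm = c(30, 38))
  expect_identical(sum(ground_truth_mask(spec, shallow)), 0L)
})

test_that("tissue-only simulation produces fully developed speckle", {
  tis <- fix_tissue()
  env <- Mod(tis$img)
  roi <- env[25:40, 20:108] # away from edges, mid depth
  snr_env <- mean(roi) / sd(roi)
  expect_gt(snr_env, 1.7)
  expect_lt(snr_env, 2.1)
})

test_that("example containers round-trip through disk", {
  d <- withr::local_tempdir()
  ex <- list(i_d = array(1:8, c(2, 2, 2)), meta = data.frame(radius_mm = 3))
  p <- write_example(ex, file.path(d, "ex.rds"))
  expect_identical(read_example(p), ex)
  mf <- write_manifest(data.frame(file = p, radius_mm = 3),
                       file.path(d, "manifest.csv"))
  expect_identical(read.csv(mf)$radius_mm, 3L)
})
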