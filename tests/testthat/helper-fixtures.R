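# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# standard probe / grid used across tests
fix_probe <- function() memo("probe", probe_config())
fix_grid <- function() memo("grid", image_grid(fix_probe(), d = 64L))

# one simulated anechoic-cyst example, fully processed
fix_example <- function() memo("example", {
  spec <- phantom_spec(4, -8, 55, 1540, seed = 11)
  raw <- simulate_plane_wave(make_phantom(spec), fix_probe())
  list(spec = spec, raw = raw,
       ex = process_example(raw, fix_grid()))
})

# a tissue-only (echogenicity 1) acquisition for speckle statistics
fix_tissue <- function() memo("tissue", {
  spec <- phantom_spec(4, -8, 55, 1540, seed = 12, echogenicity_scale = 1)
  raw <- simulate_plane_wave(make_phantom(spec), fix_probe())
  bb <- demodulate(raw)
  list(spec = spec, raw = raw, bb = bb,
       img = das_beamform(bb, fix_grid()))
})

# toy 8-element probe + tiny grid for brute-force beamforming oracles
fix_toy <- function() memo("toy", {
  probe <- probe_config(num_elements = 8L, pitch_mm = 0.30,
                        sampling_frequency = 40e6)
  grid <- structure(list(d = 16L, w = 16L,
                         depth_mm = seq(30, 40, length.out = 16),
                         line_mm = seq(-2.25, 2.25, length.out = 16),
                         span_mm = c(30, 40)),
                    class = "pw_grid")
  set.seed(42)
  n_time <- 4000L
  bb <- structure(list(
    values = matrix(complex(real = rnorm(n_time * 8),
                            imaginary = rnorm(n_time * 8)), n_time, 8),
    sampling_frequency = probe$sampling_frequency, t_start = 0,
    f_demod = probe$center_frequency, probe = probe,
    sound_speed = 1540), class = "pw_baseband")
  list(probe = probe, grid = grid, bb = bb)
})

# brute-force per-pixel delay-and-sum reference (independent of the
# package's C++ path): plain R loops with the same physical definition
das_bruteforce <- function(bb, grid, sound_speed) {
  elem <- element_positions(bb$probe) * 1e-3
  fs <- bb$sampling_frequency
  out <- matrix(0 + 0i, grid$d, grid$w)
  for (l in seq_len(grid$w)) {
    xl <- grid$line_mm[l] * 1e-3
    for (di in seq_len(grid$d)) {
      z <- grid$depth_mm[di] * 1e-3
      acc <- 0 + 0i
      for (e in seq_along(elem)) {
        t <- z / sound_speed +
          sqrt((xl - elem[e])^2 + z^2) / sound_speed
        u <- (t - bb$t_start) * fs + 1
        iu <- floor(u)
        if (iu >= 1 && iu < nrow(bb$values)) {
          frac <- u - iu
          v <- bb$values[iu, e] * (1 - frac) + bb$values[iu + 1, e] * frac
          acc <- acc + v * exp(2i * pi * bb$f_demod * t)
        }
      }
      out[di, l] <- acc
    }
  }
  out
}

# analytic (Hilbert) envelope of a real vector, via FFT
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  Mod(fft(X * h, inverse = TRUE) / n)
}
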