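#' Simulate single plane-wave channel data
#'
#' A 0-degree plane wave insonifies the scatterer field; each receive
#' channel records the superposition over scatterers of a
#' Gaussian-windowed sinusoid at the transmit frequency arriving at
#' `t = z_s / c + dist(scatterer, element) / c`, with amplitude scaled
#' by the scatterer reflectivity, 1/dist geometric spreading, and
#' two-way attenuation `10^(-attenuation * f_tx[MHz] * path[cm] / 20)`.
#' The pulse's -6 dB spectral width matches the probe's fractional
#' bandwidth at its center frequency; its support is bounded by
#' `pulse_cycles` periods of the transmit frequency.
#'
#' Elements are ideal points (no directivity, no apodization); the
#' simulation is 2-D in-plane, which is representative for cylindrical
#' targets.
#'
#' @param field a [make_phantom()] scatterer field.
#' @param probe a [probe_config()].
#' @param sound_speed m/s; defaults to the spec's value.
#' @param attenuation dB/(cm*MHz); defaults to the spec's value.
#' @return a `pw_raw` object: `samples` (n_time x n_channels),
#'   `sampling_frequency`, `t_start`, `probe`, `sound_speed`.
#' @export
simulate_plane_wave <- function(field, probe,
                                sound_speed = field$spec$sound_speed,
                                attenuation = field$spec$attenuation) {
  stopifnot(inherits(field, "pw_scatterers"), inherits(probe, "pw_probe"))
  if (sound_speed <= 0) stop("sound speed must be positive")
  if (probe$sampling_frequency <= 2 * probe$center_frequency)
    stop("sampling frequency violates Nyquist for the center frequency")
  bounds <- field$spec$bounds_z_mm
  if (any(field$z_mm < bounds[1] - 1e-9) || any(field$z_mm > bounds[2] + 1e-9))
    stop("scatterers outside the phantom axial bounds")
  fs <- probe$sampling_frequency
  half_width <- probe$pulse_cycles / (2 * probe$transmit_frequency)
  t_max <- 2 * bounds[2] * 1e-3 / sound_speed + 2 * half_width
  n_time <- as.integer(ceiling(t_max * fs)) + 1L
  samples <- cpp_simulate_plane_wave(
    field$x_mm * 1e-3, field$z_mm * 1e-3, field$amplitude,
    element_positions(probe) * 1e-3,
    sound_speed, fs, probe$transmit_frequency,
    pulse_sigma_t(probe), half_width, attenuation,
    0.0, n_time)
  structure(list(samples = samples,
                 sampling_frequency = fs,
                 t_start = 0.0,
                 probe = probe,
                 sound_speed = sound_speed,
                 attenuation = attenuation,
                 spec = field$spec),
            class = "pw_raw")
}

#' Mirror channel data across the x = 0 axis
#'
#' Reverses the receive-channel order, which for a symmetric array is
#' exactly the acquisition of the laterally mirrored scene. An
#' involution: `flip_lr(flip_lr(x))` is identical to `x`.
#'
#' @param raw a `pw_raw` object.
#' @return the flipped `pw_raw`.
#' @export
flip_lr <- function(raw) {
  stopifnot(inherits(raw, "pw_raw"))
  raw$samples <- raw$samples[, rev(seq_len(ncol(raw$samples))), drop = FALSE]
  if (!is.null(raw$spec)) raw$spec <- flip_spec(raw$spec)
  raw$flipped <- !isTRUE(raw$flipped)
  raw
}

#' @export
print.pw_raw <- function(x, ...) {
  cat(sprintf("<pw_raw> %d samples x %d channels @ %.0f MHz, c = %g m/s\n",
              nrow(x$samples), ncol(x$samples),
              x$sampling_frequency / 1e6, x$sound_speed))
  invisible(x)
}

#' Write one simulated example to disk
#'
#' One file per example holding the raw channel data, ground-truth
#' mask, phantom spec and probe config (a self-describing container in
#' R's native serialization). See [read_example()].
#'
#' @param example a list as produced by the simulation/beamforming
#'   pipeline (must carry `raw` and/or derived arrays).
#' @param path output file path (`.rds`).
#' @return the path, invisibly.
#' @export
write_example <- function(example, path) {
  saveRDS(example, path)
  invisible(path)
}

#' @rdname write_example
#' @export
read_example <- function(path) readRDS(path)

#' Write a dataset manifest
#'
#' Index CSV with one row per example file and its phantom parameters.
#' @param meta data.frame of per-example parameters (must include a
#'   `file` column).
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE)
  invisible(path)
}
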