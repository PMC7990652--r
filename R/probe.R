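#' Linear-array probe configuration
#'
#' Describes the transducer used for simulation and beamforming. The
#' default matches a 128-element, 0.30 mm pitch linear array driven at
#' a 4 MHz transmit frequency with a 5.5 MHz center frequency and 0.65
#' fractional bandwidth (an L3-8-class probe). The default sampling
#' frequency is the 40 MHz hardware rate; raise it (e.g. to 100 MHz)
#' for finer time sampling.
#'
#' Elevational width/focus are carried for completeness but unused by
#' the 2-D in-plane simulator (cyst targets are cylinders, so the
#' in-plane field is representative).
#'
#' @param num_elements number of receive elements.
#' @param pitch_mm element pitch in mm.
#' @param element_width_mm element width in mm.
#' @param kerf_mm inter-element kerf in mm (`pitch - width`).
#' @param transmit_frequency transmit frequency in Hz.
#' @param sampling_frequency sampling frequency in Hz.
#' @param pulse_cycles pulse length in cycles at the transmit
#'   frequency; bounds the support of the simulated pulse envelope.
#' @param center_frequency probe center frequency in Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth (dimensionless).
#' @param elevational_width_mm,elevational_focus_mm elevation geometry
#'   in mm (informational).
#' @return an object of class `pw_probe`.
#' @export
probe_config <- function(num_elements = 128L,
                         pitch_mm = 0.30,
                         element_width_mm = 0.24,
                         kerf_mm = 0.06,
                         transmit_frequency = 4e6,
                         sampling_frequency = 40e6,
                         pulse_cycles = 4,
                         center_frequency = 5.5e6,
                         fractional_bandwidth = 0.65,
                         elevational_width_mm = 7,
                         elevational_focus_mm = 35) {
  aperture_mm <- num_elements * pitch_mm
  probe <- structure(list(
    num_elements = as.integer(num_elements),
    pitch_mm = pitch_mm,
    element_width_mm = element_width_mm,
    kerf_mm = kerf_mm,
    aperture_mm = aperture_mm,
    transmit_frequency = transmit_frequency,
    sampling_frequency = sampling_frequency,
    pulse_cycles = pulse_cycles,
    center_frequency = center_frequency,
    fractional_bandwidth = fractional_bandwidth,
    elevational_width_mm = elevational_width_mm,
    elevational_focus_mm = elevational_focus_mm
  ), class = "pw_probe")
  validate_probe(probe)
  probe
}

validate_probe <- function(probe) {
  tol <- 1e-3 # 1 um in mm
  if (abs(probe$aperture_mm - probe$num_elements * probe$pitch_mm) > tol)
    stop("probe: aperture must equal num_elements * pitch (within 1 um)")
  if (abs(probe$pitch_mm - (probe$element_width_mm + probe$kerf_mm)) > tol)
    stop("probe: pitch must equal element_width + kerf (within 1 um)")
  if (probe$sampling_frequency <= 4 * probe$center_frequency)
    stop("probe: sampling_frequency must exceed 4 * center_frequency")
  invisible(probe)
}

#' Element lateral positions
#'
#' Element centers in mm, symmetric about the array center at x = 0.
#' @param probe a [probe_config()] object.
#' @return numeric vector of length `num_elements`.
#' @export
element_positions <- function(probe) {
  n <- probe$num_elements
  (seq_len(n) - 1 - (n - 1) / 2) * probe$pitch_mm
}

# Gaussian envelope time constant (s) whose -6 dB (half-amplitude)
# spectral full width equals fractional_bandwidth * center_frequency.
pulse_sigma_t <- function(probe) {
  bw <- probe$fractional_bandwidth * probe$center_frequency
  sigma_f <- bw / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

#' @export
print.pw_probe <- function(x, ...) {
  cat(sprintf(
    "<pw_probe> %d elements, pitch %.2f mm, aperture %.1f mm\n",
    x$num_elements, x$pitch_mm, x$aperture_mm))
  cat(sprintf("  tx %.1f MHz, fc %.1f MHz, BW %.0f%%, fs %.0f MHz, %g cycles\n",
              x$transmit_frequency / 1e6, x$center_frequency / 1e6,
              100 * x$fractional_bandwidth, x$sampling_frequency / 1e6,
              x$pulse_cycles))
  invisible(x)
}
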