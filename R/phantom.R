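#' Anechoic-cyst phantom specification
#'
#' A single cylindrical (in-plane: circular) cyst of radius `r_mm`
#' centered at (`x_mm`, `z_mm`) inside a homogeneous
#' speckle-generating tissue block. The block spans the axial interval
#' `bounds_z_mm` and lateral interval `bounds_x_mm`. Scatterer
#' amplitudes inside the cyst are multiplied by `echogenicity_scale`
#' (0 = anechoic). `echogenicity_scale = 1` yields a tissue-only
#' phantom (the cyst disappears), which is useful for speckle
#' statistics checks.
#'
#' Training-regime phantoms keep `r_mm` within 2-8 mm and
#' `sound_speed` within 1420-1600 m/s; out-of-range values are
#' rejected unless `training_range = FALSE`.
#'
#' @param r_mm cyst radius in mm.
#' @param x_mm,z_mm cyst center (lateral, axial) in mm.
#' @param sound_speed medium sound speed in m/s.
#' @param attenuation depth-dependent attenuation in dB/(cm*MHz)
#'   (0 or 0.5 in the standard regimes).
#' @param n_scatterers number of random scatterers. The default
#'   100000 is the 2-D-equivalent of the classical 50000-scatterer
#'   3-D volume: collapsing the elevational dimension removes the
#'   out-of-plane scatterers that an elevation-focused beam
#'   integrates, so the in-plane density must be higher to keep
#'   enough scatterers per resolution cell for fully developed
#'   (Rayleigh) speckle.
#' @param seed RNG seed making the scatterer field reproducible.
#' @param bounds_z_mm,bounds_x_mm phantom extents in mm.
#' @param echogenicity_scale amplitude multiplier inside the cyst.
#' @param training_range enforce the training-regime parameter ranges.
#' @return an object of class `pw_phantom_spec`.
#' @export
phantom_spec <- function(r_mm, x_mm, z_mm, sound_speed = 1540,
                         attenuation = 0, n_scatterers = 100000L,
                         seed = 1L,
                         bounds_z_mm = c(30, 80),
                         bounds_x_mm = c(-20, 20),
                         echogenicity_scale = 0,
                         training_range = TRUE) {
  spec <- structure(list(
    r_mm = r_mm, x_mm = x_mm, z_mm = z_mm,
    sound_speed = sound_speed, attenuation = attenuation,
    n_scatterers = as.integer(n_scatterers), seed = as.integer(seed),
    bounds_z_mm = bounds_z_mm, bounds_x_mm = bounds_x_mm,
    echogenicity_scale = echogenicity_scale
  ), class = "pw_phantom_spec")
  validate_phantom_spec(spec, training_range)
  spec
}

validate_phantom_spec <- function(spec, training_range = TRUE) {
  with(spec, {
    if (!is.finite(r_mm) || r_mm <= 0)
      stop("phantom: cyst radius must be positive")
    if (training_range && (r_mm < 2 || r_mm > 8))
      stop("phantom: training-regime radius must lie in [2, 8] mm")
    if (training_range && (sound_speed < 1420 || sound_speed > 1600))
      stop("phantom: training-regime sound speed must lie in [1420, 1600] m/s")
    if (z_mm - r_mm < bounds_z_mm[1] || z_mm + r_mm > bounds_z_mm[2] ||
        x_mm - r_mm < bounds_x_mm[1] || x_mm + r_mm > bounds_x_mm[2])
      stop("phantom: cyst disc must lie fully inside the phantom bounds")
    if (n_scatterers < 1) stop("phantom: need at least one scatterer")
    if (!attenuation %in% c(0, 0.5) && (attenuation < 0))
      stop("phantom: attenuation must be >= 0")
  })
  invisible(spec)
}

#' Draw the scatterer field of a phantom
#'
#' Scatterer positions are uniform over the phantom bounds; amplitudes
#' are standard normal, multiplied by `echogenicity_scale` for
#' scatterers inside the cyst disc (0 = anechoic). Deterministic given
#' `spec$seed`; the caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `pw_scatterers` with `x_mm`, `z_mm`,
#'   `amplitude` and the generating `spec`.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec, training_range = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_scatterers
  x <- runif(n, spec$bounds_x_mm[1], spec$bounds_x_mm[2])
  z <- runif(n, spec$bounds_z_mm[1], spec$bounds_z_mm[2])
  a <- rnorm(n)
  inside <- (x - spec$x_mm)^2 + (z - spec$z_mm)^2 <= spec$r_mm^2
  a[inside] <- a[inside] * spec$echogenicity_scale
  structure(list(x_mm = x, z_mm = z, amplitude = a, spec = spec),
            class = "pw_scatterers")
}

#' Image grid geometry
#'
#' The display/network pixel grid: `d` depth rows spanning
#' `depth_mm` (row 1 = shallowest) and one scan line per element
#' lateral center (column 1 = most negative lateral position).
#'
#' @param probe a [probe_config()].
#' @param d number of depth rows (256 at full scale, 64 at desk scale).
#' @param depth_mm axial span in mm.
#' @return a `pw_grid` with `depth_mm` and `line_mm` axes.
#' @export
image_grid <- function(probe, d = 256L, depth_mm = c(30, 80)) {
  structure(list(
    d = as.integer(d), w = probe$num_elements,
    depth_mm = seq(depth_mm[1], depth_mm[2], length.out = d),
    line_mm = element_positions(probe),
    span_mm = depth_mm
  ), class = "pw_grid")
}

#' Ground-truth segmentation mask
#'
#' Binary mask on the image grid: 1 exactly where the pixel center
#' lies inside the cyst disc. A tissue-only phantom
#' (`echogenicity_scale = 1`) has an all-zero mask.
#'
#' @param spec a [phantom_spec()].
#' @param grid an [image_grid()].
#' @return integer matrix `d x w` of 0/1.
#' @export
ground_truth_mask <- function(spec, grid) {
  if (!is.null(spec$echogenicity_scale) && spec$echogenicity_scale == 1) {
    return(matrix(0L, grid$d, grid$w))
  }
  dz <- outer(grid$depth_mm - spec$z_mm, rep(1, grid$w))
  dx <- outer(rep(1, grid$d), grid$line_mm - spec$x_mm)
  m <- (dz^2 + dx^2 <= spec$r_mm^2) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Mirror a phantom spec across the x = 0 axis
#' @param spec a [phantom_spec()].
#' @return the spec with `x_mm` negated.
#' @export
flip_spec <- function(spec) {
  spec$x_mm <- -spec$x_mm
  spec
}
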