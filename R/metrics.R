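#' Dice similarity coefficient
#'
#' `2 |S_p & S_t| / (|S_p| + |S_t|)` after binarizing the prediction
#' at 0.5 (values > 0.5 count as cyst). Two empty masks agree
#' perfectly and score 1.
#'
#' @param s_p predicted segmentation (continuous in `[0, 1]` or
#'   binary).
#' @param s_t binary ground truth, same shape.
#' @param threshold binarization threshold for `s_p`.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(s_p, s_t, threshold = 0.5) {
  if (!all(dim(s_p) == dim(s_t))) stop("shape mismatch")
  p <- s_p > threshold
  t <- s_t > threshold
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Uncompress a log-scaled amplitude
#'
#' `s = 10^(s_dB / 20)`.
#' @param s_db amplitude(s) in dB.
#' @return linear amplitude(s).
#' @export
uncompress <- function(s_db) 10^(s_db / 20)

# Recover uncompressed amplitudes from a [0,1] display image: the
# inverse of the (I_dB + 60)/60 rescale composed with s = 10^(dB/20)
# uncompression. Pixels at the display floor map to 10^(-3).
image_amplitudes <- function(img, dynamic_range = 60) {
  uncompress(dynamic_range * (unclass(img) - 1))
}

#' Region-of-interest specification for cyst metrics
#'
#' Automates the ROI conventions: contrast/SNR use a small disc
#' (default radius 2 mm; 1.5 mm suits irregular targets) centered at
#' the cyst center with a same-size, same-depth background disc;
#' gCNR uses the full ground-truth mask with an equal-size,
#' same-depth background region. Background regions are mirrored
#' across the lateral midline, falling back to a lateral offset when
#' the mirror would touch the cyst.
#'
#' @param spec the [phantom_spec()] of the example.
#' @param grid the [image_grid()].
#' @param s_t the ground-truth mask (for the gCNR regions).
#' @param inside_radius_mm contrast/SNR inside-disc radius.
#' @return a `pw_roi` with logical matrices `inside`, `outside`,
#'   `gcnr_inside`, `gcnr_outside`.
#' @export
roi_spec <- function(spec, grid, s_t = ground_truth_mask(spec, grid),
                     inside_radius_mm = 2) {
  inside <- disc_mask(grid, spec$x_mm, spec$z_mm, inside_radius_mm)
  cyst <- disc_mask(grid, spec$x_mm, spec$z_mm, spec$r_mm)
  outside <- place_outside(inside, cyst, grid, spec)
  g_in <- s_t == 1
  g_out <- place_outside(g_in, cyst, grid, spec)
  structure(list(inside = inside, outside = outside,
                 gcnr_inside = g_in, gcnr_outside = g_out,
                 inside_radius_mm = inside_radius_mm),
            class = "pw_roi")
}

disc_mask <- function(grid, x_mm, z_mm, r_mm) {
  dz <- outer(grid$depth_mm - z_mm, rep(1, grid$w))
  dx <- outer(rep(1, grid$d), grid$line_mm - x_mm)
  dz^2 + dx^2 <= r_mm^2
}

# Same-depth background region with the same per-row pixel count as
# the target region. Preference order: lateral mirror of the region;
# a rigid lateral shift; per-row selection of the non-cyst pixels
# farthest from the cyst (for large targets near the midline where no
# rigid translate fits).
place_outside <- function(region, cyst, grid, spec) {
  mir <- region[, rev(seq_len(ncol(region))), drop = FALSE]
  if (!any(mir & cyst) && !any(mir & region)) return(mir)
  px_w <- grid$line_mm[2] - grid$line_mm[1]
  cols <- which(colSums(region) > 0)
  width <- max(cols) - min(cols) + 1
  shift <- width + ceiling(1 / px_w) # region width + 1 mm of clearance
  for (s in c(shift, -shift, 2 * shift, -2 * shift)) {
    cand <- shift_cols(region, s)
    if (sum(cand) == sum(region) && !any(cand & cyst) &&
        !any(cand & region)) return(cand)
  }
  # per-row fallback: same count per depth row, pixels farthest from
  # the cyst's lateral center among non-cyst, non-region columns
  out <- matrix(FALSE, nrow(region), ncol(region))
  for (r in which(rowSums(region) > 0)) {
    k <- sum(region[r, ])
    avail <- which(!cyst[r, ] & !region[r, ])
    if (length(avail) < k)
      stop("could not place a same-depth background region of equal size")
    ord <- avail[order(abs(grid$line_mm[avail] - spec$x_mm),
                       decreasing = TRUE)]
    out[r, ord[seq_len(k)]] <- TRUE
  }
  out
}

shift_cols <- function(m, s) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  src <- seq_len(ncol(m))
  dst <- src + s
  keep <- dst >= 1 & dst <= ncol(m)
  out[, dst[keep]] <- m[, src[keep]]
  out
}

#' Contrast between inside and outside regions
#'
#' `20 log10(S_i / S_o)` on uncompressed amplitudes recovered from the
#' `[0, 1]` display image. The 60 dB display floor bounds the
#' magnitude at 60 dB.
#' @param img a `pw_bmode` (or `[0, 1]` matrix).
#' @param roi a [roi_spec()] (or a list with `inside` / `outside`
#'   logical matrices).
#' @param dynamic_range display dynamic range in dB.
#' @return contrast in dB.
#' @export
contrast <- function(img, roi, dynamic_range = 60) {
  s <- image_amplitudes(img, dynamic_range)
  s_i <- mean(s[roi$inside])
  s_o <- mean(s[roi$outside])
  if (s_o == 0) stop("outside region has zero mean amplitude")
  20 * log10(s_i / s_o)
}

#' Background tissue signal-to-noise ratio
#'
#' `S_o / sigma_o` on uncompressed amplitudes in the outside region;
#' fully developed speckle gives ~1.91 (Rayleigh).
#' @inheritParams contrast
#' @return unitless SNR (`Inf` with a warning for a constant region).
#' @export
snr <- function(img, roi, dynamic_range = 60) {
  s <- image_amplitudes(img, dynamic_range)[roi$outside]
  if (length(s) < 2) stop("outside region too small")
  sig <- sd(s)
  if (sig == 0) {
    warning("zero-variance outside region: SNR is infinite")
    return(Inf)
  }
  mean(s) / sig
}

#' Generalized contrast-to-noise ratio
#'
#' `1 - sum_x min(p_i(x), p_o(x))` where the probability mass
#' functions of the uncompressed amplitudes inside (ground-truth cyst)
#' and outside (equal-size, same-depth) regions are estimated with a
#' shared equal-width histogram. Bounded in `[0, 1]`.
#' @inheritParams contrast
#' @param bins number of shared histogram bins.
#' @return gCNR in `[0, 1]`.
#' @export
gcnr <- function(img, roi, bins = 100, dynamic_range = 60) {
  s <- image_amplitudes(img, dynamic_range)
  si <- s[roi$gcnr_inside]
  so <- s[roi$gcnr_outside]
  if (!length(si) || !length(so)) stop("empty gCNR region")
  gcnr_samples(si, so, bins)
}

#' gCNR from raw amplitude samples
#' @param si,so amplitude samples inside / outside.
#' @param bins number of shared histogram bins.
#' @return gCNR in `[0, 1]`.
#' @export
gcnr_samples <- function(si, so, bins = 100) {
  rng <- range(c(si, so))
  if (rng[1] == rng[2]) return(0) # identical degenerate distributions
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  hi <- tabulate(findInterval(si, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins) / length(si)
  ho <- tabulate(findInterval(so, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins) / length(so)
  1 - sum(pmin(hi, ho))
}

#' Peak signal-to-noise ratio against the enhanced reference
#'
#' `10 log10(1 / MSE)` for `[0, 1]` images (the reference maximum is
#' 1). Identical images give `Inf`.
#' @param d DNN image.
#' @param e enhanced reference image, same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(d, e) {
  if (!all(dim(d) == dim(e))) stop("shape mismatch")
  mse <- mean((unclass(d) - unclass(e))^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Coefficient of variation across acquisitions
#'
#' `sd / mean * 100` (sample standard deviation).
#' @param values numeric vector (length >= 2) of a metric across
#'   repeated acquisitions.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  mu <- mean(values)
  if (mu == 0) stop("undefined CV: zero mean")
  sd(values) / mu * 100
}

#' Per-image metric bundle
#'
#' @param d DNN (or other) image under evaluation, `[0, 1]`.
#' @param s_p predicted segmentation.
#' @param s_t ground-truth mask.
#' @param e enhanced reference image (for PSNR; may be `NULL`).
#' @param roi a [roi_spec()].
#' @return a one-row data.frame with `dsc`, `contrast`, `snr`,
#'   `gcnr`, `psnr`.
#' @export
metrics_report <- function(d, s_p, s_t, e, roi) {
  data.frame(
    dsc = dsc(s_p, s_t),
    contrast = contrast(d, roi),
    snr = snr(d, roi),
    gcnr = gcnr(d, roi),
    psnr = if (is.null(e)) NA_real_ else psnr(d, e)
  )
}

#' Detection filter and per-radius detection rates
#'
#' Applies the minimum-DSC inclusion criterion (default 0.05) on a
#' designated baseline test set; the resulting inclusion flags are
#' meant to be decided once and propagated to any other test set of
#' the same examples. Also emits the per-radius detection-rate table.
#'
#' @param reports data.frame with at least `dsc` and `radius_mm`
#'   columns (one row per test image).
#' @param threshold minimum DSC for inclusion.
#' @return list with `include` (logical vector), `reports` (the
#'   included subset) and `detection` (per-radius table: total,
#'   included, rate).
#' @export
exclusion_filter <- function(reports, threshold = 0.05) {
  include <- reports$dsc >= threshold
  radii <- sort(unique(reports$radius_mm))
  detection <- do.call(rbind, lapply(radii, function(r) {
    sel <- reports$radius_mm == r
    data.frame(radius_mm = r, total = sum(sel),
               included = sum(sel & include),
               rate = sum(sel & include) / sum(sel))
  }))
  list(include = include, reports = reports[include, , drop = FALSE],
       detection = detection)
}

#' Aggregate per-image metrics by a phantom parameter
#'
#' Mean and standard deviation of each metric column grouped by a
#' phantom parameter (radius, sound speed, depth, lateral position or
#' training epoch), the shape used for trend plots.
#'
#' @param reports per-image metrics data.frame (e.g. from
#'   [evaluate_model()]).
#' @param by name of the grouping column (e.g. `"radius_mm"`).
#' @param metrics metric column names to aggregate.
#' @return data.frame with one row per group and `<metric>_mean` /
#'   `<metric>_sd` columns.
#' @export
aggregate_metrics <- function(reports, by = "radius_mm",
                              metrics = c("dsc", "contrast", "snr",
                                          "gcnr", "psnr")) {
  metrics <- intersect(metrics, names(reports))
  groups <- sort(unique(reports[[by]]))
  out <- data.frame(group = groups)
  names(out) <- by
  for (m in metrics) {
    v <- reports[[m]]
    out[[paste0(m, "_mean")]] <- vapply(groups, function(g) {
      x <- v[reports[[by]] == g & is.finite(v)]
      mean(x)
    }, 0)
    out[[paste0(m, "_sd")]] <- vapply(groups, function(g) {
      x <- v[reports[[by]] == g & is.finite(v)]
      if (length(x) > 1) sd(x) else 0
    }, 0)
  }
  out
}

#' Plot metric trends (mean +/- one standard deviation)
#'
#' Base-graphics helper for aggregate trend panels (metric versus
#' radius, sound speed, depth, lateral position or epoch).
#'
#' @param agg an [aggregate_metrics()] result.
#' @param metric metric name (without the `_mean` suffix).
#' @param xlab,main axis/title labels.
#' @return invisibly, the plotted data.
#' @export
plot_metric_trend <- function(agg, metric = "dsc", xlab = names(agg)[1],
                              main = metric) {
  x <- agg[[1]]
  m <- agg[[paste0(metric, "_mean")]]
  s <- agg[[paste0(metric, "_sd")]]
  graphics::plot(x, m, type = "b", pch = 19, ylim = range(m - s, m + s),
                 xlab = xlab, ylab = metric, main = main)
  graphics::arrows(x, m - s, x, m + s, angle = 90, code = 3,
                   length = 0.04)
  invisible(agg)
}
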