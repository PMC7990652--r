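#' Binary-thresholding segmentation configuration
#'
#' Threshold at `threshold_factor * mean(image)` (pixels below =
#' cyst), remove connected components smaller than
#' `min_component_px`, morphologically close with a disk of radius
#' `closing_radius_px`, then dilate with a disk of radius
#' `dilation_radius_px`.
#' @param threshold_factor multiple of the mean pixel value.
#' @param min_component_px minimum component area in pixels.
#' @param closing_radius_px,dilation_radius_px disk radii in pixels.
#' @param connectivity component connectivity (8 or 4).
#' @return a `pw_btconfig`.
#' @export
bt_config <- function(threshold_factor = 0.70, min_component_px = 50L,
                      closing_radius_px = 1, dilation_radius_px = 2,
                      connectivity = 8L) {
  stopifnot(threshold_factor > 0, min_component_px > 0,
            closing_radius_px > 0, dilation_radius_px > 0)
  structure(list(threshold_factor = threshold_factor,
                 min_component_px = as.integer(min_component_px),
                 closing_radius_px = closing_radius_px,
                 dilation_radius_px = dilation_radius_px,
                 connectivity = as.integer(connectivity)),
            class = "pw_btconfig")
}

#' Non-local-means configuration
#' @param search_window,comparison_window odd window widths in pixels.
#' @param degree_of_smoothing smoothing bandwidth on `[0, 1]` images.
#' @return a `pw_nlmconfig`.
#' @export
nlm_config <- function(search_window = 21L, comparison_window = 5L,
                       degree_of_smoothing = 0.1) {
  stopifnot(search_window %% 2 == 1, comparison_window %% 2 == 1,
            degree_of_smoothing > 0)
  structure(list(search_window = as.integer(search_window),
                 comparison_window = as.integer(comparison_window),
                 degree_of_smoothing = degree_of_smoothing),
            class = "pw_nlmconfig")
}

#' Binary thresholding with morphological filtering (BT)
#'
#' Classical sequential cyst segmentation of a normalized B-mode
#' image: pixels strictly below `0.70 * mean` are labelled cyst,
#' small components are discarded as false positives, gaps are closed
#' (disk radius 1) and the result dilated (disk radius 2) to counter
#' systematic under-segmentation.
#'
#' @param i_n a `pw_bmode` (or `[0, 1]` matrix).
#' @param cfg a [bt_config()].
#' @return integer 0/1 segmentation mask.
#' @export
bt_segment <- function(i_n, cfg = bt_config()) {
  img <- unclass(i_n)
  thr <- cfg$threshold_factor * mean(img)
  mask <- img < thr
  lab <- cpp_label_components(mask, cfg$connectivity)
  n <- attr(lab, "n")
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    keep <- which(sizes >= cfg$min_component_px)
    mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  }
  if (any(mask)) {
    mask <- cpp_morph_disk(mask, cfg$closing_radius_px, TRUE)  # dilate
    mask <- cpp_morph_disk(mask, cfg$closing_radius_px, FALSE) # erode
    mask <- cpp_morph_disk(mask, cfg$dilation_radius_px, TRUE)
  }
  out <- mask * 1L
  storage.mode(out) <- "integer"
  out
}

#' Non-local-means smoothing (NLM)
#'
#' Patch-based despeckling with Gaussian-weighted patch distances;
#' the configured windows bind directly to the classical algorithm's
#' search and comparison windows.
#' @param i_n a `pw_bmode` (or `[0, 1]` matrix).
#' @param cfg a [nlm_config()].
#' @return a `pw_bmode` in `[0, 1]`.
#' @export
nlm_smooth <- function(i_n, cfg = nlm_config()) {
  out <- cpp_nlm(unclass(i_n), cfg$search_window, cfg$comparison_window,
                 cfg$degree_of_smoothing)
  out <- pmin(pmax(out, 0), 1)
  bmode_image(out, role = attr(i_n, "role") %||% "das")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DAS + NLM + BT sequential pipeline
#'
#' Smooths the DAS B-mode image with non-local means, then segments
#' the smoothed image with binary thresholding + morphology.
#' @param i_n a `pw_bmode` DAS image.
#' @param nlm_cfg a [nlm_config()].
#' @param bt_cfg a [bt_config()].
#' @return list with `image` (smoothed `pw_bmode`) and `mask`.
#' @export
das_nlm_bt <- function(i_n, nlm_cfg = nlm_config(), bt_cfg = bt_config()) {
  sm <- nlm_smooth(i_n, nlm_cfg)
  list(image = sm, mask = bt_segment(sm, bt_cfg))
}
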