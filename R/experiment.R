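#' Desk-scale experiment profile
#'
#' The scaled-down counterpart of the full-scale regime, sized for a
#' single CPU: 64-row grid (vs 256), base width 8 (vs 64), 100 000
#' scatterers (the 2-D-equivalent speckle density of the classical
#' 50 000-scatterer 3-D volume), 40 MHz sampling (the hardware rate),
#' 200 simulated training phantoms doubled to 400 by lateral flips
#' plus 50 test phantoms doubled to 100, radii 3-8 mm, and a short
#' Adam step schedule with a correspondingly larger step size (5e-3
#' for 20 epochs then 1e-3 for 6, about 650 minibatch iterations,
#' versus 1e-5 for 27 625 iterations at full scale). The step sizes
#' compensate for the iteration budget; the full-scale 1e-5 recipe
#' cannot move a fresh network measurably in a few hundred
#' iterations.
#'
#' @param seed master seed.
#' @return list of profile settings.
#' @export
desk_profile <- function(seed = 1L) {
  list(
    probe = probe_config(),            # 40 MHz hardware sampling rate
    grid_d = 64L,
    base_width = 8L,
    n_scatterers = 100000L,
    n_train_phantoms = 200L,           # doubled by flips -> 400
    n_test_phantoms = 50L,             # doubled by flips -> 100
    radii_mm = c(3, 4, 6, 8),
    epochs = 26L,
    batch_size = 16L,
    # step schedule: 20 epochs at 5e-3, then 6 fine-tuning epochs at 1e-3
    learning_rate = c(rep(5e-3, 20), rep(1e-3, 6)),
    seed = as.integer(seed)
  )
}

# Table-style phantom parameter grids: sound speed 1420-1600 m/s in
# 10 m/s steps, lateral center -16..0 mm in 2 mm steps, axial center
# 40-70 mm in 2.5 mm steps.
phantom_parameter_grids <- function() {
  list(c = seq(1420, 1600, by = 10),
       x = seq(-16, 0, by = 2),
       z = seq(40, 70, by = 2.5))
}

#' Generate a simulated dataset
#'
#' Draws phantom parameters from the standard grids (sound speed
#' 1420-1600 m/s, lateral center -16 to 0 mm, axial center 40-70 mm),
#' simulates single plane-wave channel data, and runs the full
#' processing pipeline. With `flip = TRUE` every acquisition is also
#' mirrored across x = 0 (channel-order reversal), doubling the set
#' and introducing right-sided cysts.
#'
#' @param n_phantoms number of simulated phantoms (before flips).
#' @param radii_mm cyst radii to sample from.
#' @param seed master seed; per-phantom seeds are derived from it.
#' @param probe a [probe_config()].
#' @param grid an [image_grid()].
#' @param attenuation `"off"` (0), `"on"` (0.5 dB/cm-MHz) or
#'   `"both"` (alternating halves).
#' @param flip also include the mirrored acquisitions.
#' @param n_scatterers scatterers per phantom.
#' @param focused also compute 32-channel subaperture inputs.
#' @param keep_raw also retain the raw channel data of every
#'   acquisition (memory-hungry; intended for small exports).
#' @param verbose print progress.
#' @return list with `x` (`(d, w, q, N)` normalized inputs), `e`,
#'   `s`, `i_n` (`(d, w, N)`), optionally `x_fds`, `meta`
#'   (per-example parameters), `grid`, `probe`.
#' @export
generate_dataset <- function(n_phantoms, radii_mm = c(3, 4, 6, 8),
                             seed = 1L, probe = probe_config(),
                             grid = image_grid(probe, d = 64L),
                             attenuation = c("off", "on", "both"),
                             flip = TRUE, n_scatterers = 100000L,
                             focused = FALSE, keep_raw = FALSE,
                             verbose = FALSE) {
  attenuation <- match.arg(attenuation)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  grids <- phantom_parameter_grids()
  pseeds <- sample.int(.Machine$integer.max - 1L, n_phantoms)
  radius <- sample(radii_mm, n_phantoms, replace = TRUE)
  # lateral centers are drawn conditionally on the radius so the cyst
  # disc stays inside the +/-20 mm phantom (the corner combinations of
  # the full parameter grids would clip the phantom edge)
  x_of_r <- vapply(radius, function(r) {
    ok <- grids$x[grids$x - r >= -20]
    ok[sample.int(length(ok), 1L)]
  }, 0)
  params <- data.frame(
    radius_mm = radius,
    x_mm = x_of_r,
    z_mm = sample(grids$z, n_phantoms, replace = TRUE),
    c = sample(grids$c, n_phantoms, replace = TRUE),
    attenuation = switch(attenuation,
                         off = rep(0, n_phantoms),
                         on = rep(0.5, n_phantoms),
                         both = rep(c(0, 0.5), length.out = n_phantoms)),
    seed = pseeds)

  n_out <- n_phantoms * (1L + flip)
  q <- 2L
  x <- array(0, c(grid$d, grid$w, q, n_out))
  x_fds <- if (focused) array(0, c(grid$d, grid$w, 32L, n_out))
  e <- array(0, c(grid$d, grid$w, n_out))
  s <- array(0, c(grid$d, grid$w, n_out))
  i_n <- array(0, c(grid$d, grid$w, n_out))
  raws <- if (keep_raw) vector("list", n_out)
  meta <- NULL
  k <- 0L
  for (i in seq_len(n_phantoms)) {
    spec <- phantom_spec(params$radius_mm[i], params$x_mm[i],
                         params$z_mm[i], params$c[i],
                         attenuation = params$attenuation[i],
                         n_scatterers = n_scatterers,
                         seed = params$seed[i])
    raw <- simulate_plane_wave(make_phantom(spec), probe)
    ex <- process_example(raw, grid, focused = focused)
    for (v in seq_len(1L + flip)) {
      k <- k + 1L
      if (keep_raw) raws[[k]] <- if (v == 1L) raw else flip_lr(raw)
      if (v == 1L) {
        x[, , , k] <- ex$i_d$values
        if (focused) x_fds[, , , k] <- ex$i_fds$values
        e[, , k] <- unclass(ex$e)
        s[, , k] <- ex$s_t
        i_n[, , k] <- unclass(ex$i_n)
      } else if (focused) {
        # subaperture channel grouping does not commute with a plain
        # column mirror, so flipped focused inputs are reprocessed
        exf <- process_example(flip_lr(raw), grid, focused = TRUE)
        x[, , , k] <- exf$i_d$values
        x_fds[, , , k] <- exf$i_fds$values
        e[, , k] <- unclass(exf$e)
        s[, , k] <- exf$s_t
        i_n[, , k] <- unclass(exf$i_n)
      } else {
        # channel-order reversal mirrors every pipeline stage (the
        # deterministic chain is flip-equivariant), so the flipped
        # acquisition's representations are the mirrored arrays
        rc <- rev(seq_len(grid$w))
        x[, , , k] <- ex$i_d$values[, rc, , drop = FALSE]
        e[, , k] <- unclass(ex$e)[, rc]
        s[, , k] <- ex$s_t[, rc]
        i_n[, , k] <- unclass(ex$i_n)[, rc]
      }
      meta <- rbind(meta, data.frame(
        phantom = i, flipped = v == 2L,
        radius_mm = params$radius_mm[i],
        x_mm = if (v == 2L) -params$x_mm[i] else params$x_mm[i],
        z_mm = params$z_mm[i], c = params$c[i],
        attenuation = params$attenuation[i], seed = params$seed[i]))
    }
    if (verbose && i %% 25 == 0)
      message(sprintf("simulated %d / %d phantoms", i, n_phantoms))
  }
  out <- list(x = x, e = e, s = s, i_n = i_n, meta = meta,
              grid = grid, probe = probe)
  if (focused) out$x_fds <- x_fds
  if (keep_raw) out$raw <- raws
  out
}

#' Evaluate a trained model on a dataset
#'
#' Runs batched inference and computes the per-image metric bundle
#' for both the DNN outputs and the DAS reference images, using the
#' automated ROI conventions.
#'
#' @param model a trained `pw_model`.
#' @param data a [generate_dataset()] result.
#' @param batch_size inference batch size.
#' @return data.frame: per-image DNN metrics (`dsc`, `contrast`,
#'   `snr`, `gcnr`, `psnr`), DAS reference metrics (`das_*`), and the
#'   phantom parameters.
#' @export
evaluate_model <- function(model, data, batch_size = 16L) {
  n <- dim(data$x)[4]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    pred <- infer(model, data$x[, , , idx, drop = FALSE])
    for (j in seq_along(idx)) {
      i <- idx[j]
      spec_i <- phantom_spec(data$meta$radius_mm[i], data$meta$x_mm[i],
                             data$meta$z_mm[i], data$meta$c[i],
                             seed = data$meta$seed[i])
      s_t <- matrix(data$s[, , i], data$grid$d, data$grid$w)
      roi <- roi_spec(spec_i, data$grid, s_t = s_t)
      d_img <- if (!is.null(pred$d)) pred$d[, , j] else data$i_n[, , i]
      rep_i <- metrics_report(d_img, pred$s_p[, , j], s_t,
                              matrix(data$e[, , i], nrow(s_t)), roi)
      das_img <- data$i_n[, , i]
      rep_i$das_contrast <- contrast(das_img, roi)
      rep_i$das_snr <- snr(das_img, roi)
      rep_i$das_gcnr <- gcnr(das_img, roi)
      out <- rbind(out, cbind(rep_i, data$meta[i, , drop = FALSE]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Experiment configuration
#'
#' Bundles every knob of a full run; round-trips losslessly through
#' JSON ([write_experiment_config()] / [read_experiment_config()]).
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @param attenuation training regime (`"off"`, `"on"`, `"both"`).
#' @param profile a [desk_profile()]-style list.
#' @return a `pw_expconfig`.
#' @export
experiment_config <- function(out_dir, seed = 1L,
                              attenuation = c("off", "on", "both"),
                              profile = desk_profile(seed)) {
  attenuation <- match.arg(attenuation)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 attenuation = attenuation, profile = profile),
            class = "pw_expconfig")
}

#' @rdname experiment_config
#' @param config a `pw_expconfig`.
#' @param path JSON path.
#' @export
write_experiment_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$profile$probe <- unclass(cfg$profile$probe)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$profile$probe <- do.call(probe_config, within(
    as.list(cfg$profile$probe), rm(aperture_mm)))
  cfg$profile$radii_mm <- as.numeric(cfg$profile$radii_mm)
  structure(cfg, class = "pw_expconfig")
}

#' Run a full experiment
#'
#' Dataset generation, training (one model per attenuation regime;
#' the `"both"` regime trains three models with equal iteration
#' counts), test-set inference, metric tables and detection rates.
#' Every artifact is stamped with the config hash and seed.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return list of artifact paths and the in-memory results.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pw_expconfig"))
  p <- config$profile
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  write_experiment_config(config, cfg_path)
  stamp <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                seed = config$seed)

  grid <- image_grid(p$probe, d = p$grid_d)
  train_data <- generate_dataset(p$n_train_phantoms, p$radii_mm,
                                 seed = config$seed, probe = p$probe,
                                 grid = grid,
                                 attenuation = config$attenuation,
                                 n_scatterers = p$n_scatterers,
                                 verbose = verbose)
  test_data <- generate_dataset(p$n_test_phantoms, p$radii_mm,
                                seed = config$seed + 1L, probe = p$probe,
                                grid = grid,
                                attenuation = config$attenuation,
                                n_scatterers = p$n_scatterers,
                                verbose = verbose)

  regimes <- if (config$attenuation == "both")
    list(combined = seq_len(dim(train_data$x)[4]),
         attenuated = which(train_data$meta$attenuation > 0),
         nonattenuated = which(train_data$meta$attenuation == 0))
  else list(all = seq_len(dim(train_data$x)[4]))

  iters <- ceiling(dim(train_data$x)[4] / p$batch_size) * p$epochs
  models <- list(); metrics <- list(); paths <- list(config = cfg_path)
  for (rg in names(regimes)) {
    idx <- regimes[[rg]]
    sub <- list(x = train_data$x[, , , idx, drop = FALSE],
                e = train_data$e[, , idx, drop = FALSE],
                s = train_data$s[, , idx, drop = FALSE])
    model <- build_fcnn(network_spec(base_width = p$base_width),
                        seed = config$seed)
    # equal iteration budget across regimes: subsets need more epochs,
    # and the per-epoch learning-rate schedule is stretched so that
    # every regime sees the same rate profile over iterations
    iters_per_epoch <- max(1L, ceiling(length(idx) / p$batch_size))
    n_epochs <- ceiling(iters / iters_per_epoch)
    lr_base <- rep(p$learning_rate, length.out = p$epochs)
    lr_sched <- lr_base[pmax(1L, ceiling(seq_len(n_epochs) *
                                           p$epochs / n_epochs))]
    cfg <- train_config(epochs = n_epochs,
                        batch_size = p$batch_size,
                        learning_rate = lr_sched,
                        seed = config$seed, max_iterations = iters,
                        verbose = verbose)
    model <- train(model, sub, cfg)
    models[[rg]] <- model
    mp <- file.path(config$out_dir, sprintf("model_%s.rds", rg))
    save_model(model, mp)
    paths[[paste0("model_", rg)]] <- mp

    rep <- evaluate_model(model, test_data)
    rep$regime <- rg
    metrics[[rg]] <- rep
    mpth <- file.path(config$out_dir, sprintf("metrics_%s.csv", rg))
    write.csv(rep, mpth, row.names = FALSE)
    paths[[paste0("metrics_", rg)]] <- mpth
  }

  primary <- metrics[[1]]
  filt <- exclusion_filter(primary)
  det_path <- file.path(config$out_dir, "detection.csv")
  write.csv(filt$detection, det_path, row.names = FALSE)
  paths$detection <- det_path

  summ <- lapply(metrics, function(m) {
    inc <- m[filt$include, , drop = FALSE]
    list(n = nrow(m), n_included = nrow(inc),
         dsc = mean(inc$dsc), gcnr = mean(inc$gcnr),
         contrast = mean(inc$contrast), snr = mean(inc$snr),
         psnr = mean(inc$psnr[is.finite(inc$psnr)]))
  })
  summ_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(c(stamp, summ), summ_path, auto_unbox = TRUE,
                       digits = NA)
  paths$summary <- summ_path

  list(paths = paths, models = models, metrics = metrics,
       detection = filt$detection, include = filt$include,
       test_data = test_data, stamp = stamp)
}

#' Inference timing report
#'
#' Repeats a fixed-size minibatch through the model and reports the
#' total time divided by the total number of images, plus the implied
#' frame rate. Numbers are machine-local and not comparable across
#' hardware.
#'
#' @param model a trained `pw_model`.
#' @param batch a `(d, w, q, n)` input batch.
#' @param repeats number of times the batch is pushed through.
#' @return list with `seconds_per_image`, `frame_rate_hz`, `n_images`.
#' @export
timing_report <- function(model, batch, repeats = 3L) {
  infer(model, batch) # warm-up
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(repeats)) infer(model, batch)
  dt <- proc.time()[["elapsed"]] - t0
  n <- dim(batch)[4] * repeats
  list(seconds_per_image = dt / n, frame_rate_hz = n / dt, n_images = n)
}
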