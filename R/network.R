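bn_eps <- 1e-5

#' Dual-decoder fully convolutional network specification
#'
#' A U-Net-style architecture with a single VGG-13-pattern encoder
#' (ten 3x3 convolutions, each followed by batch normalization and a
#' rectified-linear activation, interleaved with four 2x2 max-pools)
#' and one or two mirrored decoders (2x2 transposed-convolution
#' upsampling, skip concatenations from the encoder at matched scales,
#' nine convolutional layers each, sigmoid output head). With two
#' decoders the first head produces the B-mode-like image `D` and the
#' second the segmentation map `S_p`; with one decoder only `S_p` is
#' produced (the classical single-decoder U-Net baseline).
#'
#' Stage feature widths follow the VGG-13 doubling pattern
#' `(1, 2, 4, 8, 8) * base_width`; `base_width = 64` reproduces the
#' full-scale channel counts, `base_width = 8` is the desk-scale
#' setting.
#'
#' @param input_channels 2 (unfocused IQ), 32 (subaperture) or 1
#'   (B-mode input for the baseline U-Net).
#' @param n_decoders 1 or 2.
#' @param base_width stage-1 feature width.
#' @return a `pw_netspec`.
#' @export
network_spec <- function(input_channels = 2L, n_decoders = 2L,
                         base_width = 64L) {
  if (!input_channels %in% c(1L, 2L, 32L))
    stop("input_channels must be 1, 2 or 32")
  if (!n_decoders %in% c(1L, 2L)) stop("n_decoders must be 1 or 2")
  structure(list(
    input_channels = as.integer(input_channels),
    n_decoders = as.integer(n_decoders),
    base_width = as.integer(base_width),
    widths = as.integer(base_width * c(1, 2, 4, 8, 8)),
    encoder_conv_layers = 10L,
    decoder_conv_layers = 9L
  ), class = "pw_netspec")
}

decoder_names <- function(spec) {
  if (spec$n_decoders == 2L) c("img", "seg") else "seg"
}

new_conv_param <- function(cin, cout, k, bn = TRUE) {
  w <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             c(k, k, cin, cout))
  p <- list(w = w, b = numeric(cout))
  if (bn) {
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
    p$rmean <- numeric(cout)
    p$rvar <- rep(1, cout)
  }
  p
}

#' Build the network
#'
#' Allocates and He-initializes all trainable parameters. Deterministic
#' given `seed` (the caller's RNG state is preserved).
#'
#' @param spec a [network_spec()].
#' @param seed initialization seed.
#' @return a `pw_model` holding `spec`, `params` and `seed`.
#' @export
build_fcnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pw_netspec"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  w <- spec$widths
  params <- list()
  put <- function(name, p) {
    for (f in names(p)) params[[paste0(name, ".", f)]] <<- p[[f]]
  }
  cin <- spec$input_channels
  for (s in 1:5) {
    put(sprintf("enc%da", s), new_conv_param(cin, w[s], 3))
    put(sprintf("enc%db", s), new_conv_param(w[s], w[s], 3))
    cin <- w[s]
  }
  for (dec in decoder_names(spec)) {
    prev <- w[5]
    for (s in 4:1) {
      up <- list(w = array(rnorm(4 * prev * w[s], sd = sqrt(2 / (4 * prev))),
                           c(2, 2, prev, w[s])),
                 b = numeric(w[s]))
      put(sprintf("%s.up%d", dec, s), up)
      put(sprintf("%s.conv%da", dec, s), new_conv_param(2 * w[s], w[s], 3))
      put(sprintf("%s.conv%db", dec, s), new_conv_param(w[s], w[s], 3))
      prev <- w[s]
    }
    put(paste0(dec, ".out"), new_conv_param(w[1], 1L, 3, bn = FALSE))
  }
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "pw_model")
}

#' @export
print.pw_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<pw_model> %d-channel input, %d decoder(s), base width %d, %s params\n",
    x$spec$input_channels, x$spec$n_decoders, x$spec$base_width,
    format(np, big.mark = ",")))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass. x: (H, W, C, N). Returns heads and (if training) the
# cache needed for backprop plus fresh batch-norm statistics.
fcnn_forward <- function(model, x, training = FALSE) {
  P <- model$params
  spec <- model$spec
  d <- dim(x)
  if (length(d) != 4) stop("input must be a (H, W, C, N) array")
  if (d[3] != spec$input_channels)
    stop(sprintf("input has %d channels; the network expects %d",
                 d[3], spec$input_channels))
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("input spatial dims must be divisible by 16")
  cache <- if (training) new.env(parent = emptyenv())
  bn_stats <- list()

  cb <- function(name, xin) {
    z <- nn_conv_fw(xin, P[[paste0(name, ".w")]], P[[paste0(name, ".b")]])
    if (training) {
      r <- nn_bn_fw(z, P[[paste0(name, ".gamma")]],
                    P[[paste0(name, ".beta")]], bn_eps, TRUE)
      y <- r$y
      cache[[name]] <- list(x = xin, z = z, mean = r$mean,
                            invstd = r$invstd, y = y)
      bn_stats[[name]] <<- list(mean = r$mean,
                                var = 1 / r$invstd^2 - bn_eps)
      y
    } else {
      nn_relu_fw(nn_bn_apply(z, P[[paste0(name, ".gamma")]],
                             P[[paste0(name, ".beta")]],
                             P[[paste0(name, ".rmean")]],
                             P[[paste0(name, ".rvar")]], bn_eps))
    }
  }

  skips <- vector("list", 4)
  h <- x
  for (s in 1:5) {
    h <- cb(sprintf("enc%da", s), h)
    h <- cb(sprintf("enc%db", s), h)
    if (s < 5) {
      skips[[s]] <- h
      pr <- nn_pool_fw(h)
      if (training) cache[[sprintf("pool%d", s)]] <-
          list(idx = pr$idx, H = dim(h)[1], W = dim(h)[2])
      h <- pr$y
    }
  }
  bottleneck <- h

  heads <- list()
  for (dec in decoder_names(spec)) {
    h <- bottleneck
    for (s in 4:1) {
      upn <- sprintf("%s.up%d", dec, s)
      up <- nn_upconv_fw(h, P[[paste0(upn, ".w")]], P[[paste0(upn, ".b")]])
      if (training) cache[[upn]] <- list(x = h)
      cc <- nn_cat_channels(up, skips[[s]])
      h <- cb(sprintf("%s.conv%da", dec, s), cc)
      h <- cb(sprintf("%s.conv%db", dec, s), h)
    }
    outn <- paste0(dec, ".out")
    z <- nn_conv_fw(h, P[[paste0(outn, ".w")]], P[[paste0(outn, ".b")]])
    y <- sigmoid(z)
    if (training) cache[[outn]] <- list(x = h, y = y)
    heads[[dec]] <- y
  }
  list(heads = heads, cache = cache, bn_stats = bn_stats)
}

# Backward pass. ghead: list of gradients w.r.t. the sigmoid outputs
# (same shapes). Returns the gradient list aligned with model$params.
fcnn_backward <- function(model, cache, ghead) {
  P <- model$params
  spec <- model$spec
  grads <- list()

  cb_bw <- function(name, gy, need_gx = TRUE) {
    cc <- cache[[name]]
    bn <- nn_bn_bw(cc$z, gy, P[[paste0(name, ".gamma")]], cc$mean,
                   cc$invstd, cc$y)
    grads[[paste0(name, ".gamma")]] <<- bn$ggamma
    grads[[paste0(name, ".beta")]] <<- bn$gbeta
    cv <- nn_conv_bw(cc$x, P[[paste0(name, ".w")]], bn$gx, need_gx)
    grads[[paste0(name, ".w")]] <<- cv$gw
    grads[[paste0(name, ".b")]] <<- cv$gb
    cv$gx
  }

  gskips <- vector("list", 4)
  gbott <- NULL
  for (dec in decoder_names(spec)) {
    gz <- ghead[[dec]]
    outn <- paste0(dec, ".out")
    oc <- cache[[outn]]
    gz <- gz * oc$y * (1 - oc$y) # through the sigmoid
    cv <- nn_conv_bw(oc$x, P[[paste0(outn, ".w")]], gz)
    grads[[paste0(outn, ".w")]] <- cv$gw
    grads[[paste0(outn, ".b")]] <- cv$gb
    gh <- cv$gx
    for (s in 1:4) {
      gh <- cb_bw(sprintf("%s.conv%db", dec, s), gh)
      gcc <- cb_bw(sprintf("%s.conv%da", dec, s), gh)
      sp <- nn_split_channels(gcc, spec$widths[s])
      gup <- sp$a
      gskips[[s]] <- if (is.null(gskips[[s]])) sp$b else gskips[[s]] + sp$b
      upn <- sprintf("%s.up%d", dec, s)
      uv <- nn_upconv_bw(cache[[upn]]$x, P[[paste0(upn, ".w")]], gup)
      grads[[paste0(upn, ".w")]] <- uv$gw
      grads[[paste0(upn, ".b")]] <- uv$gb
      gh <- uv$gx
    }
    gbott <- if (is.null(gbott)) gh else gbott + gh
  }

  gh <- gbott
  for (s in 5:1) {
    if (s < 5) {
      pc <- cache[[sprintf("pool%d", s)]]
      gh <- nn_pool_bw(gh, pc$idx, pc$H, pc$W)
      gh <- gh + gskips[[s]]
    }
    gh <- cb_bw(sprintf("enc%db", s), gh)
    gh <- cb_bw(sprintf("enc%da", s), gh, need_gx = s > 1)
  }
  grads
}

#' Run inference
#'
#' Maps a normalized input grid (or a batch) through the trained
#' network. Both outputs lie in (0, 1) and share the input's spatial
#' shape.
#'
#' @param model a trained `pw_model`.
#' @param input a `pw_iqgrid`, a `d x w x q` array, a `pw_bmode`
#'   (1-channel baseline) or a 4-d `(d, w, q, n)` batch.
#' @return for a single input, a list with `d` (a `pw_bmode`, role
#'   `"dnn"`; `NULL` for single-decoder models) and `s_p` (continuous
#'   segmentation matrix); for a batch, a list of `d` and `s_p` arrays
#'   `(H, W, N)` in input order.
#' @export
infer <- function(model, input) {
  stopifnot(inherits(model, "pw_model"))
  single <- TRUE
  if (inherits(input, "pw_iqgrid")) {
    if (!isTRUE(input$normalized))
      stop("network input must be normalized (see normalize_input)")
    x <- input$values
  } else if (inherits(input, "pw_bmode")) {
    x <- array(unclass(input), c(dim(input), 1L))
  } else {
    x <- input
  }
  if (length(dim(x)) == 3) {
    dim(x) <- c(dim(x), 1L)
  } else if (length(dim(x)) == 4) {
    single <- FALSE
  } else stop("input must be a d x w x q array or (d, w, q, n) batch")

  fw <- fcnn_forward(model, x, training = FALSE)
  sp <- fw$heads$seg
  dd <- fw$heads$img
  if (single) {
    list(d = if (!is.null(dd)) bmode_image(dd[, , 1, 1], role = "dnn"),
         s_p = sp[, , 1, 1])
  } else {
    list(d = if (!is.null(dd)) array(dd, dim(dd)[c(1, 2, 4)]),
         s_p = array(sp, dim(sp)[c(1, 2, 4)]))
  }
}

#' Mean absolute error image loss
#'
#' Mean over the minibatch of the per-image mean absolute pixel
#' difference between predicted and enhanced reference images.
#' @param d,e arrays of identical shape (`H x W` or `H x W x N`).
#' @return scalar loss.
#' @export
l1_loss <- function(d, e) {
  if (!all(dim(d) == dim(e))) stop("shape mismatch")
  mean(abs(d - e))
}

#' Soft Dice segmentation loss
#'
#' Per image, `1 - (2 |S_p . S_t| + eps) / (|S_p| + |S_t| + eps)` with
#' soft (sum) intersection and cardinalities, averaged over the
#' minibatch. The smoothing constant guards the empty-mask 0/0 case.
#' @param s_p continuous predictions in `[0, 1]`.
#' @param s_t binary ground truth, same shape.
#' @param smooth smoothing constant.
#' @return scalar loss.
#' @export
dsc_loss <- function(s_p, s_t, smooth = 1e-6) {
  if (!all(dim(s_p) == dim(s_t))) stop("shape mismatch")
  if (length(dim(s_p)) == 2) {
    dim(s_p) <- c(dim(s_p), 1L)
    dim(s_t) <- dim(s_p)
  }
  n <- dim(s_p)[3]
  tot <- 0
  for (i in seq_len(n)) {
    p <- s_p[, , i]; t <- s_t[, , i]
    tot <- tot + 1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
  }
  tot / n
}

#' Joint training loss
#'
#' Unweighted sum of [l1_loss()] and [dsc_loss()] (both weights 1).
#' @param d,e predicted and enhanced reference images.
#' @param s_p,s_t predicted and true segmentations.
#' @param smooth Dice smoothing constant.
#' @return scalar loss.
#' @export
total_loss <- function(d, e, s_p, s_t, smooth = 1e-6) {
  l1_loss(d, e) + dsc_loss(s_p, s_t, smooth)
}

#' Training configuration
#'
#' Defaults follow the reference regime: Adam, learning rate 1e-5,
#' 25 epochs, minibatch 16, equal loss weights. Desk-scale runs use a
#' larger learning rate and far fewer iterations (see
#' [desk_profile()]).
#'
#' @param epochs passes over the training set.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size; a vector is recycled over
#'   epochs (a simple step schedule, e.g. `c(rep(5e-3, 20),
#'   rep(1e-3, 6))`).
#' @param seed master seed (data order + any augmentation).
#' @param max_iterations optional hard cap on minibatch iterations,
#'   used to equalize iteration counts across training regimes.
#' @param smooth Dice smoothing constant.
#' @param checkpoint_dir optional directory for per-epoch checkpoints.
#' @param verbose print per-epoch losses.
#' @return a `pw_trainconfig`.
#' @export
train_config <- function(epochs = 25L, batch_size = 16L,
                         learning_rate = 1e-5, seed = 1L,
                         max_iterations = NULL, smooth = 1e-6,
                         checkpoint_dir = NULL, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 max_iterations = max_iterations, smooth = smooth,
                 checkpoint_dir = checkpoint_dir, verbose = verbose),
            class = "pw_trainconfig")
}

#' Train the network
#'
#' Minibatch Adam on the joint loss (image L1 + soft Dice for
#' dual-decoder models; soft Dice alone for the single-decoder
#' baseline). Deterministic given the config seed. Batch-norm running
#' statistics are tracked with momentum 0.1 for inference.
#'
#' @param model a [build_fcnn()] model.
#' @param data list with `x` (`(H, W, C, N)` input batch), `e`
#'   (`(H, W, N)` enhanced targets; may be `NULL` for single-decoder
#'   models) and `s` (`(H, W, N)` binary masks).
#' @param config a [train_config()].
#' @return the trained model, with a `log` data frame (per-epoch mean
#'   losses) and `iterations` attached.
#' @export
train <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "pw_model"))
  x <- data$x
  if (is.null(x) || length(dim(x)) != 4 || dim(x)[4] < 1)
    stop("empty training dataset")
  n_ex <- dim(x)[4]
  dual <- model$spec$n_decoders == 2L
  if (dual && is.null(data$e))
    stop("dual-decoder training needs enhanced targets")
  npix <- prod(dim(x)[1:2])

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  m_state <- list(); v_state <- list()
  lr_epoch <- rep(config$learning_rate, length.out = config$epochs)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  iter <- 0L
  log <- NULL

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_epoch[epoch]
    ord <- sample.int(n_ex)
    ep_losses <- c(); ep_l1 <- c(); ep_dsc <- c()
    for (start in seq(1, n_ex, by = config$batch_size)) {
      if (!is.null(config$max_iterations) && iter >= config$max_iterations)
        break
      idx <- ord[start:min(start + config$batch_size - 1, n_ex)]
      nb <- length(idx)
      xb <- x[, , , idx, drop = FALSE]
      sb <- data$s[, , idx, drop = FALSE]

      fw <- fcnn_forward(model, xb, training = TRUE)
      ghead <- list()
      loss_l1 <- 0
      if (dual) {
        eb <- data$e[, , idx, drop = FALSE]
        dpred <- fw$heads$img
        diff <- dpred - array(eb, dim(dpred))
        loss_l1 <- mean(abs(diff))
        ghead$img <- sign(diff) / (nb * npix)
      }
      sp <- fw$heads$seg
      gsp <- array(0, dim(sp))
      loss_dsc <- 0
      sm <- config$smooth
      for (i in seq_len(nb)) {
        p <- sp[, , 1, i]; tt <- sb[, , i]
        sden <- sum(p) + sum(tt) + sm
        snum <- 2 * sum(p * tt) + sm
        loss_dsc <- loss_dsc + 1 - snum / sden
        gsp[, , 1, i] <- -(2 * tt * sden - snum) / (sden^2 * nb)
      }
      loss_dsc <- loss_dsc / nb
      ghead$seg <- gsp

      grads <- fcnn_backward(model, fw$cache, ghead)

      # batch-norm running statistics, momentum 0.1
      for (nm in names(fw$bn_stats)) {
        model$params[[paste0(nm, ".rmean")]] <-
          0.9 * model$params[[paste0(nm, ".rmean")]] + 0.1 * fw$bn_stats[[nm]]$mean
        model$params[[paste0(nm, ".rvar")]] <-
          0.9 * model$params[[paste0(nm, ".rvar")]] + 0.1 * fw$bn_stats[[nm]]$var
      }

      iter <- iter + 1L
      bc1 <- 1 - b1^iter; bc2 <- 1 - b2^iter
      for (nm in names(grads)) {
        g <- grads[[nm]]
        if (is.null(m_state[[nm]])) {
          m_state[[nm]] <- g * 0
          v_state[[nm]] <- g * 0
        }
        m_state[[nm]] <- b1 * m_state[[nm]] + (1 - b1) * g
        v_state[[nm]] <- b2 * v_state[[nm]] + (1 - b2) * g * g
        model$params[[nm]] <- model$params[[nm]] -
          lr * (m_state[[nm]] / bc1) / (sqrt(v_state[[nm]] / bc2) + aeps)
      }
      ep_losses <- c(ep_losses, loss_l1 + loss_dsc)
      ep_l1 <- c(ep_l1, loss_l1)
      ep_dsc <- c(ep_dsc, loss_dsc)
    }
    if (length(ep_losses)) {
      log <- rbind(log, data.frame(epoch = epoch, iterations = iter,
                                   loss = mean(ep_losses),
                                   l1 = mean(ep_l1), dsc = mean(ep_dsc)))
      if (config$verbose)
        message(sprintf("epoch %d: loss %.4f (l1 %.4f, dsc %.4f), iter %d",
                        epoch, mean(ep_losses), mean(ep_l1),
                        mean(ep_dsc), iter))
    }
    if (!is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE,
                 recursive = TRUE)
      save_model(model, file.path(config$checkpoint_dir,
                                  sprintf("epoch_%03d.rds", epoch)))
    }
    if (!is.null(config$max_iterations) && iter >= config$max_iterations)
      break
  }
  model$log <- log
  model$iterations <- iter
  model$train_config <- config
  model
}

#' Save / load a model checkpoint
#'
#' Weights plus a JSON sidecar describing the architecture, training
#' configuration and seed.
#' @param model a `pw_model`.
#' @param path checkpoint path (`.rds`); the sidecar is written next
#'   to it with extension `.json`.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(spec = unclass(model$spec), seed = model$seed,
                  iterations = model$iterations)
  if (!is.null(model$train_config))
    sidecar$train_config <- Filter(Negate(is.null),
                                   unclass(model$train_config))
  jsonlite::write_json(sidecar, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
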