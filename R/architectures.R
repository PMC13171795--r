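# Compact CNN classifiers: [optional PI feature layer] -> 2x2 conv stages
# (stride 1, asymmetric zero padding to preserve even dims, ReLU, 2x2
# max-pool between stages) -> 1x1 projection to 2 logits -> global average
# pooling -> softmax over {benign, malignant}. No dense/flatten layers.

#' Model configuration
#'
#' @param variant `"plain"` (no PI layer) or one of `"manual_before"`,
#'   `"manual_mid"`, `"auto_before"`, `"auto_mid"`.
#' @param conv_layers number of convolution stages (3, 4 or 5).
#' @param pic_after_layer stage index after which the PI layer is inserted;
#'   0 means input-side. Defaults: 0 for `*_before`, 1 for `*_mid` (between
#'   the first and second stages). Ignored for `"plain"`.
#' @param input_size even image side length (64 desk-scale, 512 native).
#' @param channels per-stage channel counts; default `c(16, 32, 64, 128,
#'   256)[1:conv_layers]`.
#' @param gains a [pi_gains()] for the PI layer (and, in `*_before`
#'   pipelines, the intensity preprocessor).
#' @param kernel_size PI layer filter support (odd; manual mode requires 3).
#' @param fusion PI fusion override (`"concat"`/`"sum"`); defaults to concat
#'   for input-side placement and sum mid-network.
#' @param seed integer seed for weight initialization.
#' @return a `model_config` object.
#' @export
model_config <- function(variant = c("plain", "manual_before", "manual_mid",
                                     "auto_before", "auto_mid"),
                         conv_layers = 3L,
                         pic_after_layer = NULL,
                         input_size = 64L,
                         channels = NULL,
                         gains = pi_gains(0.6, 0.05),
                         kernel_size = 3L,
                         fusion = NULL,
                         seed = 1L) {
  variant <- match.arg(variant)
  conv_layers <- as.integer(conv_layers)
  if (!conv_layers %in% 3:5) stop("conv_layers must be 3, 4 or 5")
  input_size <- as.integer(input_size)
  if (input_size %% 2L != 0L || input_size < 8L) {
    stop("input_size must be an even integer >= 8 (the minimal legal size for the conv stack)")
  }
  channels <- as.integer(channels %||% c(16L, 32L, 64L, 128L, 256L)[seq_len(conv_layers)])
  stopifnot(length(channels) == conv_layers, all(channels >= 1L))
  if (variant == "plain") {
    pic_after_layer <- NA_integer_
  } else if (endsWith(variant, "before")) {
    pic_after_layer <- 0L
  } else {
    pic_after_layer <- as.integer(pic_after_layer %||% 1L)
    if (pic_after_layer < 1L || pic_after_layer > conv_layers) {
      stop("pic_after_layer must lie in 1..conv_layers for mid placement")
    }
  }
  structure(list(variant = variant, conv_layers = conv_layers,
                 pic_after_layer = pic_after_layer, input_size = input_size,
                 channels = channels, gains = gains,
                 kernel_size = as.integer(kernel_size), fusion = fusion,
                 seed = as.integer(seed)),
            class = "model_config")
}

pic_mode_of <- function(variant) {
  if (startsWith(variant, "manual")) "manual" else if (startsWith(variant, "auto")) "auto" else NA_character_
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

make_pic_layer <- function(cfg, channels, params, pname, iname) {
  placement <- if (identical(cfg$pic_after_layer, 0L)) "before" else "mid"
  pc <- pic_layer_config(mode = pic_mode_of(cfg$variant), placement = placement,
                         gains = cfg$gains, kernel_size = cfg$kernel_size,
                         fusion = cfg$fusion,
                         seed = if (pic_mode_of(cfg$variant) == "auto") cfg$seed + 1L)
  layer <- list(type = "pic", cfg = pc, channels = channels,
                pname = pname, iname = iname)
  if (pc$mode == "manual") {
    layer$kern_p <- rep_kernel(laplacian_kernel(), channels)
    layer$kern_i <- rep_kernel(box_mean_kernel(pc$kernel_size), channels)
  }
  layer
}

#' Build a network from a configuration
#'
#' @param cfg a [model_config()].
#' @return a `picnet_model`: list with `cfg`, `layers`, and the trainable
#'   `params` (named arrays). Manual PI layers contribute no trainable
#'   parameters; auto PI layers contribute two bias-free depthwise kernel
#'   banks.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  layers <- list()
  params <- list()
  add_pic <- function(channels) {
    pname <- "pic_p"; iname <- "pic_i"
    layer <- make_pic_layer(cfg, channels, params, pname, iname)
    if (layer$cfg$mode == "auto") {
      kb <- auto_pic_init(layer$cfg, channels)
      params[[pname]] <<- kb$p
      params[[iname]] <<- kb$i
    }
    layers[[length(layers) + 1L]] <<- layer
    if (layer$cfg$fusion == "concat") 2L * channels else channels
  }
  size <- cfg$input_size
  in_ch <- 1L
  if (!is.na(cfg$pic_after_layer) && cfg$pic_after_layer == 0L) {
    if (size < cfg$kernel_size) stop("input_size smaller than the PI kernel support")
    in_ch <- add_pic(in_ch)
  }
  for (l in seq_len(cfg$conv_layers)) {
    wn <- sprintf("conv%d_w", l); bn <- sprintf("conv%d_b", l)
    params[[wn]] <- he_init(2L, 2L, in_ch, cfg$channels[l])
    params[[bn]] <- numeric(cfg$channels[l])
    layers[[length(layers) + 1L]] <- list(type = "conv", w = wn, b = bn)
    in_ch <- cfg$channels[l]
    if (l < cfg$conv_layers && size >= 8L) {
      layers[[length(layers) + 1L]] <- list(type = "maxpool")
      size <- size %/% 2L
    }
    if (!is.na(cfg$pic_after_layer) && cfg$pic_after_layer == l) {
      in_ch <- add_pic(in_ch)
    }
  }
  params$head_w <- he_init(1L, 1L, in_ch, 2L)
  params$head_b <- numeric(2L)
  layers[[length(layers) + 1L]] <- list(type = "head", w = "head_w", b = "head_b")
  structure(list(cfg = cfg, layers = layers, params = params),
            class = "picnet_model")
}

#' Number of trainable parameters
#' @param model a `picnet_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.picnet_model <- function(x, ...) {
  cat(sprintf("<picnet_model> variant=%s conv_layers=%d input=%dx%d params=%d\n",
              x$cfg$variant, x$cfg$conv_layers, x$cfg$input_size,
              x$cfg$input_size, count_parameters(x)))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

forward_model <- function(model, x4) {
  caches <- vector("list", length(model$layers))
  x <- x4
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (layer$type == "pic") {
      kp_bank <- layer$kern_p %||% model$params[[layer$pname]]
      ki_bank <- layer$kern_i %||% model$params[[layer$iname]]
      fw <- pic_layer_fwd(x, layer$cfg, kp_bank, ki_bank)
      caches[[li]] <- fw
      x <- fw$y
    } else if (layer$type == "conv") {
      xp <- cpp_pad2d(x, 0L, 1L, 0L, 1L, 0L)
      y <- cpp_relu_fwd(cpp_conv2d_fwd(xp, model$params[[layer$w]],
                                       model$params[[layer$b]]))
      caches[[li]] <- list(xp = xp, y = y, xdim = dim(x))
      x <- y
    } else if (layer$type == "maxpool") {
      mp <- cpp_maxpool2_fwd(x)
      caches[[li]] <- list(idx = mp$idx, xdim = dim(x))
      x <- mp$y
    } else { # head: 1x1 conv + global average pooling
      y <- cpp_conv2d_fwd(x, model$params[[layer$w]], model$params[[layer$b]])
      d <- dim(y)
      logits <- t(colMeans(matrix(y, d[1] * d[2], d[3] * d[4]))) # 1 x (2N)
      logits <- matrix(logits, d[4], d[3], byrow = TRUE)         # N x 2
      caches[[li]] <- list(x = x, ydim = d)
      x <- logits
    }
  }
  list(logits = x, caches = caches)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss over 2-class softmax; y in {0, 1}
loss_and_dlogits <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}

backward_model <- function(model, caches, dlogits) {
  grads <- list()
  dy <- dlogits
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    cache <- caches[[li]]
    if (layer$type == "head") {
      d <- cache$ydim
      # GAP backward: each spatial site receives dlogit / (H*W)
      dyy <- array(0, dim = d)
      scale <- 1 / (d[1] * d[2])
      for (f in seq_len(d[3])) {
        dyy[, , f, ] <- rep(dy[, f] * scale, each = d[1] * d[2])
      }
      g <- cpp_conv2d_bwd(cache$x, model$params[[layer$w]], dyy)
      grads[[layer$w]] <- g$dw
      grads[[layer$b]] <- g$db
      dy <- g$dx
    } else if (layer$type == "maxpool") {
      dy <- cpp_maxpool2_bwd(dy, cache$idx, cache$xdim)
    } else if (layer$type == "conv") {
      dy <- cpp_relu_bwd(dy, cache$y)
      need_dx <- li > 1L
      g <- cpp_conv2d_bwd(cache$xp, model$params[[layer$w]], dy, need_dx)
      grads[[layer$w]] <- g$dw
      grads[[layer$b]] <- g$db
      if (need_dx) {
        dy <- cpp_pad2d_adjoint(g$dx, cache$xdim[1], cache$xdim[2], 0L, 1L, 0L, 1L, 0L)
      }
    } else { # pic
      kp_bank <- layer$kern_p %||% model$params[[layer$pname]]
      ki_bank <- layer$kern_i %||% model$params[[layer$iname]]
      bw <- pic_layer_bwd(cache, layer$cfg, kp_bank, ki_bank, dy,
                          want_kernel_grads = layer$cfg$mode == "auto")
      if (layer$cfg$mode == "auto") {
        grads[[layer$pname]] <- bw$grads$p
        grads[[layer$iname]] <- bw$grads$i
      }
      dy <- bw$dx
    }
  }
  grads
}

#' Class probabilities and hard labels for a batch of images
#'
#' Deterministic given fixed weights. The hard label is the argmax class,
#' with an exact tie broken toward benign (the conservative call).
#'
#' @param object a `picnet_model`.
#' @param images a [labeled_image_set()], a list of matrices, or an
#'   (H, W, 1, N) array matching `cfg$input_size`.
#' @param ... unused.
#' @return data frame with `prob_benign`, `prob_malignant`, `label`.
#' @export
predict.picnet_model <- function(object, images, ...) {
  x4 <- if (is.array(images) && length(dim(images)) == 4L) images else as_batch_array(images)
  if (dim(x4)[1] != object$cfg$input_size || dim(x4)[2] != object$cfg$input_size) {
    stop(sprintf("images are %dx%d but the model expects %dx%d",
                 dim(x4)[1], dim(x4)[2], object$cfg$input_size, object$cfg$input_size))
  }
  p <- softmax_rows(forward_model(object, x4)$logits)
  data.frame(prob_benign = p[, 1], prob_malignant = p[, 2],
             label = as.integer(p[, 2] > p[, 1]))
}
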