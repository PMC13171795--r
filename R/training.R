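# Training loop: softmax cross-entropy (the 2-logit equivalent of binary
# cross-entropy), minibatch updates under Adam / SGD / momentum / PI,
# plateau learning-rate reduction and early stopping on validation loss.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, learning rate 1e-3, weight
#' decay 1e-4, batch size 32, at most 50 epochs, plateau LR reduction by a
#' factor 0.1, early stopping after 10 epochs without validation improvement.
#'
#' @param epochs maximum number of epochs (0 returns the model untrained).
#' @param batch_size minibatch size.
#' @param optimizer one of `"adam"`, `"sgd"`, `"momentum"`, `"pi"`.
#' @param lr learning rate (for `"pi"` this is the proportional gain `kp`).
#' @param weight_decay L2 coefficient added to every gradient.
#' @param lr_factor,lr_patience plateau scheduler: multiply `lr` by
#'   `lr_factor` after `lr_patience` epochs without validation improvement.
#' @param early_stopping epochs without validation improvement before
#'   stopping (`Inf` disables).
#' @param optimizer_args extra optimizer settings: `beta` (momentum, default
#'   0.9), `beta1`/`beta2`/`eps` (Adam), `ki` and `anti_windup` (PI).
#' @param restore_best restore the best-validation weights after training.
#' @param seed RNG seed for shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, optimizer = "adam",
                         lr = 1e-3, weight_decay = 1e-4, lr_factor = 0.1,
                         lr_patience = 5L, early_stopping = 10L,
                         optimizer_args = list(), restore_best = TRUE,
                         seed = 1L) {
  optimizer <- match.arg(optimizer, c("adam", "sgd", "momentum", "pi"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = optimizer, lr = lr, weight_decay = weight_decay,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 early_stopping = early_stopping,
                 optimizer_args = optimizer_args,
                 restore_best = isTRUE(restore_best), seed = as.integer(seed)),
            class = "train_config")
}

opt_init <- function(name, params, args) {
  zeros <- lapply(params, function(p) p * 0)
  switch(name,
         sgd = list(),
         momentum = list(v = zeros, beta = args$beta %||% 0.9),
         adam = list(m = zeros, v = zeros, t = 0L,
                     beta1 = args$beta1 %||% 0.9, beta2 = args$beta2 %||% 0.999,
                     eps = args$eps %||% 1e-8),
         pi = list(integral = zeros, ki = args$ki %||% 0.05,
                   anti_windup = args$anti_windup))
}

opt_update <- function(name, params, grads, st, lr) {
  nm <- names(params)
  if (name == "sgd") {
    for (k in nm) params[[k]] <- params[[k]] - lr * grads[[k]]
  } else if (name == "momentum") {
    for (k in nm) {
      st$v[[k]] <- st$beta * st$v[[k]] + grads[[k]]
      params[[k]] <- params[[k]] - lr * st$v[[k]]
    }
  } else if (name == "adam") {
    st$t <- st$t + 1L
    bc1 <- 1 - st$beta1^st$t
    bc2 <- 1 - st$beta2^st$t
    for (k in nm) {
      st$m[[k]] <- st$beta1 * st$m[[k]] + (1 - st$beta1) * grads[[k]]
      st$v[[k]] <- st$beta2 * st$v[[k]] + (1 - st$beta2) * grads[[k]]^2
      params[[k]] <- params[[k]] -
        lr * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + st$eps)
    }
  } else { # pi: exact integral of all past gradients, kp = lr
    for (k in nm) {
      st$integral[[k]] <- st$integral[[k]] + grads[[k]]
      if (!is.null(st$anti_windup)) {
        cl <- st$anti_windup
        st$integral[[k]] <- pmin(pmax(st$integral[[k]], -cl), cl)
      }
      params[[k]] <- params[[k]] - lr * grads[[k]] - st$ki * st$integral[[k]]
    }
  }
  list(params = params, state = st)
}

eval_batched <- function(model, x4, y, batch_size = 64L) {
  n <- dim(x4)[4]
  total_loss <- 0
  correct <- 0L
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    xb <- x4[, , , idx, drop = FALSE]
    fw <- forward_model(model, xb)
    ld <- loss_and_dlogits(fw$logits, y[idx])
    total_loss <- total_loss + ld$loss * length(idx)
    pred <- as.integer(ld$probs[, 2] > ld$probs[, 1])
    correct <- correct + sum(pred == y[idx])
  }
  list(loss = total_loss / n, acc = correct / n)
}

#' Train a model on train/validation splits
#'
#' @param model a `picnet_model` from [build_model()].
#' @param data list with elements `train` and `val`, each either a
#'   [labeled_image_set()] or a list `(x, y)` with `x` an (H, W, 1, N) array
#'   and `y` integer labels.
#' @param cfg a [train_config()].
#' @param .val_loss_fn internal diagnostic hook: a `function(epoch)` whose
#'   value replaces the measured validation loss, used to exercise the
#'   scheduler and early-stopping logic in isolation.
#' @return list with `model` (trained), `history` (one data-frame row per
#'   epoch: losses, accuracies, learning rate), and `stopped_epoch`.
#' @export
train_model <- function(model, data, cfg = train_config(), .val_loss_fn = NULL) {
  stopifnot(inherits(model, "picnet_model"), inherits(cfg, "train_config"))
  unpack <- function(d) {
    if (inherits(d, "labeled_image_set")) list(x = as_batch_array(d), y = d$labels)
    else d
  }
  tr <- unpack(data$train)
  va <- if (!is.null(data$val)) unpack(data$val)
  if (length(unique(tr$y)) < 2L) stop("training split contains a single class")
  history <- data.frame()
  if (cfg$epochs == 0L) {
    return(list(model = model, history = history, stopped_epoch = 0L))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  lr <- cfg$lr
  ost <- opt_init(cfg$optimizer, model$params, cfg$optimizer_args)
  n <- dim(tr$x)[4]
  best_val <- Inf
  best_params <- NULL
  since_improve <- 0L
  since_lr <- 0L
  stopped <- cfg$epochs
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample(n)
    ep_loss <- 0
    ep_correct <- 0L
    for (s in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- tr$y[idx]
      fw <- forward_model(model, xb)
      ld <- loss_and_dlogits(fw$logits, yb)
      if (!is.finite(ld$loss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      }
      grads <- backward_model(model, fw$caches, ld$dlogits)
      if (cfg$weight_decay > 0) {
        for (k in names(grads)) grads[[k]] <- grads[[k]] + cfg$weight_decay * model$params[[k]]
      }
      upd <- opt_update(cfg$optimizer, model$params, grads, ost, lr)
      model$params <- upd$params
      ost <- upd$state
      ep_loss <- ep_loss + ld$loss * length(idx)
      ep_correct <- ep_correct + sum(as.integer(ld$probs[, 2] > ld$probs[, 1]) == yb)
    }
    val_loss <- NA_real_
    val_acc <- NA_real_
    if (!is.null(.val_loss_fn)) {
      val_loss <- .val_loss_fn(epoch)
    } else if (!is.null(va)) {
      ve <- eval_batched(model, va$x, va$y)
      val_loss <- ve$loss
      val_acc <- ve$acc
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = val_loss, val_acc = val_acc, lr = lr))
    if (!is.na(val_loss)) {
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss
        if (cfg$restore_best && is.null(.val_loss_fn)) best_params <- model$params
        since_improve <- 0L
        since_lr <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_lr <- since_lr + 1L
        if (since_lr >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          since_lr <- 0L
        }
        if (since_improve >= cfg$early_stopping) {
          stopped <- epoch
          break
        }
      }
    }
    stopped <- epoch
  }
  if (!is.null(best_params)) model$params <- best_params
  list(model = model, history = history, stopped_epoch = stopped)
}

#' Apply closed-loop intensity regulation to every image in a set
#'
#' @param ds a [labeled_image_set()].
#' @param gains a [pi_gains()].
#' @param tolerance early-stopping tolerance, see [regulate_intensity()].
#' @return the regulated `labeled_image_set` (role preserved).
#' @export
preprocess_intensity <- function(ds, gains, tolerance = 1e-3) {
  stopifnot(inherits(ds, "labeled_image_set"))
  imgs <- lapply(ds$images, function(im) regulate_intensity(im, gains, tolerance)$image)
  labeled_image_set(imgs, ds$labels, metadata = ds$metadata, role = attr(ds, "role"))
}

#' Evaluate a trained model on a labelled set
#'
#' @param model a `picnet_model`.
#' @param ds a [labeled_image_set()].
#' @return list with `predictions` (from [predict.picnet_model()]),
#'   `counts` (a [confusion_counts()]), and `metrics`.
#' @export
evaluate_model <- function(model, ds) {
  stopifnot(inherits(ds, "labeled_image_set"))
  pred <- predict(model, ds)
  cc <- confusion_from_predictions(ds$labels, pred$label)
  list(predictions = pred, counts = cc, metrics = classification_metrics(cc))
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model as a single JSON checkpoint
#'
#' The checkpoint is one JSON file holding a manifest (configuration, the
#' name and shape of every kernel bank / parameter array) plus the flattened
#' parameter values at full precision.
#'
#' @param model a `picnet_model`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `picnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$cfg
  manifest <- list(
    variant = cfg$variant, conv_layers = cfg$conv_layers,
    pic_after_layer = cfg$pic_after_layer, input_size = cfg$input_size,
    channels = cfg$channels,
    gains = list(kp = cfg$gains$kp, ki = cfg$gains$ki,
                 target_intensity = cfg$gains$target_intensity,
                 max_iterations = cfg$gains$max_iterations),
    kernel_size = cfg$kernel_size, fusion = cfg$fusion, seed = cfg$seed,
    params = lapply(model$params, function(p) dim(p) %||% length(p)))
  payload <- list(manifest = manifest,
                  values = lapply(model$params, function(p) as.numeric(p)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- payload$manifest
  cfg <- model_config(variant = m$variant, conv_layers = m$conv_layers,
                      pic_after_layer = if (!is.na(m$pic_after_layer) && m$pic_after_layer > 0) m$pic_after_layer,
                      input_size = m$input_size, channels = m$channels,
                      gains = pi_gains(m$gains$kp, m$gains$ki,
                                       m$gains$target_intensity,
                                       m$gains$max_iterations),
                      kernel_size = m$kernel_size,
                      fusion = if (length(m$fusion)) m$fusion,
                      seed = m$seed)
  model <- build_model(cfg)
  for (k in names(model$params)) {
    v <- payload$values[[k]]
    dm <- m$params[[k]]
    model$params[[k]] <- if (length(dm) > 1) array(v, dim = dm) else as.numeric(v)
  }
  model
}
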