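# Config-driven replication harness: grid search over the controller
# parameters (validation split only), the three ablation suites, and a YAML
# experiment-config loader backing the command-line interface.

#' Default controller parameter grid
#'
#' The published search space: `kp` in \{0.4, 0.6, 0.8, 1.0, 1.5\}, `ki` in
#' \{0.05, 0.1, 0.3, 0.5, 0.8\}, target intensity in \{0.5, 1.0\}, maximum
#' iterations in \{1, 5, 10\}.
#'
#' @return named list of grid values.
#' @export
default_gain_grid <- function() {
  list(kp = c(0.4, 0.6, 0.8, 1.0, 1.5),
       ki = c(0.05, 0.1, 0.3, 0.5, 0.8),
       target_intensity = c(0.5, 1.0),
       max_iterations = c(1L, 5L, 10L))
}

#' Load an experiment configuration from YAML
#'
#' Recognized top-level keys: `model` (arguments of [model_config()] with
#' `gains` as a `kp`/`ki`/`target_intensity`/`max_iterations` mapping),
#' `training` (arguments of [train_config()]), `data` (arguments of
#' [synthetic_spec()] or a `path` for [load_image_folder()]), `grid`
#' (overrides of [default_gain_grid()]), and `seed`.
#'
#' @param path YAML file path.
#' @return a named list `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$grid <- utils::modifyList(default_gain_grid(), cfg$grid %||% list())
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "experiment_config")
}

build_model_for_gains <- function(base_cfg, gains) {
  model_config(variant = base_cfg$variant, conv_layers = base_cfg$conv_layers,
               pic_after_layer = if (!is.na(base_cfg$pic_after_layer) &&
                                     base_cfg$pic_after_layer > 0L) base_cfg$pic_after_layer,
               input_size = base_cfg$input_size, channels = base_cfg$channels,
               gains = gains, kernel_size = base_cfg$kernel_size,
               fusion = base_cfg$fusion, seed = base_cfg$seed)
}

# trains one configuration end to end: optional intensity preprocessing for
# input-side placements, then the network
train_cell <- function(model_cfg, splits, train_cfg, preprocess = TRUE) {
  use_pre <- preprocess && !is.na(model_cfg$pic_after_layer) &&
    model_cfg$pic_after_layer == 0L
  prep <- function(ds) {
    if (use_pre) preprocess_intensity(ds, model_cfg$gains) else ds
  }
  model <- build_model(model_cfg)
  fit <- train_model(model, list(train = prep(splits$train), val = prep(splits$val)),
                     train_cfg)
  list(fit = fit, prep = prep)
}

#' Train one configuration end to end and evaluate on the test split
#'
#' Applies the intensity preprocessor for input-side placements (train,
#' validation and test alike), trains, and reports test metrics.
#'
#' @param model_cfg a [model_config()].
#' @param splits list with `train`, `val`, `test` sets.
#' @param train_cfg a [train_config()].
#' @param preprocess apply [preprocess_intensity()] for input-side placements.
#' @return list with `fit` (from [train_model()]), `counts`, `metrics`.
#' @export
train_and_evaluate <- function(model_cfg, splits, train_cfg, preprocess = TRUE) {
  tc <- train_cell(model_cfg, splits, train_cfg, preprocess)
  ev <- evaluate_model(tc$fit$model, tc$prep(splits$test))
  list(fit = tc$fit, counts = ev$counts, metrics = ev$metrics)
}

#' Grid search over controller parameters on the validation split
#'
#' Trains one model per (deduplicated) grid cell, ranks cells by validation
#' F1 — ties broken toward smaller `ki`, then smaller `kp` (the conservative
#' gain rule) — and only then evaluates the single winning configuration on
#' the test split. Failed cells are recorded and skipped. The run log
#' records an MD5 hash of the test split and the number of test evaluations
#' performed (always 1), so leakage is auditable.
#'
#' @param splits list with `train`, `val`, `test` [labeled_image_set()]s.
#' @param base_cfg a [model_config()] whose gains are replaced cell by cell.
#' @param train_cfg a [train_config()].
#' @param grid list like [default_gain_grid()].
#' @param preprocess apply [preprocess_intensity()] for input-side placements.
#' @return list with `table` (per-cell validation metrics), `winner` (the
#'   chosen gains), `test_metrics`, `test_counts`, and `log`.
#' @export
run_grid_search <- function(splits, base_cfg, train_cfg,
                            grid = default_gain_grid(), preprocess = TRUE) {
  if (length(splits$val) == 0) stop("validation split is empty")
  cells <- unique(expand.grid(kp = grid$kp, ki = grid$ki,
                              target_intensity = grid$target_intensity,
                              max_iterations = grid$max_iterations))
  test_hash <- tryCatch({
    tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
    saveRDS(splits$test, tf)
    unname(tools::md5sum(tf))
  }, error = function(e) NA_character_)
  rows <- list()
  fits <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    res <- tryCatch({
      gains <- suppressWarnings(pi_gains(cell$kp, cell$ki, cell$target_intensity,
                                         cell$max_iterations))
      tc <- train_cell(build_model_for_gains(base_cfg, gains), splits, train_cfg,
                       preprocess)
      ev <- evaluate_model(tc$fit$model, tc$prep(splits$val))
      fits[[ci]] <- tc
      data.frame(cell, val_f1 = ev$metrics$f1 %||% NA_real_,
                 val_accuracy = ev$metrics$accuracy, failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(cell, val_f1 = NA_real_, val_accuracy = NA_real_, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    rows[[ci]] <- res
  }
  tab <- do.call(rbind, rows)
  ok <- which(!tab$failed & !is.na(tab$val_f1))
  if (length(ok) == 0) stop("every grid cell failed")
  ord <- ok[order(-tab$val_f1[ok], tab$ki[ok], tab$kp[ok])]
  win <- ord[1]
  tc <- fits[[win]]
  ev <- evaluate_model(tc$fit$model, tc$prep(splits$test))
  list(table = tab,
       winner = tab[win, c("kp", "ki", "target_intensity", "max_iterations")],
       test_metrics = ev$metrics, test_counts = ev$counts,
       log = list(test_split_md5 = test_hash, test_evaluations = 1L,
                  cells_run = nrow(tab), cells_failed = sum(tab$failed)))
}

ablation_suites <- function() {
  c("depth_no_pic", "pic_placement", "gain_regimes")
}

#' Run one of the ablation suites
#'
#' `depth_no_pic` trains plain CNNs of depth 3, 4 and 5. `pic_placement`
#' trains manual and auto PI layers inserted after 2 and after 3 convolution
#' stages with gains pinned at (kp 0.6, ki 0.05, target 0.5, max iterations
#' 1). `gain_regimes` trains the published gain-sensitivity settings
#' (conservative, high-target, high-ki windup, high-gain, high-iteration)
#' for the chosen placements.
#'
#' @param suite one of `"depth_no_pic"`, `"pic_placement"`, `"gain_regimes"`.
#' @param splits list with `train`, `val`, `test` sets.
#' @param train_cfg a [train_config()].
#' @param input_size,seed forwarded to [model_config()].
#' @param subset optional integer vector selecting a subset of the suite's
#'   configurations (by row).
#' @param preprocess apply intensity preprocessing for input-side placements.
#' @return data frame with one row per configuration: identifying columns,
#'   confusion counts, metrics, and a 95% Wilson interval on accuracy.
#' @export
run_ablation <- function(suite, splits, train_cfg, input_size = 64L, seed = 1L,
                         subset = NULL, preprocess = TRUE) {
  if (!suite %in% ablation_suites()) {
    stop(sprintf("unknown suite '%s'; valid suites: %s", suite,
                 paste(ablation_suites(), collapse = ", ")))
  }
  configs <- switch(
    suite,
    depth_no_pic = data.frame(variant = "plain", conv_layers = c(3L, 4L, 5L),
                              pic_after = NA_integer_, kp = NA, ki = NA,
                              target = NA, max_iter = NA),
    pic_placement = expand.grid(variant = c("manual_mid", "auto_mid"),
                                conv_layers = 3L, pic_after = c(2L, 3L),
                                kp = 0.6, ki = 0.05, target = 0.5, max_iter = 1L,
                                stringsAsFactors = FALSE),
    gain_regimes = merge(
      data.frame(variant = c("manual_before", "manual_mid"), conv_layers = 3L,
                 pic_after = c(NA_integer_, 1L), stringsAsFactors = FALSE),
      data.frame(kp = c(0.6, 0.6, 0.6, 1.5, 1.0),
                 ki = c(0.05, 0.05, 0.5, 0.8, 0.05),
                 target = c(0.5, 1.0, 0.5, 0.5, 0.5),
                 max_iter = c(5L, 1L, 1L, 1L, 10L)))
  )
  if (!is.null(subset)) configs <- configs[subset, , drop = FALSE]
  rows <- list()
  for (ci in seq_len(nrow(configs))) {
    cf <- configs[ci, ]
    gains <- if (is.na(cf$kp)) pi_gains(0.6, 0.05) else {
      suppressWarnings(pi_gains(cf$kp, cf$ki, cf$target, cf$max_iter))
    }
    mc <- model_config(variant = as.character(cf$variant),
                       conv_layers = cf$conv_layers,
                       pic_after_layer = if (!is.na(cf$pic_after)) cf$pic_after,
                       input_size = input_size, gains = gains, seed = seed)
    tc <- train_cell(mc, splits, train_cfg, preprocess)
    ev <- evaluate_model(tc$fit$model, tc$prep(splits$test))
    ci95 <- wilson_ci(ev$metrics$accuracy, length(splits$test))
    rows[[ci]] <- data.frame(
      suite = suite, variant = as.character(cf$variant),
      conv_layers = cf$conv_layers, pic_after = cf$pic_after,
      kp = cf$kp, ki = cf$ki, target = cf$target, max_iter = cf$max_iter,
      tp = ev$counts$tp, tn = ev$counts$tn, fp = ev$counts$fp, fn = ev$counts$fn,
      accuracy = ev$metrics$accuracy, precision = ev$metrics$precision,
      recall = ev$metrics$recall, f1 = ev$metrics$f1,
      acc_ci_lower = ci95$lower, acc_ci_upper = ci95$upper,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
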