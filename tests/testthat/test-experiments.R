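# Grid search, ablation suites, config loading, folder IO (small fixtures).

fast_train_cfg <- function() train_config(epochs = 2, batch_size = 16, seed = 1)

small_splits <- function(n = 36, size = 32, seed = 2) {
  ds <- generate_nodule_images(synthetic_spec(n_images = n, image_size = size,
                                              seed = seed))
  split_dataset(ds, c(train = 0.6, val = 0.2, test = 0.2), seed = seed)
}

small_cfg <- function(variant = "manual_before", ...) {
  model_config(variant, input_size = 32, channels = c(4, 6, 8), seed = 1, ...)
}

test_that("grid search selects on validation only and dedupes cells", {
  sp <- small_splits()
  grid <- list(kp = c(0.6, 0.6), ki = c(0.05), target_intensity = 0.5,
               max_iterations = 1L)
  res <- run_grid_search(sp, small_cfg(), fast_train_cfg(), grid)
  expect_identical(res$log$cells_run, 1L) # duplicated cell deduplicated
  expect_identical(res$log$test_evaluations, 1L)
  expect_true(nzchar(res$log$test_split_md5))
  expect_identical(res$winner$kp, 0.6)

  # single-cell grid: winner is that cell
  grid1 <- list(kp = 0.4, ki = 0.1, target_intensity = 0.5, max_iterations = 1L)
  res1 <- run_grid_search(sp, small_cfg(), fast_train_cfg(), grid1)
  expect_identical(unlist(res1$winner),
                   c(kp = 0.4, ki = 0.1, target_intensity = 0.5, max_iterations = 1))

  # tie-break prefers the smaller ki, then smaller kp, on equal validation F1
  tab <- data.frame(kp = c(0.8, 0.4, 0.4), ki = c(0.05, 0.3, 0.05),
                    val_f1 = c(0.9, 0.9, 0.9))
  ord <- order(-tab$val_f1, tab$ki, tab$kp)
  expect_identical(ord[1], 3L)

  expect_error(run_grid_search(list(train = sp$train,
                                    val = subset_empty <- labeled_image_set(list(), integer(0)),
                                    test = sp$test),
                               small_cfg(), fast_train_cfg(), grid1),
               "validation split is empty")
})

test_that("the default grid is the published search space", {
  g <- default_gain_grid()
  expect_identical(g$kp, c(0.4, 0.6, 0.8, 1.0, 1.5))
  expect_identical(g$ki, c(0.05, 0.1, 0.3, 0.5, 0.8))
  expect_identical(g$target_intensity, c(0.5, 1.0))
  expect_identical(g$max_iterations, c(1L, 5L, 10L))
})

test_that("ablation suites run their configuration families", {
  sp <- small_splits()
  # depth suite runs exactly depths 3, 4, 5
  tab <- run_ablation("depth_no_pic", sp, fast_train_cfg(), input_size = 32)
  expect_identical(tab$conv_layers, c(3L, 4L, 5L))
  expect_true(all(tab$variant == "plain"))

  # placement suite: manual/auto after 2 and 3 conv stages, pinned gains
  tab2 <- run_ablation("pic_placement", sp, fast_train_cfg(), input_size = 32,
                       subset = 1:2)
  expect_identical(sort(unique(tab2$pic_after)), 2L)
  expect_true(all(tab2$kp == 0.6 & tab2$ki == 0.05 &
                    tab2$target == 0.5 & tab2$max_iter == 1))

  # metrics recompute from each row's own confusion counts
  for (r in seq_len(nrow(tab))) {
    cc <- confusion_counts(tab$tp[r], tab$tn[r], tab$fp[r], tab$fn[r])
    m <- classification_metrics(cc)
    expect_equal(tab$accuracy[r], m$accuracy)
    expect_equal(tab$recall[r], m$recall)
  }

  expect_error(run_ablation("bogus", sp, fast_train_cfg()), "depth_no_pic")
})

test_that("experiment configs load from YAML with grid overrides", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("model:", "  variant: manual_before", "  input_size: 32",
               "training:", "  epochs: 2",
               "grid:", "  kp: [0.4, 0.6]", "seed: 9"), path)
  cfg <- load_experiment_config(path)
  expect_identical(cfg$model$variant, "manual_before")
  expect_identical(cfg$grid$kp, c(0.4, 0.6))
  expect_identical(cfg$grid$ki, default_gain_grid()$ki) # defaults retained
  expect_identical(cfg$seed, 9L)
  unlink(path)
})

test_that("folder IO round-trips images and handles mixed inputs", {
  skip_if_not_installed("EBImage")
  skip_if_not_installed("png")
  root <- tempfile()
  ds <- generate_nodule_images(synthetic_spec(n_images = 6, image_size = 32,
                                              seed = 3))
  attr(ds, "role") <- "train"
  write_image_folder(ds, root)
  back <- load_image_folder(file.path(root, "train"), size = 32)
  expect_identical(length(back), 6L)
  expect_identical(sort(back$labels), sort(ds$labels))
  # 8-bit PNG quantization: pixels match within 1/255
  i_b <- which(back$labels == ds$labels[1])[1]
  expect_true(all(vapply(back$images, function(m) all(m >= 0 & m <= 1), TRUE)))

  # constant-white image loads as a constant 1.0 plane
  dir.create(file.path(root, "mix", "benign"), recursive = TRUE)
  dir.create(file.path(root, "mix", "malignant"), recursive = TRUE)
  write_gray_png(matrix(1, 16, 16), file.path(root, "mix", "benign", "w.png"))
  # an RGB image lands in the same folder set
  png_rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  png::writePNG(png_rgb, file.path(root, "mix", "malignant", "rgb.png"))
  mixed <- load_image_folder(file.path(root, "mix"), size = 16)
  expect_identical(length(mixed), 2L)
  expect_true(all(vapply(mixed$images, function(m) identical(dim(m), c(16L, 16L)), TRUE)))
  expect_equal(mixed$images[[which(mixed$labels == 0L)]], matrix(1, 16, 16))

  # empty directory errors with the path named
  dir.create(file.path(root, "empty", "benign"), recursive = TRUE)
  expect_error(load_image_folder(file.path(root, "empty"), 16), "benign")
  expect_error(load_image_folder(file.path(root, "nope"), 16), "does not exist")

  # file-level regulation adapter: PNG in, adjusted PNG + CSV trace out
  src <- file.path(root, "dark.png")
  write_gray_png(matrix(0.1, 16, 16), src)
  out_png <- file.path(root, "adj.png")
  out_csv <- file.path(root, "trace.csv")
  res <- regulate_image_file(src, out_png, out_csv,
                             gains = pi_gains(0.6, 0.05, 0.5, 3), tolerance = 0)
  expect_true(abs(mean(res$image) - 0.5) < abs(0.1 - 0.5))
  trace <- read.csv(out_csv)
  expect_identical(names(trace), c("iteration", "mean", "error", "integral", "signal"))
  expect_true(file.exists(out_png))
  unlink(root, recursive = TRUE)
})
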