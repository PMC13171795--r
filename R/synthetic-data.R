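# Seeded generator of CT-like grayscale nodule slices. Each image is a dark
# background with two bright lung-field ellipses and one nodule; the benign
# and malignant generators are identical except for the amplitude of a
# seeded sinusoidal radial perturbation of the nodule margin (spiculation),
# so margin roughness is the class-discriminating signal by construction.

#' Specification of a synthetic nodule dataset
#'
#' @param n_images number of images to generate.
#' @param class_fractions named proportions for `benign` and `malignant`,
#'   each in (0, 1), summing to 1.
#' @param image_size even image side length in pixels (64 is the desk-scale
#'   default; 512 matches the native CT slice size).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param intensity_jitter standard deviation of a per-image global
#'   brightness offset, emulating acquisition intensity variability.
#' @param spiculation malignant margin-perturbation amplitude in \[0, 1\];
#'   0 makes the two classes statistically indistinguishable.
#' @param heterogeneity_mode adds per-image contrast scaling and a background
#'   gradient, emulating a harder, more varied acquisition regime.
#' @param seed integer seed; identical specs generate identical datasets.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_images,
                           class_fractions = c(benign = 0.5, malignant = 0.5),
                           image_size = 64L,
                           noise_sd = 0.05,
                           intensity_jitter = 0.05,
                           spiculation = 0.6,
                           heterogeneity_mode = FALSE,
                           seed = 1L) {
  n_images <- as.integer(n_images)
  stopifnot(n_images >= 1L, length(class_fractions) == 2)
  if (is.null(names(class_fractions))) {
    names(class_fractions) <- c("benign", "malignant")
  }
  if (abs(sum(class_fractions) - 1) > 1e-8 || any(class_fractions <= 0) ||
      any(class_fractions >= 1)) {
    stop("class_fractions must lie in (0, 1) and sum to 1")
  }
  image_size <- as.integer(image_size)
  if (image_size %% 2L != 0L) stop("image_size must be even")
  if (image_size < 32L) stop("image_size too small to contain a nodule (minimum 32)")
  stopifnot(noise_sd >= 0, intensity_jitter >= 0,
            spiculation >= 0, spiculation <= 1)
  structure(list(n_images = n_images, class_fractions = class_fractions,
                 image_size = image_size, noise_sd = noise_sd,
                 intensity_jitter = intensity_jitter, spiculation = spiculation,
                 heterogeneity_mode = isTRUE(heterogeneity_mode),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Preset study conditions for the synthetic generator
#'
#' `"balanced"` is the learnability harness (equal classes); `"imbalanced"`
#' reproduces the source dataset's image-level benign:malignant ratio of
#' 120:416; `"heterogeneous"` switches on the cross-dataset variability mode.
#'
#' @param name preset name.
#' @param n_images,seed forwarded to [synthetic_spec()].
#' @param ... further overrides forwarded to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
synthetic_preset <- function(name = c("balanced", "imbalanced", "heterogeneous"),
                             n_images = 400L, seed = 1L, ...) {
  name <- match.arg(name)
  args <- list(n_images = n_images, seed = seed, ...)
  if (name == "imbalanced") {
    args$class_fractions <- c(benign = 120 / 536, malignant = 416 / 536)
  } else if (name == "heterogeneous") {
    args$heterogeneity_mode <- TRUE
  }
  do.call(synthetic_spec, args)
}

#' Labelled image set container
#'
#' @param images list of numeric matrices with values in \[0, 1\].
#' @param labels integer vector, 0 = benign, 1 = malignant.
#' @param metadata optional data frame of per-image generation parameters.
#' @param role optional split role (`"train"`, `"val"`, `"test"`); the
#'   augmentation leakage guard only accepts `"train"` sets.
#' @return a `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, metadata = NULL, role = NULL) {
  stopifnot(is.list(images), length(images) == length(labels))
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) stop("labels must be 0 (benign) or 1 (malignant)")
  structure(list(images = images, labels = labels, metadata = metadata),
            class = "labeled_image_set", role = role)
}

#' @export
length.labeled_image_set <- function(x) length(x$images)

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- if (length(x)) dim(x$images[[1]]) else c(0, 0)
  cat(sprintf("<labeled_image_set> %d images (%dx%d), benign %d / malignant %d%s\n",
              length(x), d[1], d[2], sum(x$labels == 0L), sum(x$labels == 1L),
              if (!is.null(attr(x, "role"))) paste0(", role=", attr(x, "role")) else ""))
  invisible(x)
}

subset_image_set <- function(ds, idx, role = attr(ds, "role")) {
  labeled_image_set(ds$images[idx], ds$labels[idx],
                    metadata = if (!is.null(ds$metadata)) ds$metadata[idx, , drop = FALSE],
                    role = role)
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# renders one slice; the benign/malignant difference is only `amp`
render_slice <- function(S, nodule_center, radius, amp, freqs, amps, phases,
                         brightness_offset, noise_sd, contrast = 1,
                         bg_gradient = c(0, 0)) {
  X <- matrix(seq_len(S), S, S, byrow = TRUE) # column index
  Y <- matrix(seq_len(S), S, S)               # row index
  img <- matrix(0.08, S, S)
  img <- img + bg_gradient[1] * (X / S) + bg_gradient[2] * (Y / S)
  for (cx in c(0.30 * S, 0.70 * S)) {
    q <- ((X - cx) / (0.17 * S))^2 + ((Y - 0.5 * S) / (0.32 * S))^2
    img <- img + 0.35 * smoothstep((1 - q) / 0.15 + 0.5)
  }
  dx <- X - nodule_center[1]
  dy <- Y - nodule_center[2]
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  s <- matrix(0, S, S)
  for (j in seq_along(freqs)) {
    s <- s + amps[j] * sin(freqs[j] * theta + phases[j])
  }
  s <- s / sum(abs(amps))
  r_theta <- radius * (1 + amp * s)
  img <- img + 0.45 * smoothstep((r_theta - d) / (0.24 * radius) + 0.5)
  if (contrast != 1) img <- (img - mean(img)) * contrast + mean(img)
  if (noise_sd > 0) img <- img + matrix(rnorm(S * S, 0, noise_sd), S, S)
  clip01(img + brightness_offset)
}

#' Generate a synthetic CT-like nodule dataset
#'
#' Deterministic given the spec: identical specs produce identical images.
#' Benign nodules have a smooth margin; malignant nodules share the same
#' renderer with a seeded sinusoidal radial margin perturbation of amplitude
#' `spec$spiculation`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [labeled_image_set()] whose `metadata` records every per-image
#'   generation parameter (sufficient to regenerate each image).
#' @export
generate_nodule_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_images
  S <- spec$image_size
  n_benign <- round(spec$class_fractions[["benign"]] * n)
  labels <- sample(rep(c(0L, 1L), c(n_benign, n - n_benign)))
  images <- vector("list", n)
  meta <- vector("list", n)
  for (idx in seq_len(n)) {
    side <- sample(c(0.30, 0.70), 1)
    center <- c(side * S + runif(1, -0.04, 0.04) * S,
                0.5 * S + runif(1, -0.12, 0.12) * S)
    radius <- runif(1, 0.10, 0.16) * S
    freqs <- sample(5:12, 3)
    amps <- runif(3, 0.5, 1)
    phases <- runif(3, 0, 2 * pi)
    offset <- rnorm(1, 0, spec$intensity_jitter)
    contrast <- if (spec$heterogeneity_mode) runif(1, 0.7, 1.3) else 1
    bg_grad <- if (spec$heterogeneity_mode) runif(2, -0.08, 0.08) else c(0, 0)
    amp <- if (labels[idx] == 1L) spec$spiculation else 0
    images[[idx]] <- render_slice(S, center, radius, amp, freqs, amps, phases,
                                  offset, spec$noise_sd, contrast, bg_grad)
    meta[[idx]] <- data.frame(label = labels[idx], center_x = center[1],
                              center_y = center[2], radius = radius,
                              spiculation = amp, brightness_offset = offset,
                              contrast = contrast)
  }
  labeled_image_set(images, labels, metadata = do.call(rbind, meta))
}

# ---- augmentation primitives ----------------------------------------------

#' Augmentation primitives
#'
#' `img_hflip` mirrors columns (an involution); `img_brightness` adds a
#' constant offset and clips to \[0, 1\]; `img_translate` shifts by integer
#' pixels with zero fill (positive `dx` moves content toward higher column
#' indices, positive `dy` toward higher row indices).
#'
#' @param img numeric matrix.
#' @param delta brightness offset.
#' @param dx,dy integer pixel shifts.
#' @return the transformed matrix.
#' @export
img_hflip <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' @rdname img_hflip
#' @export
img_brightness <- function(img, delta) clip01(img + delta)

#' @rdname img_hflip
#' @export
img_translate <- function(img, dx = 0L, dy = 0L) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  sr <- seq_len(H) - dy
  sc <- seq_len(W) - dx
  ok_r <- sr >= 1 & sr <= H
  ok_c <- sc >= 1 & sc <= W
  out[ok_r, ok_c] <- img[sr[ok_r], sc[ok_c]]
  out
}

#' Augment a training split
#'
#' Appends transformed copies of the training images (one copy per image per
#' op and pass). To prevent evaluation leakage only sets whose role is
#' `"train"` are accepted. With `balance = TRUE` only the minority class is
#' augmented (ops cycled) until class counts are equal, mirroring
#' augmentation used to correct class imbalance.
#'
#' @param ds a [labeled_image_set()] with role `"train"`.
#' @param ops subset of `c("hflip", "brightness", "translate")`.
#' @param seed seed for the random brightness offsets and shifts.
#' @param times number of augmentation passes over `ops`.
#' @param brightness_delta offsets are drawn uniformly from
#'   `[-brightness_delta, brightness_delta]`.
#' @param translate_max shifts are drawn uniformly from
#'   `-translate_max..translate_max` per axis.
#' @param balance augment only the minority class up to parity instead.
#' @return the augmented `labeled_image_set`.
#' @export
augment_images <- function(ds, ops = c("hflip", "brightness", "translate"),
                           seed = 1L, times = 1L, brightness_delta = 0.1,
                           translate_max = 3L, balance = FALSE) {
  stopifnot(inherits(ds, "labeled_image_set"))
  if (!identical(attr(ds, "role"), "train")) {
    stop("augmentation is restricted to the training split (leakage guard)")
  }
  ops <- match.arg(ops, several.ok = TRUE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  apply_op <- function(img, op) {
    switch(op,
           hflip = img_hflip(img),
           brightness = img_brightness(img, runif(1, -brightness_delta, brightness_delta)),
           translate = img_translate(img,
                                     dx = sample(-translate_max:translate_max, 1),
                                     dy = sample(-translate_max:translate_max, 1)))
  }
  new_images <- list()
  new_labels <- integer(0)
  if (balance) {
    minority <- if (sum(ds$labels == 0L) < sum(ds$labels == 1L)) 0L else 1L
    deficit <- abs(sum(ds$labels == 0L) - sum(ds$labels == 1L))
    pool <- which(ds$labels == minority)
    for (j in seq_len(deficit)) {
      src <- pool[(j - 1L) %% length(pool) + 1L]
      op <- ops[(j - 1L) %% length(ops) + 1L]
      new_images[[j]] <- apply_op(ds$images[[src]], op)
      new_labels[j] <- minority
    }
  } else {
    k <- 0L
    for (pass in seq_len(times)) {
      for (op in ops) {
        for (i in seq_along(ds$images)) {
          k <- k + 1L
          new_images[[k]] <- apply_op(ds$images[[i]], op)
          new_labels[k] <- ds$labels[i]
        }
      }
    }
  }
  labeled_image_set(c(ds$images, new_images), c(ds$labels, new_labels),
                    metadata = NULL, role = "train")
}

#' Stratified train/validation/test split
#'
#' Sizes are allocated by largest-remainder rounding (per class when
#' stratified, with remainder ties broken in split order train, val, test);
#' assignment within a class is a seeded permutation. Under stratification
#' every split must receive at least one image of each class, otherwise the
#' split is rejected.
#'
#' @param ds a [labeled_image_set()].
#' @param fractions named numeric vector `(train, val, test)` summing to 1.
#' @param stratified allocate per class (default `TRUE`).
#' @param seed permutation seed.
#' @return list of `labeled_image_set`s named `train`, `val`, `test`, with
#'   roles set.
#' @export
split_dataset <- function(ds, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                          stratified = TRUE, seed = 1L) {
  stopifnot(inherits(ds, "labeled_image_set"), length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")
  largest_remainder <- function(n) {
    q <- n * fractions
    base <- floor(q)
    rem <- as.integer(n - sum(base))
    if (rem > 0) {
      ord <- order(q - base, c(3, 2, 1), decreasing = TRUE) # tie: train, val, test
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    as.integer(base)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  assign_split <- integer(length(ds$labels))
  if (stratified) {
    for (cl in c(0L, 1L)) {
      idx <- which(ds$labels == cl)
      sizes <- largest_remainder(length(idx))
      if (any(sizes == 0L)) {
        stop(sprintf("class %d would receive zero samples in some split under stratification", cl))
      }
      idx <- sample(idx)
      assign_split[idx] <- rep(1:3, sizes)
    }
  } else {
    sizes <- largest_remainder(length(ds$labels))
    assign_split[sample(seq_along(ds$labels))] <- rep(1:3, sizes)
  }
  roles <- c("train", "val", "test")
  out <- lapply(1:3, function(s) subset_image_set(ds, which(assign_split == s), role = roles[s]))
  names(out) <- roles
  out
}

# stack a labeled_image_set (or list of matrices) into an (H, W, 1, N) batch
#' Convert images to the 4-d batch array consumed by the network
#' @param x a `labeled_image_set` or list of equally sized matrices.
#' @return numeric array with dim (H, W, 1, N).
#' @export
as_batch_array <- function(x) {
  imgs <- if (inherits(x, "labeled_image_set")) x$images else x
  stopifnot(length(imgs) >= 1)
  d <- dim(imgs[[1]])
  arr <- array(0, dim = c(d[1], d[2], 1L, length(imgs)))
  for (i in seq_along(imgs)) arr[, , 1L, i] <- imgs[[i]]
  arr
}
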