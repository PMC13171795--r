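# Independent reference implementations used as oracles. These are written
# against the definitions directly (plain loops, brute force), not against
# the package's compiled paths.

# scalar PI recurrence: control signals for an error sequence
oracle_pi_signals <- function(errors, kp, ki) {
  integral <- 0
  vapply(errors, function(e) {
    integral <<- integral + e
    kp * e + ki * integral
  }, numeric(1))
}

# closed-loop mean regulation of a constant image (no clipping active)
oracle_regulate_means <- function(start_mean, target, kp, ki, iters) {
  m <- start_mean
  integral <- 0
  means <- numeric(iters)
  for (t in seq_len(iters)) {
    e <- target - m
    integral <- integral + e
    m <- m + kp * e + ki * integral
    means[t] <- m
  }
  means
}

# brute-force same-size 2-D convolution with mirror (no edge repeat) padding
oracle_conv2d_reflect <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  k <- nrow(kern); p <- (k - 1) %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      acc <- 0
      for (dr in seq_len(k)) {
        for (dc in seq_len(k)) {
          rr <- refl(r + dr - 1 - p, H)
          cs <- refl(cc + dc - 1 - p, W)
          acc <- acc + kern[dr, dc] * img[rr, cs]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

# AUC as the concordant-pair fraction (Mann-Whitney identity; ties count 1/2)
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# scalar PI optimizer recurrence on L = theta^2 / 2 (gradient = theta)
oracle_pi_quadratic <- function(theta0, kp, ki, steps) {
  th <- theta0
  integral <- 0
  out <- numeric(steps)
  for (t in seq_len(steps)) {
    g <- th
    integral <- integral + g
    th <- th - kp * g - ki * integral
    out[t] <- th
  }
  out
}

# margin roughness: mean |4-neighbour Laplacian| in a ring around the margin,
# computed with plain R array shifts (no package convolution code)
oracle_margin_roughness <- function(img, cx, cy, radius) {
  H <- nrow(img); W <- ncol(img)
  lap <- matrix(0, H, W)
  ii <- 2:(H - 1); jj <- 2:(W - 1)
  lap[ii, jj] <- 4 * img[ii, jj] - img[ii - 1, jj] - img[ii + 1, jj] -
    img[ii, jj - 1] - img[ii, jj + 1]
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  d <- sqrt((X - cx)^2 + (Y - cy)^2)
  ring <- d > 0.7 * radius & d < 1.5 * radius
  mean(abs(lap[ring]))
}

# tiny deterministic image set for fast architecture tests
tiny_image_set <- function(n = 16, size = 32, seed = 3, role = "train") {
  ds <- generate_nodule_images(synthetic_spec(n_images = n, image_size = size,
                                              seed = seed))
  attr(ds, "role") <- role
  ds
}
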