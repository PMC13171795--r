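# PI feature layers: a fixed high-pass (proportional) path and a fixed
# smoothing (integral) path, or learnable depthwise kernel banks in "auto"
# mode, fused either by channel concatenation or as a residual sum. Gains
# kp/ki are fixed multipliers in both modes; only auto-mode kernels train.

#' Fixed 3x3 kernels used by the manual PI feature paths
#'
#' The proportional path uses the 4-neighbour discrete Laplacian (centre 4,
#' edge-adjacent -1, corners 0), the canonical high-pass filter; the integral
#' path uses the k x k uniform box mean, the canonical smoother.
#'
#' @param kernel_size odd kernel support (the Laplacian is defined for 3).
#' @return a numeric matrix.
#' @export
laplacian_kernel <- function(kernel_size = 3L) {
  if (kernel_size != 3L) stop("the 4-neighbour Laplacian is defined for kernel_size = 3")
  matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
}

#' @rdname laplacian_kernel
#' @export
box_mean_kernel <- function(kernel_size = 3L) {
  k <- as.integer(kernel_size)
  if (k < 1L || k %% 2L == 0L) stop("kernel_size must be an odd positive integer")
  matrix(1 / k^2, k, k)
}

# coerce to (H, W, C) array; remembers whether the input was a plain matrix
as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("feature map must be a matrix or an (H, W, C) array")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("feature map contains non-finite values")
  x
}

restore_shape <- function(y, x) if (is.matrix(x)) y[, , 1L] else y

# same-size depthwise convolution of an (H, W, C, N) batch with a per-channel
# kernel bank (kh, kw, C); reflect padding
depthwise_same <- function(x4, kern) {
  kh <- dim(kern)[1]
  if (dim(x4)[1] < kh || dim(x4)[2] < dim(kern)[2]) {
    stop("spatial dims smaller than the kernel support")
  }
  p <- (kh - 1L) %/% 2L
  xp <- cpp_pad2d(x4, p, p, p, p, 1L)
  cpp_depthwise_fwd(xp, kern)
}

depthwise_same_bwd <- function(x4, kern, dy) {
  p <- (dim(kern)[1] - 1L) %/% 2L
  xp <- cpp_pad2d(x4, p, p, p, p, 1L)
  g <- cpp_depthwise_bwd(xp, kern, dy)
  list(dx = cpp_pad2d_adjoint(g$dx, dim(x4)[1], dim(x4)[2], p, p, p, p, 1L),
       dk = g$dk)
}

rep_kernel <- function(kern, channels) {
  array(kern, dim = c(dim(kern), channels))
}

#' Manual proportional (high-pass) and integral (smoothing) filters
#'
#' Per-channel convolution with a fixed 3x3 Laplacian (`manual_p_filter`) or
#' a fixed 3x3 box mean (`manual_i_filter`), with reflect padding so spatial
#' dimensions are preserved.
#'
#' @param x a numeric matrix or an (H, W, C) array.
#' @return an array of the same shape as `x`.
#' @examples
#' manual_p_filter(matrix(1, 5, 5)) # all zeros: the Laplacian kills constants
#' @export
manual_p_filter <- function(x) {
  fm <- as_feature_map(x)
  x4 <- array(fm, dim = c(dim(fm), 1L))
  y <- depthwise_same(x4, rep_kernel(laplacian_kernel(), dim(fm)[3]))
  restore_shape(array(y, dim = dim(fm)), x)
}

#' @rdname manual_p_filter
#' @export
manual_i_filter <- function(x) {
  fm <- as_feature_map(x)
  x4 <- array(fm, dim = c(dim(fm), 1L))
  y <- depthwise_same(x4, rep_kernel(box_mean_kernel(), dim(fm)[3]))
  restore_shape(array(y, dim = dim(fm)), x)
}

#' PI feature layer configuration
#'
#' @param mode `"manual"` (fixed filters) or `"auto"` (learnable depthwise
#'   kernel banks; requires `seed`).
#' @param placement `"before"` (acts on the input image) or `"mid"` (acts on
#'   a mid-network feature map). Chooses the default fusion: concatenation
#'   before the network (the next convolution absorbs the doubled channels),
#'   residual sum mid-network (preserves channel counts).
#' @param gains a [pi_gains()] object; `kp` and `ki` scale the proportional
#'   and integral paths and stay fixed during training in both modes.
#' @param kernel_size odd filter support (manual mode requires 3).
#' @param fusion `"concat"` (stacks the two paths, doubling channels) or
#'   `"sum"` (residual: `x + p + i`). Default depends on `placement`.
#' @param seed integer initialization seed, auto mode only.
#' @return a `pic_layer_config` object.
#' @export
pic_layer_config <- function(mode = c("manual", "auto"),
                             placement = c("before", "mid"),
                             gains = pi_gains(0.6, 0.05),
                             kernel_size = 3L,
                             fusion = NULL,
                             seed = NULL) {
  mode <- match.arg(mode)
  placement <- match.arg(placement)
  stopifnot(inherits(gains, "pi_gains"))
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L) {
    stop("kernel_size must be an odd positive integer")
  }
  if (mode == "manual" && kernel_size != 3L) {
    stop("manual mode uses the fixed 3x3 filter pair")
  }
  fusion <- fusion %||% if (placement == "before") "concat" else "sum"
  if (!fusion %in% c("concat", "sum")) {
    stop(sprintf("unknown fusion mode '%s' (use 'concat' or 'sum')", fusion))
  }
  if (mode == "auto" && is.null(seed)) stop("auto mode requires a seed")
  structure(list(mode = mode, placement = placement, gains = gains,
                 kernel_size = kernel_size, fusion = fusion,
                 seed = if (mode == "auto") as.integer(seed) else NULL),
            class = "pic_layer_config")
}

#' Initialize learnable kernel banks for an auto PI layer
#'
#' Kernels are drawn from a zero-mean uniform distribution scaled by
#' `1 / kernel_size^2`, under the configured seed.
#'
#' @param cfg a [pic_layer_config()] with `mode = "auto"`.
#' @param channels number of input channels the layer will see.
#' @return list with kernel banks `p` and `i`, each `(k, k, channels)`.
#' @export
auto_pic_init <- function(cfg, channels) {
  stopifnot(inherits(cfg, "pic_layer_config"), cfg$mode == "auto")
  k <- cfg$kernel_size
  a <- 1 / k^2
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  list(p = array(runif(k * k * channels, -a, a), dim = c(k, k, channels)),
       i = array(runif(k * k * channels, -a, a), dim = c(k, k, channels)))
}

fuse_paths <- function(x, p, i, fusion) {
  if (fusion == "concat") {
    d <- dim(x)
    out <- array(0, dim = c(d[1], d[2], 2L * d[3]))
    out[, , seq_len(d[3])] <- p
    out[, , d[3] + seq_len(d[3])] <- i
    out
  } else {
    x + p + i
  }
}

#' Forward pass of a PI feature layer
#'
#' `manual_pic_forward` applies the fixed Laplacian/box-mean pair;
#' `auto_pic_forward` applies learnable depthwise kernel banks. In both, the
#' proportional path is scaled by `kp`, the integral path by `ki`, and the
#' paths are fused per `cfg$fusion` (`"concat"`: channel-stacked `[p, i]`,
#' doubling channels; `"sum"`: residual `x + p + i`).
#'
#' @param x a matrix or (H, W, C) array.
#' @param cfg a [pic_layer_config()].
#' @param params for `auto_pic_forward`, a kernel-bank list as produced by
#'   [auto_pic_init()].
#' @return the fused feature map (same spatial dims; channels doubled under
#'   concat fusion).
#' @export
manual_pic_forward <- function(x, cfg) {
  stopifnot(inherits(cfg, "pic_layer_config"), cfg$mode == "manual")
  fm <- as_feature_map(x)
  p <- cfg$gains$kp * as_feature_map(manual_p_filter(fm))
  i <- cfg$gains$ki * as_feature_map(manual_i_filter(fm))
  y <- fuse_paths(fm, p, i, cfg$fusion)
  if (cfg$fusion == "sum") restore_shape(y, x) else y
}

#' @rdname manual_pic_forward
#' @export
auto_pic_forward <- function(x, cfg, params) {
  stopifnot(inherits(cfg, "pic_layer_config"), cfg$mode == "auto")
  fm <- as_feature_map(x)
  C <- dim(fm)[3]
  k <- cfg$kernel_size
  ok <- function(b) is.array(b) && length(dim(b)) == 3L &&
    all(dim(b) == c(k, k, C))
  if (!is.list(params) || !ok(params$p) || !ok(params$i)) {
    stop(sprintf("params must hold (k, k, C) = (%d, %d, %d) kernel banks 'p' and 'i'",
                 k, k, C))
  }
  x4 <- array(fm, dim = c(dim(fm), 1L))
  p <- cfg$gains$kp * array(depthwise_same(x4, params$p), dim = dim(fm))
  i <- cfg$gains$ki * array(depthwise_same(x4, params$i), dim = dim(fm))
  y <- fuse_paths(fm, p, i, cfg$fusion)
  if (cfg$fusion == "sum") restore_shape(y, x) else y
}

# ---- internal batched forward/backward used inside the network ------------

# layer: list(cfg, manual kernels or param names); x4: (H, W, C, N)
pic_layer_fwd <- function(x4, cfg, kern_p, kern_i) {
  p <- cfg$gains$kp * depthwise_same(x4, kern_p)
  i <- cfg$gains$ki * depthwise_same(x4, kern_i)
  d <- dim(x4)
  if (cfg$fusion == "concat") {
    y <- array(0, dim = c(d[1], d[2], 2L * d[3], d[4]))
    y[, , seq_len(d[3]), ] <- p
    y[, , d[3] + seq_len(d[3]), ] <- i
  } else {
    y <- x4 + p + i
  }
  list(y = y, x = x4)
}

# returns dx and (for auto mode) kernel gradients; gains receive no gradient
pic_layer_bwd <- function(cache, cfg, kern_p, kern_i, dy, want_kernel_grads) {
  d <- dim(cache$x)
  if (cfg$fusion == "concat") {
    dyp <- dy[, , seq_len(d[3]), , drop = FALSE]
    dyi <- dy[, , d[3] + seq_len(d[3]), , drop = FALSE]
    dx_extra <- NULL
  } else {
    dyp <- dy
    dyi <- dy
    dx_extra <- dy
  }
  gp <- depthwise_same_bwd(cache$x, kern_p, cfg$gains$kp * dyp)
  gi <- depthwise_same_bwd(cache$x, kern_i, cfg$gains$ki * dyi)
  dx <- gp$dx + gi$dx
  if (!is.null(dx_extra)) dx <- dx + dx_extra
  out <- list(dx = dx)
  if (want_kernel_grads) out$grads <- list(p = gp$dk, i = gi$dk)
  out
}
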