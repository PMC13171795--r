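# Manual and learnable PI feature paths against a brute-force convolution
# oracle, fusion contracts, and gradient flow.

test_that("manual filters match the brute-force convolution oracle", {
  # impulse/constant identities
  expect_true(all(manual_p_filter(matrix(0.7, 5, 5)) == 0))
  expect_equal(manual_i_filter(matrix(0.7, 5, 5)), matrix(0.7, 5, 5),
               tolerance = 1e-15)
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  got <- manual_p_filter(imp)
  expect_equal(got[3:5, 3:5], laplacian_kernel(), tolerance = 1e-15)
  got_i <- manual_i_filter(imp)
  expect_equal(got_i[3:5, 3:5], matrix(1 / 9, 3, 3), tolerance = 1e-15)

  # 5x5 checkerboard: interior Laplacian response is +-4
  cb <- outer(1:5, 1:5, function(i, j) (i + j) %% 2)
  lp <- manual_p_filter(cb)
  expect_equal(abs(lp[2:4, 2:4]), matrix(4, 3, 3), tolerance = 1e-12)
  expect_equal(lp, oracle_conv2d_reflect(cb, laplacian_kernel()),
               tolerance = 1e-12)

  # random maps against the oracle to near machine precision
  set.seed(11)
  for (rep in 1:5) {
    x <- matrix(runif(64), 8, 8)
    expect_equal(manual_p_filter(x), oracle_conv2d_reflect(x, laplacian_kernel()),
                 tolerance = 1e-10)
    expect_equal(manual_i_filter(x), oracle_conv2d_reflect(x, box_mean_kernel()),
                 tolerance = 1e-10)
  }

  # spatial dims below the kernel support are rejected
  expect_error(manual_p_filter(matrix(0.1, 2, 2)), "kernel")
})

test_that("manual paths are linear operators", {
  set.seed(12)
  for (f in list(manual_p_filter, manual_i_filter)) {
    x <- matrix(runif(49), 7, 7)
    y <- matrix(runif(49), 7, 7)
    a <- 1.7; b <- -0.4
    expect_equal(f(a * x + b * y), a * f(x) + b * f(y), tolerance = 1e-12)
  }
})

test_that("manual_pic_forward fuses gain-scaled paths", {
  # zero gains with residual fusion pass the input through unchanged
  cfg0 <- pic_layer_config("manual", "mid",
                           gains = suppressWarnings(pi_gains(1e-12, 0)),
                           fusion = "sum")
  x <- matrix(runif(36), 6, 6)
  expect_equal(manual_pic_forward(x, cfg0), x, tolerance = 1e-10)

  # concat on a constant map: both halves zero when ki = 0
  cfgc <- pic_layer_config("manual", "before", gains = pi_gains(1, 0), fusion = "concat")
  out <- manual_pic_forward(matrix(0.3, 5, 5), cfgc)
  expect_identical(dim(out), c(5L, 5L, 2L))
  expect_true(all(out == 0))

  # residual fusion equals the composition of the two filter oracles
  cb <- outer(1:5, 1:5, function(i, j) (i + j) %% 2)
  cfg <- pic_layer_config("manual", "mid", gains = pi_gains(0.6, 0.05), fusion = "sum")
  expect_equal(manual_pic_forward(cb, cfg),
               cb + 0.6 * oracle_conv2d_reflect(cb, laplacian_kernel()) +
                 0.05 * oracle_conv2d_reflect(cb, box_mean_kernel()),
               tolerance = 1e-12)

  expect_error(pic_layer_config("manual", "mid", fusion = "mean"), "fusion")

  # gain monotonicity: ||output - input|| non-decreasing in kp and ki on a
  # smooth fixture under residual fusion
  set.seed(13)
  x <- manual_i_filter(manual_i_filter(matrix(runif(100), 10, 10)))
  dev_norm <- function(kp, ki) {
    cfg <- suppressWarnings(pic_layer_config("manual", "mid",
                                             gains = pi_gains(max(kp, 1e-12), ki),
                                             fusion = "sum"))
    sqrt(sum((manual_pic_forward(x, cfg) - x)^2))
  }
  kps <- c(0.1, 0.3, 0.6, 1.0)
  kis <- c(0, 0.05, 0.2, 0.5)
  for (ki in kis) {
    norms <- vapply(kps, dev_norm, numeric(1), ki = ki)
    expect_true(all(diff(norms) >= -1e-12))
  }
  for (kp in kps) {
    norms <- vapply(kis, function(ki) dev_norm(kp, ki), numeric(1))
    expect_true(all(diff(norms) >= -1e-12))
  }
})

test_that("auto layer seeded at the manual kernels reproduces manual output", {
  set.seed(14)
  x <- array(runif(6 * 6 * 2), dim = c(6, 6, 2))
  for (fusion in c("concat", "sum")) {
    cfg_a <- pic_layer_config("auto", "mid", gains = pi_gains(0.6, 0.05),
                              fusion = fusion, seed = 1)
    cfg_m <- pic_layer_config("manual", "mid", gains = pi_gains(0.6, 0.05),
                              fusion = fusion)
    params <- list(p = array(laplacian_kernel(), c(3, 3, 2)),
                   i = array(box_mean_kernel(), c(3, 3, 2)))
    expect_identical(auto_pic_forward(x, cfg_a, params),
                     manual_pic_forward(x, cfg_m))
  }

  # zero kernels with residual fusion give the identity map
  cfg_a <- pic_layer_config("auto", "mid", fusion = "sum", seed = 1)
  z <- list(p = array(0, c(3, 3, 2)), i = array(0, c(3, 3, 2)))
  expect_equal(auto_pic_forward(x, cfg_a, z), x, tolerance = 1e-15)

  # kernel bank shape mismatch is rejected
  bad <- list(p = array(0, c(3, 3, 1)), i = array(0, c(3, 3, 2)))
  expect_error(auto_pic_forward(x, cfg_a, bad), "kernel banks")

  # auto mode requires a seed; manual mode ignores it
  expect_error(pic_layer_config("auto", "mid"), "seed")
  expect_null(pic_layer_config("manual", "mid", seed = 9)$seed)
})

test_that("auto kernel gradients match central finite differences", {
  # 1-channel 6x6 input, scalar loss = sum of the layer output
  set.seed(15)
  x4 <- array(runif(36), c(6, 6, 1, 1))
  cfg <- pic_layer_config("auto", "mid", gains = pi_gains(0.6, 0.05),
                          fusion = "sum", seed = 2)
  kb <- auto_pic_init(cfg, 1L)
  fw <- picnet:::pic_layer_fwd(x4, cfg, kb$p, kb$i)
  dy <- array(1, dim = dim(fw$y)) # d(sum)/dy = 1
  bw <- picnet:::pic_layer_bwd(fw, cfg, kb$p, kb$i, dy, want_kernel_grads = TRUE)
  loss_of <- function(kb2) sum(picnet:::pic_layer_fwd(x4, cfg, kb2$p, kb2$i)$y)
  h <- 1e-5
  for (bank in c("p", "i")) {
    for (i in seq_len(9)) {
      kb2 <- kb; kb2[[bank]][i] <- kb[[bank]][i] + h
      up <- loss_of(kb2)
      kb2[[bank]][i] <- kb[[bank]][i] - h
      dn <- loss_of(kb2)
      expect_equal(bw$grads[[bank]][i], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("feature maps reject non-finite values and preserve shape", {
  expect_error(manual_p_filter(matrix(c(NA, 1, 2, 3), 2, 2)), "non-finite")
  x <- array(runif(5 * 7 * 3), dim = c(5, 7, 3))
  expect_identical(dim(manual_p_filter(x)), dim(x))
  expect_identical(dim(manual_i_filter(x)), dim(x))
})
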