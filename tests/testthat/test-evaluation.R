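# Metrics, Wilson intervals, bootstrap, significance protocol, ROC.

test_that("classification metrics follow the count definitions", {
  cc <- confusion_counts(tp = 8, tn = 5, fp = 2, fn = 1)
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 13 / 16)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))

  perfect <- classification_metrics(confusion_counts(10, 10, 0, 0))
  expect_true(all(unlist(perfect) == 1))

  # undefined metrics are NA, not zero
  none_pos <- classification_metrics(confusion_counts(0, 10, 0, 0))
  expect_true(is.na(none_pos$precision))
  expect_true(is.na(none_pos$recall))
  expect_error(classification_metrics(confusion_counts(0, 0, 0, 0)), "zero")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("harmonic/geometric/arithmetic mean ordering holds for P and R", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(1, 0.05, 1); r <- runif(1, 0.05, 1)
    f1 <- f1_from_precision_recall(p, r)
    expect_lte(f1, sqrt(p * r) + 1e-12)
    expect_lte(sqrt(p * r), (p + r) / 2 + 1e-12)
  }
})

test_that("wilson_ci matches the closed form and its boundary behavior", {
  ci <- wilson_ci(0.99, 116)
  expect_equal(round(ci$lower, 3), 0.951)
  expect_equal(round(ci$upper, 3), 0.998)

  # interval always contains p_hat; boundary cases collapse exactly
  set.seed(42)
  for (i in 1:25) {
    p <- runif(1); n <- sample(5:500, 1)
    ci <- wilson_ci(p, n)
    expect_true(ci$lower <= p && p <= ci$upper)
    expect_true(ci$lower >= 0 && ci$upper <= 1)
  }
  expect_equal(wilson_ci(0, 30)$lower, 0)
  expect_equal(wilson_ci(1, 30)$upper, 1)

  # width shrinks monotonically in n
  widths <- vapply(c(20, 50, 100, 400, 1000), function(n) wilson_ci(0.9, n)$width,
                   numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("bootstrap_metric is seeded, excludes undefined resamples", {
  labels <- rep(c(0L, 1L), each = 58)
  perfect <- labels
  bt <- bootstrap_metric(labels, perfect, "f1", n_boot = 50, seed = 3)
  expect_true(all(bt$samples == 1))
  expect_identical(bt$excluded, 0L)
  expect_equal(unname(bt$summary[3] - bt$summary[1]), 0) # IQR 0

  b1 <- bootstrap_metric(labels, perfect, "accuracy", n_boot = 1, seed = 9)
  b2 <- bootstrap_metric(labels, perfect, "accuracy", n_boot = 1, seed = 9)
  expect_identical(b1$samples, b2$samples)

  # accuracy 0.9 fixture on n = 116: bootstrap mean within 2 SE of the point value
  set.seed(10)
  labels <- rep(c(0L, 1L), c(58, 58))
  preds <- labels
  flip <- sample(116, 12) # accuracy 104/116
  preds[flip] <- 1L - preds[flip]
  p_hat <- mean(preds == labels)
  bt <- bootstrap_metric(labels, preds, "accuracy", n_boot = 1000, seed = 4)
  se <- sqrt(p_hat * (1 - p_hat) / 116)
  expect_lt(abs(mean(bt$samples) - p_hat), 2 * se)

  # degenerate predictor (never positive): f1 undefined on every resample
  bt0 <- bootstrap_metric(labels, rep(0L, 116), "precision", n_boot = 20, seed = 1)
  expect_identical(bt0$excluded, 20L)
  expect_error(bootstrap_metric(integer(0), integer(0)), "empty")
})

test_that("significance protocol yields a symmetric unit-diagonal matrix", {
  set.seed(43)
  a <- rbeta(300, 40, 4)
  b <- a # identical: degenerate pair
  c_ <- pmin(1, a + 0.05) # shifted distribution
  suite <- significance_suite(list(A = a, B = b, C = c_))
  expect_true(isSymmetric(suite$p_matrix))
  expect_true(all(diag(suite$p_matrix) == 1))
  expect_true(suite$degenerate["A", "B"])
  expect_identical(suite$p_matrix["A", "B"], 1)
  expect_lt(suite$p_matrix["A", "C"], 0.05)

  # three clearly shifted groups: Kruskal-Wallis flags the difference
  g1 <- rbeta(1000, 40, 10); g2 <- pmin(1, g1 + 0.05); g3 <- pmin(1, g1 + 0.10)
  kw <- significance_suite(list(g1 = g1, g2 = g2, g3 = g3))$kruskal
  expect_lt(kw$p.value, 0.01)
  # cross-check the H statistic against stats::kruskal.test directly
  ref <- kruskal.test(list(g1, g2, g3))
  expect_equal(kw$statistic, unname(ref$statistic))
})

test_that("roc_curve matches the pair-counting oracle and pROC", {
  # 4-point toy: AUC 0.75
  toy <- roc_curve(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(toy$auc, 0.75)
  expect_equal(oracle_auc_pairs(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)

  expect_equal(roc_curve(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))$auc, 1)
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(44)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2) # ties likely
    expect_equal(roc_curve(labels, scores)$auc, oracle_auc_pairs(labels, scores),
                 tolerance = 1e-12)
  }
  # scores independent of labels give AUC near 1/2
  labels <- rep(c(0, 1), 500)
  scores <- rnorm(1000)
  expect_lt(abs(roc_curve(labels, scores)$auc - 0.5), 0.06)

  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(45)
    labels <- sample(c(0, 1), 40, replace = TRUE)
    scores <- runif(40)
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
    expect_equal(roc_curve(labels, scores)$auc, ref, tolerance = 1e-12)
  }
})

test_that("eval_report bundles metrics, intervals and significance", {
  set.seed(46)
  labels <- rep(c(0L, 1L), each = 30)
  good <- labels; good[sample(60, 3)] <- 1L - good[sample(60, 3)]
  bad <- labels; bad[sample(60, 18)] <- 1L - bad[sample(60, 18)]
  rep_ <- eval_report(list(good = list(labels = labels, predictions = good),
                           bad = list(labels = labels, predictions = bad)),
                      n_boot = 200, seed = 2)
  expect_named(rep_$models, c("good", "bad"))
  expect_true(rep_$models$good$metrics$accuracy >
                rep_$models$bad$metrics$accuracy)
  expect_true(all(diag(rep_$significance$p_matrix) == 1))

  # serialization and cosmetic plots produce the expected artifacts
  dir <- tempfile()
  save_eval_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "eval_report.json")))
  expect_true(file.exists(file.path(dir, "p_matrix.csv")))
  roc <- roc_curve(labels, runif(60))
  png_path <- tempfile(fileext = ".png")
  plot_roc(roc, png_path = png_path)
  plot_bootstrap_box(list(a = rep_$models$good$bootstrap$samples),
                     png_path = tempfile(fileext = ".png"))
  expect_gt(file.size(png_path), 0)
  unlink(dir, recursive = TRUE)
})
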