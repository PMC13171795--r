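# Evaluation protocol: confusion-matrix metrics, Wilson score intervals,
# bootstrap metric distributions, Kruskal-Wallis + pairwise Wilcoxon
# signed-rank testing, and ROC analysis.

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts (true/false
#'   positives/negatives; positive = malignant).
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param labels,predictions integer vectors in \{0, 1\} (1 = malignant).
#' @export
confusion_from_predictions <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions))
  confusion_counts(tp = sum(labels == 1L & predictions == 1L),
                   tn = sum(labels == 0L & predictions == 0L),
                   fp = sum(labels == 0L & predictions == 1L),
                   fn = sum(labels == 1L & predictions == 0L))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' silently as 0.
#'
#' @param counts a [confusion_counts()].
#' @return named list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("total count is zero")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' F1 score as the harmonic mean of precision and recall
#' @param precision,recall proportions in \[0, 1\].
#' @return the F1 score.
#' @export
f1_from_precision_recall <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Wilson score confidence interval for a proportion
#'
#' `center = (p + z^2/(2n)) / (1 + z^2/n)`;
#' `half_width = z * sqrt(p(1-p)/n + z^2/(4n^2)) / (1 + z^2/n)`.
#' The interval always contains `p_hat` and stays inside \[0, 1\], including
#' at the boundaries `p_hat = 0` or `1`.
#'
#' @param p_hat observed proportion in \[0, 1\].
#' @param n sample size (>= 1).
#' @param z critical value (default 1.96 for 95% confidence).
#' @return a `wilson_interval`: list with `p_hat`, `n`, `z`, `lower`,
#'   `upper`, `width`.
#' @examples
#' wilson_ci(0.99, 116) # lower 0.951, upper 0.998 at 3 decimals
#' @export
wilson_ci <- function(p_hat, n, z = 1.96) {
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 1, z > 0)
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  structure(list(p_hat = p_hat, n = as.integer(n), z = z,
                 lower = center - half, upper = center + half,
                 width = 2 * half),
            class = "wilson_interval")
}

#' @export
print.wilson_interval <- function(x, ...) {
  cat(sprintf("Wilson 95%% CI: p=%.3f, n=%d -> (%.3f, %.3f), width %.3f\n",
              x$p_hat, x$n, x$lower, x$upper, x$width))
  invisible(x)
}

metric_from_counts <- function(counts, metric) {
  classification_metrics(counts)[[metric]]
}

#' Bootstrap distribution of a classification metric
#'
#' Resamples test indices with replacement and recomputes the metric per
#' resample. Resamples on which the metric is undefined (for example no
#' predicted positives) are excluded and counted, never coerced to 0.
#'
#' @param labels,predictions equal-length 0/1 vectors.
#' @param metric one of `"f1"`, `"accuracy"`, `"precision"`, `"recall"`.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed; results are reproducible.
#' @return list with `samples` (metric values, `NA` rows removed),
#'   `excluded` (count of undefined resamples), and `summary` (quartiles).
#' @export
bootstrap_metric <- function(labels, predictions, metric = "f1",
                             n_boot = 1000L, seed = 1L) {
  metric <- match.arg(metric, c("f1", "accuracy", "precision", "recall"))
  n <- length(labels)
  if (n == 0) stop("empty label/prediction vectors")
  stopifnot(length(predictions) == n, n_boot >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[b] <- metric_from_counts(
      confusion_from_predictions(labels[idx], predictions[idx]), metric)
  }
  excluded <- sum(is.na(vals))
  samples <- vals[!is.na(vals)]
  list(samples = samples, excluded = excluded,
       summary = quantile(samples, c(0.25, 0.5, 0.75), names = TRUE))
}

#' Kruskal-Wallis and pairwise Wilcoxon significance protocol
#'
#' Takes per-model bootstrap metric vectors (paired: generated with the same
#' resample indices), reports the global Kruskal-Wallis H test across models
#' and the matrix of pairwise Wilcoxon signed-rank p-values. The p-value
#' matrix is symmetric with unit diagonal; a pair whose differences are all
#' zero is degenerate and reported as p = 1 with a flag.
#'
#' @param samples named list (>= 2 entries) of equal-length numeric vectors.
#' @param alpha significance level for the `significant` flag matrix.
#' @return list with `kruskal` (statistic, p.value), `p_matrix`,
#'   `significant` (logical matrix at `alpha`), `degenerate` (logical
#'   matrix).
#' @export
significance_suite <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  lens <- vapply(samples, length, numeric(1))
  if (length(unique(lens)) != 1) stop("sample vectors must have equal length")
  nm <- names(samples) %||% paste0("model", seq_along(samples))
  kw <- kruskal.test(samples)
  k <- length(samples)
  pm <- matrix(1, k, k, dimnames = list(nm, nm))
  dg <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- samples[[i]] - samples[[j]]
      if (all(d == 0)) {
        pm[i, j] <- pm[j, i] <- 1
        dg[i, j] <- dg[j, i] <- TRUE
      } else {
        wt <- suppressWarnings(wilcox.test(samples[[i]], samples[[j]],
                                           paired = TRUE, exact = FALSE))
        pm[i, j] <- pm[j, i] <- wt$p.value
      }
    }
  }
  list(kruskal = list(statistic = unname(kw$statistic), p.value = kw$p.value),
       p_matrix = pm, significant = pm < alpha, degenerate = dg)
}

#' ROC curve and area under the curve
#'
#' Standard threshold sweep over the distinct score values (ties grouped),
#' AUC by the trapezoid rule.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores real-valued scores (higher means more malignant).
#' @return list with `curve` (data frame `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
roc_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) stop("ROC requires both classes in labels")
  if (any(!is.finite(scores))) stop("scores must be finite")
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / neg, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}

#' Basic ROC and bootstrap box plots
#'
#' Cosmetic base-graphics output; pass a `png_path` to write a file instead
#' of drawing on the active device.
#'
#' @param roc result of [roc_curve()].
#' @param samples named list of bootstrap metric vectors.
#' @param png_path optional output PNG path.
#' @param ... forwarded to the underlying plot call.
#' @return the input, invisibly.
#' @export
plot_roc <- function(roc, png_path = NULL, ...) {
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(roc$curve$fpr, roc$curve$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", roc$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(roc)
}

#' @rdname plot_roc
#' @export
plot_bootstrap_box <- function(samples, png_path = NULL, ...) {
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(samples, ylab = "bootstrap metric", ...)
  invisible(samples)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON plus the confusion counts and pairwise p-value
#' matrix as CSV files.
#'
#' @param report an [eval_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    metric = report$metric, n_boot = report$n_boot, seed = report$seed,
    models = lapply(report$models, function(m) {
      list(counts = m$counts[c("tp", "tn", "fp", "fn")],
           metrics = m$metrics,
           wilson = lapply(m$wilson, function(ci) {
             if (!is.null(ci)) list(lower = ci$lower, upper = ci$upper)
           }),
           bootstrap_excluded = m$bootstrap$excluded,
           bootstrap_quartiles = as.list(m$bootstrap$summary))
    }),
    kruskal = report$significance$kruskal)
  jsonlite::write_json(payload, file.path(dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  counts <- do.call(rbind, lapply(report$models, function(m) {
    as.data.frame(m$counts[c("tp", "tn", "fp", "fn")])
  }))
  write.csv(cbind(model = names(report$models), counts),
            file.path(dir, "confusion_counts.csv"), row.names = FALSE)
  if (!is.null(report$significance)) {
    write.csv(report$significance$p_matrix, file.path(dir, "p_matrix.csv"))
  }
  invisible(dir)
}

#' Full evaluation report for a set of model runs
#'
#' @param runs named list; each element holds `labels` and `predictions`
#'   (0/1 vectors) for one model on the same test set.
#' @param n_boot,seed bootstrap settings shared across models (the same
#'   resample indices pair the models).
#' @param metric metric bootstrapped for the significance protocol.
#' @return an `eval_report`: per-model metrics and Wilson intervals,
#'   bootstrap summaries, Kruskal-Wallis result and pairwise p-value matrix.
#' @export
eval_report <- function(runs, n_boot = 1000L, seed = 1L, metric = "f1") {
  stopifnot(is.list(runs), length(runs) >= 1)
  nm <- names(runs) %||% paste0("model", seq_along(runs))
  per_model <- list()
  boots <- list()
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    cc <- confusion_from_predictions(r$labels, r$predictions)
    met <- classification_metrics(cc)
    n <- length(r$labels)
    cis <- lapply(met, function(m) if (is.na(m)) NULL else wilson_ci(m, n))
    bt <- bootstrap_metric(r$labels, r$predictions, metric = metric,
                           n_boot = n_boot, seed = seed)
    per_model[[nm[i]]] <- list(counts = cc, metrics = met, wilson = cis,
                               bootstrap = bt)
    boots[[nm[i]]] <- bt$samples
  }
  sig <- if (length(runs) >= 2 && length(unique(lengths(boots))) == 1) {
    significance_suite(boots)
  }
  structure(list(models = per_model, significance = sig,
                 metric = metric, n_boot = n_boot, seed = seed),
            class = "eval_report")
}
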