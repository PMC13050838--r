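#' Confusion counts for binary predictions
#'
#' The positive class is `CML` (encoded 1), the negative class `Control`
#' (encoded 0); labels may also be given as those strings.
#'
#' @param y_true,y_pred equal-length binary vectors (0/1 or
#'   `"Control"`/`"CML"`).
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  yt <- as_binary(y_true)
  yp <- as_binary(y_pred)
  if (length(yt) != length(yp)) stop("y_true and y_pred lengths differ")
  structure(list(tp = sum(yt == 1 & yp == 1), tn = sum(yt == 0 & yp == 0),
                 fp = sum(yt == 0 & yp == 1), fn = sum(yt == 1 & yp == 0)),
            class = "confusion_counts")
}

as_binary <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (!all(y %in% class_levels())) stop("labels must be Control/CML or 0/1")
    return(as.integer(y == "CML"))
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be Control/CML or 0/1")
  y
}

#' Confusion-count constructor from explicit cells
#' @param tp,tn,fp,fn non-negative integer counts (positive class = CML).
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != floor(v))) stop("counts must be non-negative integers")
  structure(lapply(as.list(v), as.integer), class = "confusion_counts")
}

safe_div <- function(num, den, what, warn = TRUE) {
  if (den == 0) {
    if (warn) warning("zero denominator in ", what, "; returning 0")
    return(0)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`; per-class precision, recall and F1 (harmonic
#' mean) computed by treating each class in turn as positive; macro
#' averages are unweighted class means, weighted averages use supports.
#' Zero-denominator metrics are 0 with a warning.
#'
#' @param cc a `confusion_counts` (or [confusion()] output).
#' @param warn emit warnings for zero-denominator metrics (default `TRUE`).
#' @return A `metric_report` list: `accuracy`, `per_class` data frame
#'   (precision/recall/f1/support for Control and CML), `macro`,
#'   `weighted`, `support`.
#' @export
classification_metrics <- function(cc, warn = TRUE) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total == 0) stop("no samples")
  # per-class cells: for CML, positives as given; for Control, swap roles
  ctp <- c(Control = cc$tn, CML = cc$tp)
  cfp <- c(Control = cc$fn, CML = cc$fp)
  cfn <- c(Control = cc$fp, CML = cc$fn)
  prec <- rec <- f1 <- numeric(2)
  for (i in 1:2) {
    cl <- names(ctp)[i]
    prec[i] <- safe_div(ctp[i], ctp[i] + cfp[i], paste(cl, "precision"), warn)
    rec[i] <- safe_div(ctp[i], ctp[i] + cfn[i], paste(cl, "recall"), warn)
    f1[i] <- if (prec[i] + rec[i] == 0) {
      if (warn) warning("zero denominator in ", cl, " F1; returning 0")
      0
    } else 2 * prec[i] * rec[i] / (prec[i] + rec[i])
  }
  per <- data.frame(class = names(ctp), precision = unname(prec),
                    recall = unname(rec), f1 = unname(f1),
                    support = unname(ctp + cfn), stringsAsFactors = FALSE,
                    row.names = NULL)
  w <- per$support / sum(per$support)
  structure(list(
    accuracy = (cc$tp + cc$tn) / total,
    per_class = per,
    macro = c(precision = mean(per$precision), recall = mean(per$recall),
              f1 = mean(per$f1)),
    weighted = c(precision = sum(w * per$precision),
                 recall = sum(w * per$recall), f1 = sum(w * per$f1)),
    support = sum(per$support)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  # layout mirrors a standard classification report
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cat(sprintf("%-14s %9s %9s %9s %9s\n", "", "precision", "recall",
              "f1-score", "support"))
  for (i in seq_len(nrow(x$per_class))) {
    p <- x$per_class[i, ]
    cat(sprintf("%-14s %9s %9s %9s %9d\n", p$class, fmt(p$precision),
                fmt(p$recall), fmt(p$f1), p$support))
  }
  cat(sprintf("%-14s %9s %9s %9s %9d\n", "accuracy", "", "",
              fmt(x$accuracy), x$support))
  cat(sprintf("%-14s %9s %9s %9s %9d\n", "macro avg", fmt(x$macro["precision"]),
              fmt(x$macro["recall"]), fmt(x$macro["f1"]), x$support))
  cat(sprintf("%-14s %9s %9s %9s %9d\n", "weighted avg",
              fmt(x$weighted["precision"]), fmt(x$weighted["recall"]),
              fmt(x$weighted["f1"]), x$support))
  invisible(x)
}

#' ROC area under the curve
#'
#' Trapezoidal integration over all thresholds, numerically equal to the
#' Mann--Whitney statistic: the proportion of (positive, negative) pairs
#' ranked correctly, ties counted 1/2 (computed via average ranks).
#'
#' @param scores numeric scores (higher = more CML-like).
#' @param labels binary labels (0/1 or Control/CML); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision--recall area under the curve
#'
#' Step-wise integration of precision over recall across all score
#' thresholds (descending), i.e. `sum (R_i - R_{i-1}) * P_i`.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  ord <- order(-scores)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  # evaluate at distinct thresholds only (last index of each tied block)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y == 1L)
  sum(diff(c(0, rec)) * prec)
}

#' Percentile bootstrap confidence interval for a test-set metric
#'
#' Resamples test indices with replacement `B` times and reports the 2.5
#' and 97.5 percent empirical quantiles. Resamples lacking one of the
#' classes are redrawn (their count is reported), so metrics that need
#' both classes stay defined.
#'
#' @param metric_fn function of `(y_true, x)` returning a scalar (e.g.
#'   accuracy on predictions, or [roc_auc()] on scores).
#' @param y_true binary labels.
#' @param x predictions or scores, aligned with `y_true`.
#' @param B number of resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return A `bootstrap_ci` list: `point`, `lower`, `upper`, `B`, `seed`,
#'   `redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, y_true, x, B = 1000L, seed = 0L,
                         level = 0.95) {
  if (B < 2L) stop("B must be >= 2")
  y <- as_binary(y_true)
  n <- length(y)
  point <- metric_fn(y, x)
  redrawn <- 0L
  stats_v <- with_seed(seed, {
    out <- numeric(B)
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        redrawn <- redrawn + 1L
      }
      out[b] <- metric_fn(y[idx], x[idx])
    }
    out
  })
  alpha <- (1 - level) / 2
  q <- unname(stats::quantile(stats_v, c(alpha, 1 - alpha), type = 7))
  structure(list(point = point, lower = q[1], upper = q[2], B = as.integer(B),
                 seed = as.integer(seed), redrawn = redrawn),
            class = "bootstrap_ci")
}

#' Paired two-tailed t-test on per-run metric differences
#'
#' For comparing two model variants over the same seeded training
#' repetitions. Degenerate cases follow the documented contract: identical
#' vectors give statistic 0 and p = 1; zero-variance nonzero differences
#' are reported as a deterministic difference (p = 0, flagged).
#'
#' @param metric_runs_a,metric_runs_b equal-length paired metric vectors
#'   (same seeds), n >= 2.
#' @return List with `statistic`, `p_value`, `df`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_ttest <- function(metric_runs_a, metric_runs_b) {
  a <- as.numeric(metric_runs_a); b <- as.numeric(metric_runs_b)
  if (length(a) != length(b)) stop("paired runs must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired runs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      return(list(statistic = 0, p_value = 1, df = n - 1L, mean_diff = 0,
                  degenerate = FALSE))
    }
    return(list(statistic = sign(m) * Inf, p_value = 0, df = n - 1L,
                mean_diff = m, degenerate = TRUE))
  }
  t_stat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(statistic = t_stat, p_value = p, df = n - 1L, mean_diff = m,
       degenerate = FALSE)
}

#' Mean silhouette coefficient
#'
#' Per point, `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' Euclidean distance to the point's own class and `b_i` the smallest mean
#' distance to another class; points in singleton clusters get `s_i = 0`.
#'
#' @param points numeric matrix of coordinates (n x d).
#' @param labels class labels (>= 2 classes).
#' @return A `silhouette_result`: overall mean `s`, per-point `s_i`, `a`,
#'   `b`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  dm <- as.matrix(stats::dist(points))
  a <- b <- si <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) {  # singleton cluster convention
      a[i] <- 0; b[i] <- 0; si[i] <- 0
      next
    }
    a[i] <- mean(dm[i, own])
    b[i] <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dm[i, labels == cl])
    }, numeric(1)))
    si[i] <- if (max(a[i], b[i]) == 0) 0 else (b[i] - a[i]) / max(a[i], b[i])
  }
  structure(list(s = mean(si), s_i = si, a = a, b = b),
            class = "silhouette_result")
}

#' Deterministic 2-D projection of feature vectors
#'
#' Pluggable interface for latent-space visualization. The default linear
#' method is principal components (centred, deterministic sign fix:
#' largest-magnitude loading positive). A custom nonlinear method can be
#' supplied as a function `(x, seed) -> n x 2 matrix`.
#'
#' @param vectors numeric matrix (>= 3 rows).
#' @param method `"pca"` or a function.
#' @param seed passed to a function method (ignored by `"pca"`, which is
#'   deterministic).
#' @return n x 2 coordinate matrix.
#' @export
project_2d <- function(vectors, method = "pca", seed = 0L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 3L) stop("need at least 3 vectors")
  if (is.function(method)) return(method(vectors, seed))
  if (!identical(method, "pca")) stop("unknown projection method")
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) coords <- cbind(coords, 0)
  for (j in 1:2) {
    if (j <= ncol(pc$rotation)) {
      load <- pc$rotation[, j]
      if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
    }
  }
  unname(coords)
}

#' Assemble an evaluation report
#'
#' Bundles confusion counts, the classification metrics, both AUCs and
#' (optionally) bootstrap CIs for accuracy and ROC-AUC into one object;
#' `print()` mirrors a classification-report table.
#'
#' @param y_true binary labels.
#' @param scores CML-class probabilities.
#' @param threshold decision threshold on `scores` (default 0.5).
#' @param bootstrap number of bootstrap resamples for CIs (0 = skip).
#' @param seed bootstrap seed.
#' @return An `eval_report`.
#' @export
eval_report <- function(y_true, scores, threshold = 0.5, bootstrap = 1000L,
                        seed = 0L) {
  y <- as_binary(y_true)
  preds <- as.integer(scores >= threshold)
  cc <- confusion(y, preds)
  mr <- classification_metrics(cc)
  out <- list(confusion = cc, metrics = mr,
              roc_auc = roc_auc(scores, y), pr_auc = pr_auc(scores, y),
              n = length(y))
  if (bootstrap > 0) {
    acc_fn <- function(yt, x) mean(yt == as.integer(x >= threshold))
    out$ci_accuracy <- bootstrap_ci(acc_fn, y, scores, B = bootstrap,
                                    seed = seed)
    out$ci_roc_auc <- bootstrap_ci(function(yt, s) roc_auc(s, yt), y, scores,
                                   B = bootstrap, seed = seed + 1L)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d sequences (positive class: CML)\n\n", x$n))
  print(x$metrics)
  cat(sprintf("\nROC-AUC %.3f | PR-AUC %.3f\n", x$roc_auc, x$pr_auc))
  if (!is.null(x$ci_accuracy)) {
    cat(sprintf("accuracy 95%% CI [%.3f, %.3f] | ROC-AUC 95%% CI [%.3f, %.3f] (B = %d)\n",
                x$ci_accuracy$lower, x$ci_accuracy$upper,
                x$ci_roc_auc$lower, x$ci_roc_auc$upper, x$ci_accuracy$B))
  }
  invisible(x)
}

#' Export ROC and PR curve points as TSV
#' @param scores,labels as in [roc_auc()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curves <- function(scores, labels, path) {
  y <- as_binary(labels)
  ord <- order(-scores)
  y <- y[ord]
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  df <- data.frame(threshold = scores[ord],
                   tpr = tp / sum(y == 1L), fpr = fp / sum(y == 0L),
                   precision = tp / (tp + fp))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
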