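test_that("confusion counts use CML as positive class", {
  cc <- confusion(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0))
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 3L, tn = 2L, fp = 0L, fn = 0L))

  # the in-study test set: 120 + 120 with 5 controls and 3 positives wrong
  y_true <- c(rep(0, 120), rep(1, 120))
  y_pred <- c(rep(1, 5), rep(0, 115), rep(0, 3), rep(1, 117))
  cc <- confusion(y_true, y_pred)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 117L, tn = 115L, fp = 5L, fn = 3L))

  # swapping predictions swaps tp<->fn and tn<->fp
  cs <- confusion(y_true, 1 - y_pred)
  expect_equal(cs$tp, cc$fn)
  expect_equal(cs$tn, cc$fp)
  expect_equal(cs$fp, cc$tn)
  expect_equal(cs$fn, cc$tp)

  expect_error(confusion(c(0, 2), c(0, 1)), "labels")
  expect_error(confusion(c("CML", "Ctl"), c("CML", "CML")), "labels")
  expect_equal(confusion(c("CML", "Control"), c("CML", "CML"))$fp, 1L)
})

test_that("classification metrics match per-sample brute force", {
  set.seed(17)
  for (trial in 1:25) {
    cells <- as.integer(rmultinom(1, sample(5:50, 1), rep(0.25, 4)))
    tp <- cells[1]; tn <- cells[2]; fp <- cells[3]; fn <- cells[4]
    if ((tp + fn) == 0 || (tn + fp) == 0) next
    got <- suppressWarnings(classification_metrics(
      confusion_counts(tp, tn, fp, fn)))
    ref <- ref_metrics_from_counts(tp, tn, fp, fn)
    expect_equal(got$accuracy, ref$accuracy)
    expect_equal(unname(unlist(
      got$per_class[got$per_class$class == "Control",
                    c("precision", "recall", "f1")])),
      unname(ref$control[c("precision", "recall", "f1")]))
    expect_equal(unname(unlist(
      got$per_class[got$per_class$class == "CML",
                    c("precision", "recall", "f1")])),
      unname(ref$cml[c("precision", "recall", "f1")]))
    # F1 is the harmonic mean of its own precision/recall
    pc <- got$per_class
    for (i in 1:2) {
      if (pc$precision[i] + pc$recall[i] > 0) {
        expect_equal(pc$f1[i], 2 * pc$precision[i] * pc$recall[i] /
                       (pc$precision[i] + pc$recall[i]))
      }
    }
    # balanced supports: accuracy equals mean class recall
    if (tp + fn == tn + fp) {
      expect_equal(got$accuracy, unname(got$macro["recall"]))
    }
  }
  expect_equal(classification_metrics(confusion_counts(5, 5, 5, 5))$accuracy,
               0.5)
  expect_warning(expect_warning(
    classification_metrics(confusion_counts(0, 5, 0, 5)),
    "zero denominator"))
})

test_that("roc_auc equals the exhaustive concordant-pair fraction", {
  # the documented 4-point example
  s <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(s, y), ref_auc_pairs(s, y))
  expect_equal(roc_auc(s, y), 0.75)

  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(23)
  for (trial in 1:20) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # ties likely
    expect_equal(roc_auc(s, y), ref_auc_pairs(s, y), info = trial)
  }
})

test_that("pr_auc integrates precision over recall step-wise", {
  # perfect ranking: PR-AUC 1
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # hand computation: scores desc y = (1,0,1,0)
  # thresholds: r=1/2 p=1; r=1/2 p=1/2; r=1 p=2/3; r=1 p=1/2
  # steps: 0.5*1 + 0.5*(2/3)
  expect_equal(pr_auc(c(4, 3, 2, 1), c(1, 0, 1, 0)), 0.5 + 0.5 * 2 / 3)
  expect_error(pr_auc(1:3, c(0, 0, 0)), "both classes")
})

test_that("bootstrap CI behaves per contract and matches an oracle", {
  y <- rep(c(0L, 1L), 10)
  pred <- c(rep(0L, 9), 1L, rep(1L, 9), 0L)
  acc_fn <- function(yt, x) mean(yt == x)

  ci <- bootstrap_ci(acc_fn, y, pred, B = 200, seed = 1)
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)

  # constant metric: zero-width CI at the constant
  ci0 <- bootstrap_ci(function(yt, x) 0.42, y, pred, B = 50, seed = 2)
  expect_equal(c(ci0$lower, ci0$point, ci0$upper), rep(0.42, 3))

  # same seed twice: identical bounds
  ci1 <- bootstrap_ci(acc_fn, y, pred, B = 300, seed = 7)
  ci2 <- bootstrap_ci(acc_fn, y, pred, B = 300, seed = 7)
  expect_identical(ci1[c("lower", "upper")], ci2[c("lower", "upper")])

  # independent oracle within Monte-Carlo tolerance (accuracy on 20 samples
  # is lattice-valued, so compare at a large B)
  ci3 <- bootstrap_ci(acc_fn, y, pred, B = 20000, seed = 1)
  ref <- ref_bootstrap_acc(y, pred, B = 20000, seed = 99)
  expect_lt(abs(ci3$lower - ref[1]), 0.01)
  expect_lt(abs(ci3$upper - ref[2]), 0.01)

  expect_error(bootstrap_ci(acc_fn, y, pred, B = 1), "B must")
})

test_that("bootstrap CI width shrinks as n grows tenfold", {
  set.seed(3)
  make <- function(n) {
    y <- rep(c(0L, 1L), n / 2)
    s <- y * 0.3 + runif(n)  # overlapping classes: AUC well inside (0.5, 1)
    list(y = y, s = s)
  }
  small <- make(40); big <- make(400)
  w <- function(d) {
    ci <- bootstrap_ci(function(yt, s) roc_auc(s, yt), d$y, d$s,
                       B = 300, seed = 5)
    ci$upper - ci$lower
  }
  expect_lt(w(big), w(small))
})

test_that("paired t-test handles the documented cases", {
  expect_equal(paired_ttest(c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7))$p_value, 1)
  deg <- paired_ttest(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)

  d <- c(0.2, -0.1, 0.3, 0.1, 0.0)
  res <- paired_ttest(d, rep(0, 5))
  t_ref <- mean(d) / (sd(d) / sqrt(5))         # textbook closed form
  p_ref <- 2 * pt(-abs(t_ref), df = 4)
  expect_equal(res$statistic, t_ref)
  expect_equal(res$p_value, p_ref)
  expect_error(paired_ttest(1, 2), "at least 2")
  expect_error(paired_ttest(1:3, 1:2), "equal length")
})

test_that("silhouette matches the brute-force double loop", {
  # two tight clusters far apart
  pts <- rbind(c(0, 0), c(0, 1), c(100, 0), c(100, 1))
  lab <- c("a", "a", "b", "b")
  s <- silhouette_score(pts, lab)
  expect_gt(s$s, 0.98)
  expect_equal(s$s, ref_silhouette(pts, lab))

  # a == b gives s_i = 0: symmetric point between clusters
  pts2 <- rbind(c(0, 0), c(2, 0), c(1, 0), c(1, 0.0001))
  lab2 <- c("a", "b", "a", "b")
  s2 <- silhouette_score(pts2, lab2)
  expect_equal(s2$s, ref_silhouette(pts2, lab2))

  set.seed(8)
  for (trial in 1:10) {
    pts <- matrix(rnorm(20), 10)
    lab <- sample(c("x", "y", "z"), 10, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(pts, lab)$s, ref_silhouette(pts, lab),
                 info = trial)
  }
  expect_error(silhouette_score(matrix(rnorm(8), 4), rep("a", 4)),
               "2 classes")

  # s -> 1 as separation grows with fixed spread
  lab4 <- c("a", "a", "b", "b")
  s_near <- silhouette_score(rbind(c(0, 0), c(0, 1), c(5, 0), c(5, 1)),
                             lab4)$s
  s_far <- silhouette_score(rbind(c(0, 0), c(0, 1), c(500, 0), c(500, 1)),
                            lab4)$s
  expect_gt(s_far, s_near)
  expect_gt(s_far, 0.99)
})

test_that("project_2d is deterministic and respects linear structure", {
  set.seed(12)
  x <- matrix(rnorm(60), 12)
  c1 <- project_2d(x)
  c2 <- project_2d(x)
  expect_identical(c1, c2)
  expect_equal(dim(c1), c(12L, 2L))

  # 2-D input under the linear method: a rotation (distances preserved)
  x2 <- matrix(rnorm(20), 10)
  p2 <- project_2d(x2)
  expect_equal(as.numeric(dist(p2)), as.numeric(dist(x2)))

  # collinear 5-D points stay collinear in 2-D
  base <- rnorm(5); dir <- rnorm(5)
  x3 <- rbind(base, base + dir, base + 2 * dir)
  p3 <- project_2d(x3)
  v1 <- p3[2, ] - p3[1, ]; v2 <- p3[3, ] - p3[1, ]
  expect_equal(v1[1] * v2[2] - v1[2] * v2[1], 0, tolerance = 1e-10)

  expect_error(project_2d(x3[1:2, ]), "at least 3")
  custom <- function(v, seed) matrix(seed, nrow(v), 2)
  expect_equal(project_2d(x3, method = custom, seed = 4)[1, 1], 4)
})

test_that("eval_report bundles metrics and prints the report layout", {
  set.seed(31)
  y <- rep(c(0L, 1L), 30)
  s <- y * 0.7 + runif(60) * 0.4
  rep_ <- eval_report(y, s, bootstrap = 100, seed = 2)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$n, 60L)
  txt <- capture.output(print(rep_))
  expect_true(any(grepl("precision", txt)))
  expect_true(any(grepl("macro avg", txt)))
  expect_true(any(grepl("CML", txt)))
})
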