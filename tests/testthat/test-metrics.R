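test_that("confusion matrices count correctly", {
  cm <- confusion(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 2L), 2L)
  expect_equal(unclass(cm)[1:2, 1:2],
               matrix(c(1L, 0L, 1L, 2L), 2, 2), ignore_attr = TRUE)
  expect_identical(sum(cm), 4L)
  perfect <- confusion(c(1L, 2L, 3L), c(1L, 2L, 3L), 3L)
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  expect_error(confusion(c(1L, 4L), c(1L, 1L), 3L), "range")
})

test_that("binary collapse of the worked-example matrix matches the tallies", {
  cm <- example_screening_confusion()
  m <- binary_collapse(cm, c("inflammation_ulcer_bleeding_erosion",
                             "polyp_protrusion"))
  expect_identical(m[1, 1], 11430L)   # TP
  expect_identical(m[1, 2], 295L)     # FN
  expect_identical(m[2, 1], 213L)     # FP
  expect_identical(m[2, 2], 16060L)   # TN
  # printed test-set composition
  expect_identical(m[1, 1] + m[1, 2], 11725L)
  expect_identical(sum(m), 27998L)
  # collapsing a diagonal matrix keeps the off-diagonals zero
  d3 <- confusion(c(1L, 2L, 3L), c(1L, 2L, 3L), 3L)
  md <- binary_collapse(d3, 2:3)
  expect_identical(md[1, 2] + md[2, 1], 0L)
  expect_error(binary_collapse(cm, integer(0)), "subset")
  expect_error(binary_collapse(cm, 1:3), "subset")
})

test_that("diagnostic metrics reproduce the worked example at printed precision", {
  cm <- example_screening_confusion()
  bm <- binary_metrics(binary_collapse(cm, 2:3))
  expect_equal(round(100 * bm$sensitivity, 1), 97.5)
  expect_equal(round(100 * bm$specificity, 1), 98.7)
  expect_equal(round(100 * bm$precision, 1), 98.2)
  expect_equal(round(bm$youden, 3), 0.962)
  # the matrix yields F1 ~ 0.978 (the published table prints 0.979);
  # asserted to 2 d.p. only - see the documented discrepancy
  expect_equal(round(bm$f1, 2), 0.98)
  expect_identical(bm$youden, bm$sensitivity + bm$specificity - 1)
  # all-correct table
  all1 <- binary_metrics(matrix(c(10L, 0L, 0L, 10L), 2, 2, byrow = TRUE))
  expect_equal(unlist(all1[c("sensitivity", "specificity", "precision",
                             "accuracy", "f1")]),
               rep(1, 5), ignore_attr = TRUE)
  # zero denominator reports NA, not 0
  deg <- binary_metrics(matrix(c(0L, 0L, 3L, 7L), 2, 2, byrow = TRUE))
  expect_true(is.na(deg$sensitivity))
})

test_that("AUC equals the pairwise ordering probability and the ROC area", {
  # perfectly separated
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # 3 of 4 (pos, neg) pairs correctly ordered
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  # ties counted 1/2
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  # rank and trapezoid methods agree on random vectors
  set.seed(1)
  for (k in 1:20) {
    n <- sample(10:200, 1)
    sc <- round(rnorm(n), sample(0:2, 1))   # force ties sometimes
    lb <- runif(n) < 0.4
    if (!any(lb) || all(lb)) next
    expect_equal(roc_auc(sc, lb, "rank"), roc_auc(sc, lb, "trapezoid"),
                 tolerance = 1e-10)
  }
  # independent scores -> AUC near 1/2
  set.seed(2)
  sc <- rnorm(2000); lb <- runif(2000) < 0.5
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.05)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(3)
  sc <- c(rnorm(80, 1), rnorm(120))
  lb <- rep(c(1, 0), c(80, 120))
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-10)
})

test_that("the Youden threshold matches an exhaustive scan and is shift-invariant", {
  # separable toy: J = 1 attained first at the lowest positive score
  yt <- youden_threshold(c(0.1, 0.2, 0.7, 0.9), c(0, 0, 1, 1))
  expect_equal(yt$threshold, 0.7)
  expect_equal(yt$youden, 1)
  set.seed(4)
  for (k in 1:10) {
    sc <- rnorm(60)
    lb <- runif(60) < 0.5
    if (!any(lb) || all(lb)) next
    yt <- youden_threshold(sc, lb)
    # brute force over all observed-score thresholds
    js <- vapply(sort(unique(sc)), function(th) {
      sens <- mean(sc[lb] >= th); spec <- mean(sc[!lb] < th)
      sens + spec - 1
    }, 0)
    expect_equal(yt$youden, max(js), tolerance = 1e-12)
    # shifting all scores shifts the threshold, J unchanged
    y2 <- youden_threshold(sc + 3, lb)
    expect_equal(y2$threshold, yt$threshold + 3, tolerance = 1e-12)
    expect_equal(y2$youden, yt$youden, tolerance = 1e-12)
  }
  expect_error(youden_threshold(1:3, c(1, 1, 1)), "both classes")
})

test_that("every emitted report satisfies the Youden identity", {
  set.seed(5)
  for (k in 1:20) {
    m <- matrix(sample.int(50, 4, replace = TRUE), 2, 2)
    bm <- binary_metrics(m)
    expect_identical(bm$youden, bm$sensitivity + bm$specificity - 1)
  }
})
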