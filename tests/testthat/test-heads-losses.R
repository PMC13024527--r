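test_that("classification head emits valid softmax probabilities", {
  set.seed(1)
  fused <- array(rnorm(8 * 2 * 2 * 3), c(8, 2, 2, 3))
  hd <- classification_head(8, 3, depth = 2)
  p <- classify(hd, fused)
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # controlled logits through a single-layer head: W = 0, bias = (0, ln 2)
  h1 <- classification_head(8, 2, depth = 1)
  lin <- h1$children[[1]]$layers[[1]]
  lin$par$W[] <- 0
  lin$par$b <- array(c(0, log(2)), 2)
  p1 <- classify(h1, fused)
  expect_equal(p1[, 1], c(1, 2) / 3, tolerance = 1e-10)
  # softmax shift invariance: adding a constant to all logits
  lin$par$b <- array(c(0, log(2)) + 5, 2)
  expect_equal(classify(h1, fused), p1, tolerance = 1e-10)
  # all-equal logits -> uniform
  lin$par$b <- array(0, 2)
  expect_equal(classify(h1, fused)[, 1], c(0.5, 0.5), tolerance = 1e-10)
  expect_error(classification_head(8, 1), "classes")
})

test_that("bounding-box head outputs lie in [0,1] and are deterministic", {
  set.seed(2)
  fused <- array(rnorm(8 * 2 * 2 * 4), c(8, 2, 2, 4))
  bh <- bbox_head(8)
  # zero pre-activation -> (0.5, 0.5, 0.5, 0.5)
  bh$children[[1]]$par$W[] <- 0
  bh$children[[1]]$par$b[] <- 0
  expect_equal(unname(regress_bbox(bh, fused)), matrix(0.5, 4, 4))
  for (i in 1:10) {
    set.seed(i + 10)
    bh2 <- bbox_head(8)
    b <- regress_bbox(bh2, fused)
    expect_true(all(b >= 0 & b <= 1))
    expect_identical(b, regress_bbox(bh2, fused))
  }
})

test_that("cross-entropy matches its closed forms and weight linearity", {
  # perfect one-hot prediction -> 0 (up to the eps clamp)
  p <- matrix(c(1, 0, 0), 3, 1)
  expect_lt(suppressWarnings(cross_entropy_loss(1L, p)), 1e-10)
  # uniform prediction over K classes -> ln K per sample
  K <- 5L
  pu <- matrix(1 / K, K, 4)
  expect_equal(cross_entropy_loss(rep(2L, 4), pu), log(K), tolerance = 1e-12)
  # weight 2 on the minority class doubles that sample's contribution
  set.seed(3)
  probs <- matrix(runif(3 * 6) + 0.1, 3, 6)
  probs <- sweep(probs, 2, colSums(probs), "/")
  y <- c(1L, 1L, 1L, 1L, 2L, 3L)
  base <- cross_entropy_loss(y, probs)
  w <- c(1, 2, 1)
  per <- -log(probs[cbind(y, 1:6)])
  expect_equal(cross_entropy_loss(y, probs, w),
               mean(per * w[y]), tolerance = 1e-12)
  # zero probability at the true class is clamped with a warning
  pz <- matrix(c(0, 1), 2, 1)
  expect_warning(v <- cross_entropy_loss(1L, pz), "clamped")
  expect_true(is.finite(v))
  expect_error(cross_entropy_loss(c(1L, 4L), matrix(0.5, 2, 2)), "range")
})

test_that("smooth L1 matches the Huber closed form on both branches", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(0.5), 0.125)
  expect_equal(smooth_l1(1), 0.5)
  expect_equal(smooth_l1(-1), 0.5)
  expect_equal(smooth_l1(-2), 1.5)
  expect_error(smooth_l1(c(1, Inf)), "finite")
})

test_that("smooth L1 is even, bounded by the quadratic and C1 at the knee", {
  xs <- seq(-4, 4, by = 0.01)
  expect_equal(smooth_l1(xs), smooth_l1(-xs))
  expect_true(all(smooth_l1(xs) <= 0.5 * xs^2 + 1e-14))
  # continuity and continuous first derivative at |x| = 1
  h <- 1e-6
  expect_equal(smooth_l1(1 - h), smooth_l1(1 + h), tolerance = 1e-5)
  dleft <- (smooth_l1(1) - smooth_l1(1 - h)) / h
  dright <- (smooth_l1(1 + h) - smooth_l1(1)) / h
  expect_equal(dleft, 1, tolerance = 1e-4)
  expect_equal(dright, 1, tolerance = 1e-4)
})

test_that("the composite objective holds exactly and masks lesion-free images", {
  lb <- total_loss(0.3, 0.2, 1)
  expect_identical(lb$total, 0.5)
  expect_identical(total_loss(0.7, 5, 0)$total, 0.7)
  expect_identical(lb$total, lb$classification + lb$lambda * lb$regression)
  # monotone non-decreasing in lambda for reg > 0
  ls <- vapply(seq(0, 3, by = 0.5),
               function(lam) total_loss(0.3, 0.2, lam)$total, 0)
  expect_true(all(diff(ls) >= 0))
  expect_error(total_loss(0.3, 0.2, -1), "lambda")
  # masked regression: empty mask contributes nothing
  set.seed(4)
  pred <- matrix(runif(12), 4, 3)
  tgt <- matrix(runif(12), 4, 3)
  expect_identical(bbox_regression_loss(pred, tgt, rep(FALSE, 3)), 0)
  m <- c(TRUE, FALSE, TRUE)
  expect_equal(bbox_regression_loss(pred, tgt, m),
               mean(smooth_l1(pred[, m] - tgt[, m])), tolerance = 1e-12)
})

test_that("inverse-frequency weights emphasize minority classes", {
  w <- inverse_frequency_weights(c(1L, 1L, 1L, 2L), 3L)
  expect_gt(w[2], w[1])
  expect_equal(w[3], 1)   # absent class falls back to weight 1
})
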