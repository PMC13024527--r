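test_that("squash preserves direction and compresses norms into [0, 1)", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  # unit-norm input -> same direction, norm 1/2
  z <- c(1, 0, 0)
  expect_equal(squash(z), c(0.5, 0, 0), tolerance = 1e-7)
  # norm-3 input -> norm 9/10
  z3 <- c(3, 0, 0) / sqrt(1) * 1
  expect_equal(sqrt(sum(squash(z3)^2)), 0.9, tolerance = 1e-7)
  set.seed(1)
  for (i in 1:50) {
    z <- rnorm(sample(2:16, 1)) * 10^runif(1, -2, 2)
    v <- squash(z)
    expect_lt(sqrt(sum(v^2)), 1)
    # direction preserved
    if (sqrt(sum(z^2)) > 1e-6)
      expect_equal(v / sqrt(sum(v^2)), z / sqrt(sum(z^2)), tolerance = 1e-5)
  }
  expect_error(squash(c(1, NA)), "finite")
})

test_that("squash is norm-monotone", {
  set.seed(2)
  dir <- rnorm(6)
  norms <- sort(runif(20, 0, 5))
  out <- vapply(norms, function(n) {
    z <- dir / sqrt(sum(dir^2)) * n
    sqrt(sum(squash(z)^2))
  }, 0)
  expect_true(all(diff(out) > 0))
})

test_that("primary capsule formation counts, squashes and zero-maps correctly", {
  set.seed(3)
  fm <- array(rnorm(32 * 2 * 2), c(32, 2, 2))
  cs <- form_primary_capsules(fm, n_caps_per_cell = 4, d = 8)
  expect_identical(dim(cs$vectors), c(16L, 8L))
  expect_identical(length(cs$cells), 16L)
  # zero map -> zero capsules (linearity + squash(0) = 0)
  W <- matrix(rnorm(32 * 32), 32, 32)
  cs0 <- form_primary_capsules(array(0, c(32, 2, 2)), 4, 8, W = W)
  expect_equal(max(abs(cs0$vectors)), 0)
  # every capsule norm < 1 over many random maps
  for (i in 1:1000) {
    fm <- array(rnorm(16 * 2 * 2, sd = 3), c(16, 2, 2))
    cs <- form_primary_capsules(fm, 2, 8)
    expect_lt(max(sqrt(rowSums(cs$vectors^2))), 1)
  }
  expect_error(form_primary_capsules(fm, 4, 8, W = matrix(0, 5, 16)),
               "channel")
})

test_that("vote prediction equals the per-pair affine transform", {
  set.seed(4)
  N <- 6L; K <- 3L; d <- 4L; dp <- 5L
  u <- matrix(rnorm(N * d), N, d)
  # identity transform (square) returns the capsules themselves
  Wi <- array(0, c(N, K, d, d))
  for (i in 1:N) for (j in 1:K) Wi[i, j, , ] <- diag(d)
  vi <- predict_votes(u, Wi)
  for (j in 1:K) expect_equal(matrix(vi[, j, ], N, d), u)
  # zero transform -> zero votes
  expect_equal(max(abs(predict_votes(u, array(0, c(N, K, dp, d))))), 0)
  # random case vs naive loop oracle
  W <- array(rnorm(N * K * dp * d), c(N, K, dp, d))
  v <- predict_votes(u, W)
  for (i in 1:N) for (j in 1:K)
    expect_equal(v[i, j, ], as.vector(matrix(W[i, j, , ], dp, d) %*% u[i, ]),
                 tolerance = 1e-6)
  expect_error(predict_votes(u, array(0, c(N, K, dp, d + 1))), "incompatible")
})

test_that("routing handles the degenerate single-class case and r = 1", {
  set.seed(5)
  # N = 1, K = 1: coupling 1, v = squash(vote)
  votes <- array(rnorm(4), c(1, 1, 4))
  rt <- dynamic_routing(votes, r = 3)
  expect_equal(rt$couplings[1, 1], 1)
  expect_equal(rt$v[1, ], oracle_squash(votes[1, 1, ]), tolerance = 1e-10)
  # r = 1 with b = 0: uniform couplings c = 1/K
  votes <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  rt1 <- dynamic_routing(votes, r = 1)
  for (j in 1:3) {
    s <- colSums(matrix(votes[, j, ], 5, 4)) / 3
    expect_equal(rt1$v[j, ], oracle_squash(s), tolerance = 1e-10)
  }
  expect_error(dynamic_routing(votes, r = 0), "iteration")
})

test_that("aligned votes attract monotonically growing couplings", {
  # two aligned votes for class 1, one orthogonal: agreement reinforces the
  # aligned pair across iterations
  votes <- array(0, c(3, 2, 4))
  votes[1, 1, ] <- c(1, 0, 0, 0)
  votes[2, 1, ] <- c(1, 0.05, 0, 0)
  votes[3, 1, ] <- c(0, 0, 1, 0)
  votes[, 2, ] <- matrix(rep(c(0, 0, 0, 0.2), each = 3), 3, 4)
  prev <- 0.5
  cpl <- c()
  for (r in 1:4) {
    rt <- dynamic_routing(votes, r)
    cpl <- c(cpl, rt$couplings[1, 1])
  }
  expect_gt(cpl[4], 0.5)
  expect_true(all(diff(cpl) >= -1e-12))
})

test_that("vectorized routing matches the naive triple-loop oracle", {
  set.seed(6)
  for (t in 1:20) {
    N <- sample(2:20, 1); K <- sample(2:5, 1)
    dd <- sample(2:8, 1); r <- sample(1:4, 1)
    votes <- array(rnorm(N * K * dd), c(N, K, dd))
    a <- dynamic_routing(votes, r)
    b <- oracle_routing(votes, r)
    expect_lt(max(abs(a$v - b$v)), 1e-5)
    expect_lt(max(abs(a$couplings - b$couplings)), 1e-5)
    # coupling normalization and squashed norms
    expect_equal(rowSums(a$couplings), rep(1, N), tolerance = 1e-6)
    expect_true(all(a$couplings > 0))
    expect_true(all(sqrt(rowSums(a$v^2)) < 1))
  }
})

test_that("category capsules re-spatialize by broadcast to the target grid", {
  set.seed(7)
  v <- matrix(rnorm(3 * 16), 3, 16)
  fm <- capsules_to_feature_map(v, c(7, 7))
  expect_identical(dim(fm), c(48L, 7L, 7L))
  # every cell carries the same concatenated vector
  for (i in 1:7) for (j in 1:7)
    expect_equal(fm[, i, j], as.vector(t(v)))
  expect_equal(max(abs(capsules_to_feature_map(matrix(0, 3, 16), c(2, 2)))), 0)
  expect_error(capsules_to_feature_map(v, c(0, 7)), "target")
})

test_that("the batched capsule branch agrees with the per-image functional path", {
  set.seed(8)
  cb <- duodet:::capsule_branch(8, n_caps = 2, d = 4, dprime = 5, K = 3, r = 3)
  fc <- array(rnorm(8 * 2 * 2 * 3), c(8, 2, 2, 3))
  fv <- cb$forward(fc, training = FALSE)
  Wconv <- cb$children[[1]]$par$W
  for (n in 1:3) {
    cs <- form_primary_capsules(fc[, , , n], 2, 4, W = Wconv)
    Ni <- nrow(cs$vectors)
    votes <- array(0, c(Ni, 3, 5))
    for (i in seq_len(Ni)) {
      t_i <- ((i - 1) %% 2) + 1
      for (j in 1:3)
        votes[i, j, ] <- matrix(cb$par$Wt[, , t_i, j], 5, 4) %*% cs$vectors[i, ]
    }
    rt <- dynamic_routing(votes, 3)
    expect_equal(fv[, , , n], capsules_to_feature_map(rt$v, c(2, 2)),
                 tolerance = 1e-10)
  }
})
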