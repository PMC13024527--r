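# Shared test helpers: finite-difference gradients and a naive
# routing-by-agreement oracle kept deliberately independent of the package's
# vectorized implementation.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_squash <- function(z, eps = 1e-8) {
  n <- sqrt(sum(z^2))
  z * (n^2 / ((1 + n^2) * (n + eps)))
}

# routing by explicit loops over capsules, classes and components
oracle_routing <- function(votes, r) {
  N <- dim(votes)[1]; K <- dim(votes)[2]; dd <- dim(votes)[3]
  softmax <- function(row) { e <- exp(row - max(row)); e / sum(e) }
  b <- matrix(0, N, K)
  v <- matrix(0, K, dd)
  for (it in seq_len(r)) {
    cc <- t(apply(b, 1L, softmax))
    if (K == 1L) cc <- matrix(1, N, 1L)
    for (j in seq_len(K)) {
      s <- rep(0, dd)
      for (i in seq_len(N)) s <- s + cc[i, j] * votes[i, j, ]
      v[j, ] <- oracle_squash(s)
    }
    if (it < r) {
      for (i in seq_len(N)) for (j in seq_len(K))
        b[i, j] <- b[i, j] + sum(votes[i, j, ] * v[j, ])
    }
  }
  cc <- t(apply(b, 1L, softmax))
  if (K == 1L) cc <- matrix(1, N, 1L)
  list(v = v, couplings = cc, logits = b)
}

# tiny labeled dataset helper
subset_data <- function(d, i) {
  list(x = d$x[, , , i, drop = FALSE], labels = d$labels[i],
       bbox = d$bbox[, i, drop = FALSE], mask = d$mask[i])
}

# re-attach generator metadata so a split behaves like a full dataset
subset_to_dataset <- function(sub, full) {
  sub$class_names <- full$class_names
  sub
}
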