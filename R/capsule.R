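#' Squash nonlinearity
#'
#' Compresses a capsule vector's norm into `[0, 1)` while preserving its
#' direction: `v = (||z||^2 / (1 + ||z||^2)) * z / (||z|| + eps)`. The norm of
#' the output is `||z||^2 / (1 + ||z||^2)`, so presence probability saturates
#' smoothly towards (but never reaches) 1. The `eps` term guards the 0/0
#' direction at the zero vector, which maps to the zero vector.
#'
#' @param z numeric vector, or matrix whose columns are capsule vectors.
#' @param eps small positive guard for the zero-vector direction.
#' @return object of the same shape as `z`.
#' @export
squash <- function(z, eps = 1e-8) {
  if (!all(is.finite(z))) stop("squash: non-finite input")
  if (is.matrix(z)) {
    n <- sqrt(colSums(z * z))
    scale <- n^2 / ((1 + n^2) * (n + eps))
    return(sweep(z, 2L, scale, `*`))
  }
  n <- sqrt(sum(z * z))
  z * (n^2 / ((1 + n^2) * (n + eps)))
}

# Backward of squash for columns-as-capsules matrices; s is the pre-squash
# input cached at forward time. Uses the closed form h(n) = n/(1+n^2),
# h'(n) = (1-n^2)/(1+n^2)^2; the eps guard only matters at n ~ 0 where both
# terms vanish.
squash_backward <- function(s, dv, eps = 1e-8) {
  n <- sqrt(colSums(s * s))
  h <- n / (1 + n^2)
  hp <- (1 - n^2) / (1 + n^2)^2
  sdv <- colSums(s * dv)
  sweep(dv, 2L, h, `*`) + sweep(s, 2L, hp * sdv / pmax(n, eps), `*`)
}

#' Form primary capsules from a feature map
#'
#' Applies a 1x1 capsule-forming convolution mapping the `C` input channels
#' to `n_caps_per_cell * d` channels, partitions each spatial cell's
#' activation into `n_caps_per_cell` vectors of dimension `d`, and squashes
#' each vector. Capsule-to-cell provenance is retained so category capsules
#' can later be re-spatialized.
#'
#' @param fm feature map of dim `(C, Hc, Wc)` (single image).
#' @param n_caps_per_cell capsules formed per spatial cell.
#' @param d primary capsule dimensionality.
#' @param W optional `(n_caps_per_cell * d) x C` weight matrix for the 1x1
#'   convolution; defaults to He-initialized weights from the current RNG.
#' @return a `capsule_set`: list with `vectors` (`N x d`, one capsule per
#'   row), `cells` (cell index of each capsule), `spatial` (`c(Hc, Wc)`).
#' @export
form_primary_capsules <- function(fm, n_caps_per_cell, d, W = NULL) {
  dm <- dim(fm)
  if (length(dm) != 3L) stop("form_primary_capsules: expected (C,Hc,Wc) map")
  C <- dm[1]; hc <- dm[2]; wc <- dm[3]
  nc <- as.integer(n_caps_per_cell) * as.integer(d)
  if (is.null(W)) W <- he_init(c(nc, C), C)
  if (!all(dim(W) == c(nc, C)))
    stop("form_primary_capsules: weight must map ", C, " channels to ",
         n_caps_per_cell, " x ", d, " = ", nc, " capsule channels")
  y <- W %*% matrix(fm, C, hc * wc)           # (n_caps*d) x cells
  ncell <- hc * wc
  u <- array(y, dim = c(d, n_caps_per_cell, ncell))
  m <- matrix(u, d, n_caps_per_cell * ncell)  # capsule index = (t, cell)
  v <- squash(m)
  structure(list(
    vectors = t(v),
    cells = rep(seq_len(ncell), each = n_caps_per_cell),
    n_caps_per_cell = as.integer(n_caps_per_cell),
    d = as.integer(d),
    spatial = c(hc, wc)
  ), class = "capsule_set")
}

#' Affine vote prediction
#'
#' Each lower capsule `u_i` predicts every category capsule through an
#' affine transform: `vote[i, j, ] = W[i, j, , ] %*% u[i, ]`.
#'
#' @param caps `N x d` matrix of capsule vectors (rows), or a `capsule_set`.
#' @param W transform weights, array of dim `(N, K, d_out, d)`.
#' @return vote tensor, array of dim `(N, K, d_out)`.
#' @export
predict_votes <- function(caps, W) {
  u <- if (inherits(caps, "capsule_set")) caps$vectors else caps
  dw <- dim(W)
  if (length(dw) != 4L) stop("predict_votes: W must have dim (N, K, d_out, d)")
  N <- nrow(u); d <- ncol(u)
  if (dw[1] != N || dw[4] != d)
    stop("predict_votes: W dim ", paste(dw, collapse = "x"),
         " incompatible with ", N, " capsules of dim ", d)
  K <- dw[2]; dout <- dw[3]
  votes <- array(0, dim = c(N, K, dout))
  for (i in seq_len(N)) {
    for (j in seq_len(K)) {
      votes[i, j, ] <- matrix(W[i, j, , ], dout, d) %*% u[i, ]
    }
  }
  votes
}

#' Dynamic routing-by-agreement
#'
#' Iteratively re-weights the contribution of each lower capsule's vote to
#' each category capsule. Logits `b` start at zero, so the first couplings
#' are uniform `1/K`. Each round computes `s_j = sum_i c_ij vote_ij`,
#' `v_j = squash(s_j)`, then reinforces `b_ij` by the scalar agreement
#' `vote_ij . v_j`; couplings are the softmax of `b` over the category axis.
#'
#' @param votes array of dim `(N, K, d_out)` from [predict_votes()].
#' @param r number of routing iterations (>= 1).
#' @param eps squash guard.
#' @return list with `v` (`K x d_out` category capsules), `couplings`
#'   (`N x K`, rows summing to 1), `logits` (`N x K`) and `iterations`.
#' @export
dynamic_routing <- function(votes, r = 3L, eps = 1e-8) {
  if (r < 1L) stop("dynamic_routing: at least one iteration required")
  dv <- dim(votes)
  if (length(dv) != 3L) stop("dynamic_routing: votes must have dim (N, K, d_out)")
  N <- dv[1]; K <- dv[2]; dout <- dv[3]
  b <- matrix(0, N, K)
  v <- NULL
  for (it in seq_len(r)) {
    cc <- softmax_rows(b)
    s <- matrix(0, dout, K)
    for (j in seq_len(K)) {
      s[, j] <- crossprod(matrix(votes[, j, ], N, dout), cc[, j])
    }
    v <- squash(s, eps)                      # d_out x K, columns squashed
    if (it < r) {
      for (j in seq_len(K)) {
        b[, j] <- b[, j] + matrix(votes[, j, ], N, dout) %*% v[, j]
      }
    }
  }
  cc <- softmax_rows(b)
  list(v = t(v), couplings = cc, logits = b, iterations = r)
}

softmax_rows <- function(b) {
  e <- exp(b - apply(b, 1L, max))
  e / rowSums(e)
}

#' Re-spatialize category capsules into a feature map
#'
#' Concatenates the K category capsule vectors into a `K * d_out` channel
#' vector and broadcasts it to every cell of the target spatial grid, so the
#' pose-aware map shares the convolutional branch's spatial dimensions.
#'
#' @param v `K x d_out` matrix of category capsules (rows), or the list
#'   returned by [dynamic_routing()].
#' @param target spatial dims `c(Hc, Wc)` of the convolutional feature map.
#' @return array of dim `(K * d_out, Hc, Wc)`.
#' @export
capsules_to_feature_map <- function(v, target) {
  if (is.list(v)) v <- v$v
  if (length(target) != 2L || any(target < 1L))
    stop("capsules_to_feature_map: target must be positive c(Hc, Wc)")
  ch <- as.vector(t(v))                       # d_out fastest within capsule
  array(ch, dim = c(length(ch), target[1], target[2]))
}

# ---------------------------------------------------------------------------
# Batched capsule branch layer used inside the assembled model.
#
# forward: Fc (C,Hc,Wc,B) -> 1x1 capsule-forming conv -> primary capsules
# (d, n_caps, cells, B) -> squash -> shared-transform votes
# (d_out, Ni, K, B), Ni = n_caps * cells -> routing -> category capsules
# (d_out, K, B) -> broadcast to (K*d_out, Hc, Wc, B).
#
# backward treats the final coupling coefficients as constants (routing is
# not unrolled); gradients flow through the weighted sum, both squashes, the
# vote transforms and the capsule-forming convolution.
capsule_branch <- function(in_c, n_caps = 8L, d = 8L, dprime = 16L, K = 3L,
                           r = 3L, eps = 1e-8) {
  l <- new_layer("capsule_branch")
  l$n_caps <- as.integer(n_caps); l$d <- as.integer(d)
  l$dprime <- as.integer(dprime); l$K <- as.integer(K); l$r <- as.integer(r)
  l$eps <- eps
  conv <- layer_conv2d(in_c, n_caps * d, k = 1L)
  l$children <- list(conv)
  # shared affine transforms: one (dprime x d) matrix per (capsule type, class)
  l$par$Wt <- he_init(c(dprime, d, n_caps, K), d)
  l$out_channels <- K * dprime

  l$forward <- function(fc, training = FALSE) {
    dm <- dim(fc)
    hc <- dm[2]; wc <- dm[3]; B <- dm[4]
    ncell <- hc * wc
    y <- conv$forward(fc, training)                 # (n_caps*d, hc, wc, B)
    u_pre <- matrix(y, l$d, l$n_caps * ncell * B)   # cols: (t, cell, B)
    u <- squash(u_pre, l$eps)
    Ni <- l$n_caps * ncell
    # votes: (dprime, Ni, K, B); capsule i = (type t, cell)
    votes <- array(0, dim = c(l$dprime, Ni, l$K, B))
    u_arr <- array(u, dim = c(l$d, l$n_caps, ncell * B))
    for (t in seq_len(l$n_caps)) {
      ut <- matrix(u_arr[, t, ], l$d, ncell * B)
      for (j in seq_len(l$K)) {
        vt <- matrix(l$par$Wt[, , t, j], l$dprime, l$d) %*% ut
        votes[, seq(t, Ni, by = l$n_caps), j, ] <-
          array(vt, dim = c(l$dprime, ncell, B))
      }
    }
    # routing
    b <- array(0, dim = c(Ni, l$K, B))
    v <- s <- NULL
    for (it in seq_len(l$r)) {
      cc <- softmax_mid(b)
      s <- array(0, dim = c(l$dprime, l$K, B))
      for (j in seq_len(l$K)) {
        wv <- matrix(votes[, , j, ], l$dprime, Ni * B) *
          rep(as.vector(cc[, j, ]), each = l$dprime)
        s[, j, ] <- colSums(aperm(array(wv, c(l$dprime, Ni, B)), c(2, 1, 3)))
      }
      v <- array(squash(matrix(s, l$dprime, l$K * B), l$eps),
                 dim = c(l$dprime, l$K, B))
      if (it < l$r) b <- agreement_update(b, votes, v)
    }
    cc <- softmax_mid(b)
    if (training) {
      l$cache <- list(u_pre = u_pre, u = u, votes = votes, cc = cc, s = s,
                      hc = hc, wc = wc, B = B, ncell = ncell, Ni = Ni)
    }
    # broadcast category capsules to the spatial grid
    fv <- array(0, dim = c(l$out_channels, hc, wc, B))
    vb <- matrix(v, l$dprime * l$K, B)
    for (n in seq_len(B)) fv[, , , n] <- vb[, n]
    l$last_v <- v
    l$last_cc <- cc
    fv
  }

  l$backward <- function(dfv) {
    ca <- l$cache
    dm <- dim(dfv)
    hc <- ca$hc; wc <- ca$wc; B <- ca$B; Ni <- ca$Ni; ncell <- ca$ncell
    # broadcast backward: sum over cells
    dv <- array(0, dim = c(l$dprime * l$K, B))
    m <- matrix(dfv, l$dprime * l$K, hc * wc * B)
    dv <- rowsum(t(m), group = rep(seq_len(B), each = hc * wc))  # B x (dprime*K)
    dv <- t(dv)
    # through final squash: columns are (j, b) capsules
    ds <- squash_backward(matrix(ca$s, l$dprime, l$K * B),
                          matrix(dv, l$dprime, l$K * B), l$eps)
    ds <- array(ds, dim = c(l$dprime, l$K, B))
    # through weighted sum with couplings fixed
    dvotes <- array(0, dim = c(l$dprime, Ni, l$K, B))
    for (j in seq_len(l$K)) {
      dsj <- matrix(ds[, j, ], l$dprime, B)
      dvj <- dsj[, rep(seq_len(B), each = Ni), drop = FALSE] *
        rep(as.vector(ca$cc[, j, ]), each = l$dprime)
      dvotes[, , j, ] <- array(dvj, c(l$dprime, Ni, B))
    }
    # through the shared transforms
    du <- matrix(0, l$d, l$n_caps * ncell * B)
    u_arr <- array(ca$u, dim = c(l$d, l$n_caps, ncell * B))
    l$gr$Wt <- array(0, dim = dim(l$par$Wt))
    for (t in seq_len(l$n_caps)) {
      ut <- matrix(u_arr[, t, ], l$d, ncell * B)
      idx <- seq(t, Ni, by = l$n_caps)
      dut <- matrix(0, l$d, ncell * B)
      for (j in seq_len(l$K)) {
        dvt <- matrix(dvotes[, idx, j, ], l$dprime, ncell * B)
        Wtj <- matrix(l$par$Wt[, , t, j], l$dprime, l$d)
        l$gr$Wt[, , t, j] <- dvt %*% t(ut)
        dut <- dut + crossprod(Wtj, dvt)
      }
      # scatter back into (t, cell, B) column order
      cols <- as.vector(outer(t, seq_len(ncell * B), function(a, b) a + (b - 1L) * l$n_caps))
      du[, cols] <- dut
    }
    # through the primary squash
    du_pre <- squash_backward(ca$u_pre, du, l$eps)
    dy <- array(du_pre, dim = c(l$n_caps * l$d, hc, wc, B))
    l$cache <- NULL
    conv$backward(dy)
  }
  l
}

# softmax over the middle (class) axis of an (Ni, K, B) array
softmax_mid <- function(b) {
  d <- dim(b)
  m <- b[, 1, , drop = FALSE]
  if (d[2] > 1L) for (j in 2:d[2]) m <- pmax(m, b[, j, , drop = FALSE])
  e <- exp(b - array(m[, rep(1L, d[2]), ], d))
  tot <- array(0, dim = c(d[1], 1, d[3]))
  for (j in seq_len(d[2])) tot <- tot + e[, j, , drop = FALSE]
  e / array(tot[, rep(1L, d[2]), ], d)
}

# b_ij <- b_ij + vote_ij . v_j for an (Ni,K,B) logit array
agreement_update <- function(b, votes, v) {
  d <- dim(votes)                 # (dprime, Ni, K, B)
  Ni <- d[2]; K <- d[3]; B <- d[4]
  for (j in seq_len(K)) {
    vj <- matrix(v[, j, ], d[1], B)
    vexp <- vj[, rep(seq_len(B), each = Ni), drop = FALSE]
    a <- colSums(matrix(votes[, , j, ], d[1], Ni * B) * vexp)
    b[, j, ] <- b[, j, ] + array(a, c(Ni, B))
  }
  b
}
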