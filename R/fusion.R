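#' Scalar-weighted feature fusion
#'
#' Elementwise convex combination `alpha * Fc + (1 - alpha) * Fv` of two
#' channel-aligned feature maps, the fixed-coefficient ancestor of the
#' learned attention gate. Retained as a diagnostic/teaching mode.
#'
#' @param Fc,Fv feature maps of identical dim.
#' @param alpha fusion coefficient in `[0, 1]`.
#' @return fused map of the same dim.
#' @export
scalar_fusion <- function(Fc, Fv, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("scalar_fusion: alpha must be a single value in [0, 1]")
  if (!identical(dim(Fc), dim(Fv)))
    stop("scalar_fusion: inputs must be channel- and spatially aligned")
  alpha * Fc + (1 - alpha) * Fv
}

#' Summation / concatenation fusion (ablation variants)
#'
#' `sum` adds the two channel-aligned maps; `concat` stacks them on the
#' channel axis and reduces back to `Fc`'s channel count with a 1x1
#' convolution.
#'
#' @param Fc,Fv feature maps sharing spatial dims (and channels for `sum`).
#' @param mode `"sum"` or `"concat"`.
#' @param W_reduce optional `Cc x (Cc + Cv)` reduction weights for `concat`;
#'   defaults to He-initialized weights from the current RNG.
#' @return fused map with `Fc`'s dim.
#' @export
ablation_fusion <- function(Fc, Fv, mode = c("sum", "concat"), W_reduce = NULL) {
  mode <- match.arg(mode)
  dc <- dim(Fc); dv <- dim(Fv)
  if (!identical(dc[-1], dv[-1]))
    stop("ablation_fusion: spatial dims must match")
  if (mode == "sum") {
    if (dc[1] != dv[1]) stop("ablation_fusion: sum requires aligned channels")
    return(Fc + Fv)
  }
  cc <- dc[1]; cv <- dv[1]
  if (is.null(W_reduce)) W_reduce <- he_init(c(cc, cc + cv), cc + cv)
  hwn <- prod(dc[-1])
  cat_m <- rbind(matrix(Fc, cc, hwn), matrix(Fv, cv, hwn))
  out <- W_reduce %*% cat_m
  dim(out) <- dc
  out
}

#' Channel-attention fusion
#'
#' The learned gate of the full model: the channel-concatenated inputs are
#' globally average-pooled, passed through a two-layer bottleneck MLP and a
#' sigmoid, giving a per-channel gate `alpha` in `(0,1)^Cc`; the output is
#' `alpha (.) Fc + (1 - alpha) (.) phi(Fv)` where `phi` is a 1x1
#' channel-alignment convolution.
#'
#' @param Fc convolutional feature map `(Cc, H, W)` or `(Cc, H, W, N)`.
#' @param Fv capsule feature map with the same spatial dims.
#' @param gate a [fusion_layer()] in `"attention"` mode matching the channel
#'   counts; created (randomly initialized) when omitted.
#' @return fused map with attribute `"alpha"` (`Cc x N` gate values).
#' @export
attention_fusion <- function(Fc, Fv, gate = NULL) {
  had_batch <- length(dim(Fc)) == 4L
  if (!had_batch) {
    dim(Fc) <- c(dim(Fc), 1L)
    dim(Fv) <- c(dim(Fv), 1L)
  }
  if (!identical(dim(Fc)[2:3], dim(Fv)[2:3]))
    stop("attention_fusion: spatial dims must match")
  if (is.null(gate)) gate <- fusion_layer(dim(Fc)[1], dim(Fv)[1], "attention")
  out <- gate$forward_pair(Fc, Fv, training = FALSE)
  if (!had_batch) dim(out) <- dim(out)[1:3]
  attr(out, "alpha") <- gate$last_alpha
  out
}

#' Fusion layer constructor
#'
#' Builds the trainable fusion block combining the convolutional map (`Cc`
#' channels) and capsule map (`Cv` channels). All modes align `Fv` to `Cc`
#' channels through a bias-free 1x1 convolution `phi` (skipped when already
#' aligned) and preserve spatial dims, so downstream heads are mode-agnostic.
#'
#' @param cc,cv channel counts of the convolutional and capsule maps.
#' @param mode `"attention"` (learned per-channel gate), `"scalar"` (fixed
#'   coefficient), `"sum"` or `"concat"`.
#' @param reduction bottleneck reduction of the gate MLP.
#' @param alpha fixed coefficient for `"scalar"` mode.
#' @param pool pooling feeding the gate MLP (`"avg"`, or `"max"` for the
#'   max-pooling ablation).
#' @return layer object with `$forward_pair(Fc, Fv, training)` and
#'   `$backward(dy)` returning `list(dFc, dFv)`.
#' @export
fusion_layer <- function(cc, cv, mode = c("attention", "scalar", "sum", "concat"),
                         reduction = 16L, alpha = 0.5, pool = "avg") {
  mode <- match.arg(mode)
  if (alpha < 0 || alpha > 1) stop("fusion_layer: alpha must lie in [0, 1]")
  if (reduction < 1L) stop("fusion_layer: reduction must be >= 1")
  l <- new_layer(paste0("fusion_", mode))
  l$cc <- cc; l$cv <- cv; l$mode <- mode; l$alpha_scalar <- alpha
  phi <- if (cv != cc || mode == "attention") layer_conv2d(cv, cc, k = 1L) else NULL
  kids <- list()
  if (!is.null(phi)) kids <- c(kids, list(phi))
  if (mode == "attention") {
    hidden <- max(1L, cc %/% reduction)
    lin1 <- layer_linear(cc + cv, hidden)
    lin2 <- layer_linear(hidden, cc)
    relu <- layer_relu()
    gpool <- layer_global_pool(pool)
    kids <- c(kids, list(lin1, lin2))
    l$lin1 <- lin1; l$lin2 <- lin2; l$relu <- relu; l$gpool <- gpool
  }
  if (mode == "concat") {
    reduce <- layer_conv2d(2L * cc, cc, k = 1L)
    kids <- c(kids, list(reduce))
    l$reduce <- reduce
  }
  l$children <- kids
  l$phi <- phi
  l$out_channels <- cc

  l$forward_pair <- function(Fc, Fv, training = FALSE) {
    if (!identical(dim(Fc)[2:3], dim(Fv)[2:3]))
      stop("fusion: spatial dims of the two branches must match")
    pv <- if (is.null(phi)) Fv else phi$forward(Fv, training)
    if (l$mode == "sum") {
      out <- Fc + pv
    } else if (l$mode == "scalar") {
      out <- l$alpha_scalar * Fc + (1 - l$alpha_scalar) * pv
    } else if (l$mode == "concat") {
      d <- dim(Fc)
      cat_t <- array(rbind(matrix(Fc, d[1], prod(d[-1])),
                           matrix(pv, d[1], prod(d[-1]))),
                     dim = c(2L * d[1], d[2], d[3], d[4]))
      out <- l$reduce$forward(cat_t, training)
    } else {
      d <- dim(Fc)
      cat_t <- array(rbind(matrix(Fc, l$cc, prod(d[-1])),
                           matrix(Fv, l$cv, prod(d[-1]))),
                     dim = c(l$cc + l$cv, d[2], d[3], d[4]))
      g <- l$gpool$forward(cat_t, training)            # (cc+cv, B)
      h <- l$relu$forward(l$lin1$forward(g, training), training)
      logit <- l$lin2$forward(h, training)
      a <- 1 / (1 + exp(-logit))                       # (cc, B)
      out <- array(0, dim = d)
      for (n in seq_len(d[4]))
        out[, , , n] <- a[, n] * Fc[, , , n] + (1 - a[, n]) * pv[, , , n]
      l$last_alpha <- a
      if (training) l$att_cache <- list(Fc = Fc, pv = pv, a = a, d = d)
    }
    if (training) l$fwd_mode_batch <- dim(Fc)[4]
    out
  }

  l$backward <- function(dy) {
    if (l$mode == "sum") {
      dFc <- dy
      dpv <- dy
    } else if (l$mode == "scalar") {
      dFc <- l$alpha_scalar * dy
      dpv <- (1 - l$alpha_scalar) * dy
    } else if (l$mode == "concat") {
      dcat <- l$reduce$backward(dy)
      d <- dim(dy)
      m <- matrix(dcat, 2L * d[1], prod(d[-1]))
      dFc <- array(m[seq_len(d[1]), ], dim = d)
      dpv <- array(m[d[1] + seq_len(d[1]), ], dim = d)
    } else {
      ca <- l$att_cache
      d <- ca$d
      a <- ca$a
      dFc <- array(0, dim = d)
      dpv <- array(0, dim = d)
      dalpha <- matrix(0, l$cc, d[4])
      for (n in seq_len(d[4])) {
        dFc[, , , n] <- a[, n] * dy[, , , n]
        dpv[, , , n] <- (1 - a[, n]) * dy[, , , n]
        diff <- ca$Fc[, , , n] - ca$pv[, , , n]
        dalpha[, n] <- rowSums(matrix(dy[, , , n] * diff, l$cc, d[2] * d[3]))
      }
      dlogit <- dalpha * a * (1 - a)
      dh <- l$lin2$backward(dlogit)
      dg <- l$lin1$backward(l$relu$backward(dh))
      dcat <- l$gpool$backward(dg)                     # (cc+cv, H, W, B)
      m <- matrix(dcat, l$cc + l$cv, prod(d[-1]))
      dFc <- dFc + array(m[seq_len(l$cc), ], dim = d)
      dFv_gate <- array(m[l$cc + seq_len(l$cv), ],
                        dim = c(l$cv, d[2], d[3], d[4]))
      dFv <- if (is.null(phi)) dpv else phi$backward(dpv)
      l$att_cache <- NULL
      return(list(dFc = dFc, dFv = dFv + dFv_gate))
    }
    dFv <- if (is.null(phi)) dpv else phi$backward(dpv)
    list(dFc = dFc, dFv = dFv)
  }
  l
}
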