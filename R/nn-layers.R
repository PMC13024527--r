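# Minimal layer framework. Activations are dense arrays with dim
# c(C, H, W, N) -- channel-first, column-major -- so 1x1 convolutions and
# per-channel statistics reduce to plain matrix operations on a C x (H*W*N)
# view. Each layer is an environment exposing $par (named list of parameter
# arrays), $gr (matching gradients), $forward(x, training) and $backward(dy).
# Backward must be called right after the forward pass whose intermediates it
# consumes.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$par <- list()
  e$gr <- list()
  e
}

#' @keywords internal
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

zero_like <- function(p) lapply(p, function(a) array(0, dim = dim(a) %||% length(a)))

`%||%` <- function(a, b) if (is.null(a)) b else a

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# 2-D convolution. Weight matrix rows: out channels; columns ordered
# (c, kh, kw) with c fastest, matching im2col_cpp.
layer_conv2d <- function(in_c, out_c, k, stride = 1L, pad = 0L, bias = FALSE) {
  l <- new_layer("conv2d")
  l$in_c <- in_c; l$out_c <- out_c; l$k <- as.integer(k)
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  fan_in <- in_c * k * k
  l$par$W <- he_init(c(out_c, fan_in), fan_in)
  if (bias) l$par$b <- array(0, out_c)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (length(d) != 4L || d[1] != l$in_c)
      stop("conv2d: expected input with ", l$in_c, " channels, got dim ",
           paste(d, collapse = "x"))
    oH <- conv_out_dim(d[2], l$k, l$stride, l$pad)
    oW <- conv_out_dim(d[3], l$k, l$stride, l$pad)
    if (oH < 1L || oW < 1L) stop("conv2d: input spatially smaller than kernel")
    if (l$k == 1L && l$stride == 1L && l$pad == 0L) {
      cols <- x
      dim(cols) <- c(d[1], d[2] * d[3] * d[4])
    } else {
      cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    }
    y <- l$par$W %*% cols
    if (!is.null(l$par$b)) y <- y + as.vector(l$par$b)
    if (training) { l$cols <- cols; l$in_dim <- d }
    dim(y) <- c(l$out_c, oH, oW, d[4])
    y
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    dim(dy) <- c(l$out_c, length(dy) %/% l$out_c)
    l$gr$W <- tcrossprod(dy, l$cols)
    if (!is.null(l$par$b)) l$gr$b <- array(rowSums(dy), l$out_c)
    dcols <- crossprod(l$par$W, dy)
    if (l$k == 1L && l$stride == 1L && l$pad == 0L) {
      dx <- dcols
    } else {
      dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    }
    l$cols <- NULL
    dim(dx) <- d
    dx
  }
  l
}

# Batch normalization over (H, W, N) per channel.
layer_bn2d <- function(C, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn2d")
  l$C <- C; l$momentum <- momentum; l$eps <- eps
  l$par$gamma <- array(1, C)
  l$par$beta <- array(0, C)
  l$running_mean <- rep(0, C)
  l$running_var <- rep(1, C)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    m <- x
    dim(m) <- c(d[1], prod(d[-1]))
    if (training) {
      mu <- rowMeans(m)
      xc <- m - mu
      v <- rowMeans(xc * xc)
      l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
      l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- xc * invstd
      l$xhat <- xhat; l$invstd <- invstd; l$in_dim <- d
      y <- as.vector(l$par$gamma) * xhat + as.vector(l$par$beta)
    } else {
      invstd <- 1 / sqrt(l$running_var + l$eps)
      y <- as.vector(l$par$gamma) * (m - l$running_mean) * invstd +
        as.vector(l$par$beta)
    }
    dim(y) <- d
    y
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    dim(dy) <- c(d[1], prod(d[-1]))
    xhat <- l$xhat
    l$gr$gamma <- array(rowSums(dy * xhat), l$C)
    l$gr$beta <- array(rowSums(dy), l$C)
    g <- as.vector(l$par$gamma) * l$invstd
    m1 <- rowMeans(dy)
    m2 <- rowMeans(dy * xhat)
    dx <- g * (dy - m1 - xhat * m2)
    l$xhat <- NULL
    dim(dx) <- d
    dx
  }
  l
}

layer_relu <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, training = FALSE) {
    m <- x > 0
    if (training) l$mask <- m
    x * m
  }
  l$backward <- function(dy) {
    dx <- dy * l$mask
    l$mask <- NULL
    dx
  }
  l
}

layer_maxpool2d <- function(k, stride, pad = 0L) {
  l <- new_layer("maxpool2d")
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    oH <- conv_out_dim(d[2], l$k, l$stride, l$pad)
    oW <- conv_out_dim(d[3], l$k, l$stride, l$pad)
    res <- maxpool_fwd_cpp(x, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
    if (training) { l$argmax <- res$argmax; l$n_in <- length(x); l$in_dim <- d }
    y <- res$out
    dim(y) <- c(d[1], oH, oW, d[4])
    y
  }
  l$backward <- function(dy) {
    dx <- maxpool_bwd_cpp(dy, l$argmax, l$n_in)
    dim(dx) <- l$in_dim
    l$argmax <- NULL
    dx
  }
  l
}

# Global pooling (C,H,W,N) -> (C,N). mode "avg" or "max".
layer_global_pool <- function(mode = c("avg", "max")) {
  mode <- match.arg(mode)
  l <- new_layer(paste0("gpool_", mode))
  l$mode <- mode
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    hw <- d[2] * d[3]
    if (hw < 1L) stop("global pool: empty spatial extent")
    if (training) l$in_dim <- d
    if (l$mode == "avg") {
      m <- x
      dim(m) <- c(d[1] * hw, d[4])
      y <- rowsum(m, group = rep(seq_len(d[1]), times = hw), reorder = TRUE) / hw
    } else {
      y <- matrix(0, d[1], d[4])
      arg <- integer(d[1] * d[4])
      xm <- x
      dim(xm) <- c(d[1], hw, d[4])
      for (n in seq_len(d[4])) {
        m <- matrix(xm[, , n], d[1], hw)
        j <- max.col(m, ties.method = "first")
        y[, n] <- m[cbind(seq_len(d[1]), j)]
        arg[(n - 1L) * d[1] + seq_len(d[1])] <-
          seq_len(d[1]) + (j - 1L) * d[1] + (n - 1L) * d[1] * hw
      }
      if (training) l$argmax <- arg
    }
    matrix(y, nrow = d[1], ncol = d[4])
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    hw <- d[2] * d[3]
    if (l$mode == "avg") {
      dx <- array(0, dim = d)
      per <- matrix(as.vector(dy) / hw, d[1], d[4])
      for (n in seq_len(d[4])) dx[, , , n] <- per[, n]
    } else {
      dx <- numeric(prod(d))
      dx[l$argmax] <- as.vector(dy)
      dim(dx) <- d
      l$argmax <- NULL
    }
    dx
  }
  l
}

# Fully connected layer on (in, N) matrices.
layer_linear <- function(in_d, out_d, bias = TRUE) {
  l <- new_layer("linear")
  l$in_d <- in_d; l$out_d <- out_d
  l$par$W <- he_init(c(out_d, in_d), in_d)
  if (bias) l$par$b <- array(0, out_d)
  l$forward <- function(x, training = FALSE) {
    if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
    if (nrow(x) != l$in_d) stop("linear: expected ", l$in_d, " inputs")
    if (training) l$x <- x
    y <- l$par$W %*% x
    if (!is.null(l$par$b)) y <- y + as.vector(l$par$b)
    y
  }
  l$backward <- function(dy) {
    l$gr$W <- tcrossprod(dy, l$x)
    if (!is.null(l$par$b)) l$gr$b <- array(rowSums(dy), l$out_d)
    dx <- crossprod(l$par$W, dy)
    l$x <- NULL
    dx
  }
  l
}

# Sequential container.
layer_seq <- function(...) {
  l <- new_layer("seq")
  l$layers <- list(...)
  if (length(l$layers) == 1L && is.list(l$layers[[1]]) &&
      !is.environment(l$layers[[1]]))
    l$layers <- l$layers[[1]]
  l$forward <- function(x, training = FALSE) {
    for (sub in l$layers) x <- sub$forward(x, training)
    x
  }
  l$backward <- function(dy) {
    for (sub in rev(l$layers)) dy <- sub$backward(dy)
    dy
  }
  l
}

# Flatten all parameterized leaf layers (depth-first, stable order).
collect_layers <- function(l) {
  if (is.environment(l)) {
    subs <- list()
    if (!is.null(l$layers)) subs <- l$layers
    if (!is.null(l$children)) subs <- c(subs, l$children)
    if (length(subs) == 0) return(if (length(l$par)) list(l) else list())
    out <- list()
    if (length(l$par)) out <- list(l)
    for (s in subs) out <- c(out, collect_layers(s))
    return(out)
  }
  out <- list()
  for (s in l) out <- c(out, collect_layers(s))
  out
}

count_parameters <- function(model) {
  sum(vapply(collect_layers(model),
             function(l) sum(vapply(l$par, length, 0L)), 0))
}

get_state <- function(model) {
  lapply(collect_layers(model), function(l)
    list(kind = l$kind, par = l$par,
         running_mean = l$running_mean, running_var = l$running_var))
}

set_state <- function(model, state) {
  ls <- collect_layers(model)
  stopifnot(length(ls) == length(state))
  for (i in seq_along(ls)) {
    ls[[i]]$par <- state[[i]]$par
    if (!is.null(state[[i]]$running_mean)) {
      ls[[i]]$running_mean <- state[[i]]$running_mean
      ls[[i]]$running_var <- state[[i]]$running_var
    }
  }
  invisible(model)
}
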