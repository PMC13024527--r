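#' Convolutional branch of the dual-branch network
#'
#' Builds a ResNet50-topology feature extractor: a 7x7 stride-2 stem
#' convolution with batch normalization and ReLU, a 3x3 stride-2 max pool,
#' then four stages of bottleneck residual blocks (3, 4, 6 and 3 blocks with
#' internal down-sampling), for a total output stride of 32. With
#' `width_mult = 1` the final feature map has 2048 channels; a reduced-width
#' profile (e.g. `width_mult = 0.25`, 512 channels) keeps CPU training
#' tractable and records its own channel count in `$out_channels`.
#'
#' Weights are randomly initialized (He initialization) from the current RNG
#' state; there is no dependence on pretrained checkpoints.
#'
#' @param in_c number of input channels (3 for RGB frames).
#' @param width_mult channel width multiplier applied to every stage.
#' @param blocks number of bottleneck blocks per stage.
#' @return a backbone object with `$forward(x, training)`, `$out_channels`
#'   and `$stride` (always 32).
#' @export
resnet_backbone <- function(in_c = 3L, width_mult = 1, blocks = c(3L, 4L, 6L, 3L)) {
  ch <- function(n) max(8L, as.integer(round(n * width_mult)))
  stem_c <- ch(64)
  l <- new_layer("resnet_backbone")
  stem <- layer_seq(
    layer_conv2d(in_c, stem_c, k = 7L, stride = 2L, pad = 3L),
    layer_bn2d(stem_c),
    layer_relu(),
    layer_maxpool2d(k = 3L, stride = 2L, pad = 1L)
  )
  mids <- c(ch(64), ch(128), ch(256), ch(512))
  outs <- mids * 4L
  stages <- list()
  prev <- stem_c
  for (s in seq_along(blocks)) {
    stage <- list()
    for (b in seq_len(blocks[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      stage[[b]] <- bottleneck_block(prev, mids[s], outs[s], stride)
      prev <- outs[s]
    }
    stages[[s]] <- layer_seq(stage)
  }
  l$children <- c(list(stem), stages)
  l$out_channels <- outs[length(outs)]
  l$stride <- 32L
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (length(d) != 4L || d[1] != in_c)
      stop("backbone: expected ", in_c, "-channel input of dim (C,H,W,N)")
    if (d[2] < 32L || d[3] < 32L)
      stop("backbone: input must be at least 32x32 pixels")
    for (ch_ in l$children) x <- ch_$forward(x, training)
    x
  }
  l$backward <- function(dy) {
    for (ch_ in rev(l$children)) dy <- ch_$backward(dy)
    dy
  }
  l
}

# Bottleneck residual block: 1x1 reduce -> 3x3 -> 1x1 expand, with a
# projection shortcut when shape changes. Post-activation (v1) ordering.
bottleneck_block <- function(in_c, mid_c, out_c, stride = 1L) {
  l <- new_layer("bottleneck")
  main <- layer_seq(
    layer_conv2d(in_c, mid_c, k = 1L),
    layer_bn2d(mid_c),
    layer_relu(),
    layer_conv2d(mid_c, mid_c, k = 3L, stride = stride, pad = 1L),
    layer_bn2d(mid_c),
    layer_relu(),
    layer_conv2d(mid_c, out_c, k = 1L),
    layer_bn2d(out_c)
  )
  proj <- NULL
  if (stride != 1L || in_c != out_c) {
    proj <- layer_seq(
      layer_conv2d(in_c, out_c, k = 1L, stride = stride),
      layer_bn2d(out_c)
    )
  }
  relu_out <- layer_relu()
  l$children <- c(list(main), if (!is.null(proj)) list(proj), list(relu_out))
  l$forward <- function(x, training = FALSE) {
    y <- main$forward(x, training)
    s <- if (is.null(proj)) x else proj$forward(x, training)
    relu_out$forward(y + s, training)
  }
  l$backward <- function(dy) {
    dy <- relu_out$backward(dy)
    dx <- main$backward(dy)
    dx + if (is.null(proj)) dy else proj$backward(dy)
  }
  l
}

#' Extract the convolutional feature map
#'
#' Runs the convolutional branch in inference mode and returns the stage-4
#' activation grid, the common currency passed to the capsule branch and the
#' fusion gate.
#'
#' @param backbone a [resnet_backbone()] object.
#' @param batch image tensor of dim `(3, H, W, N)` with `H, W >= 32`.
#' @return feature map of dim `(C, H/32, W/32, N)` with attribute `stride`.
#' @export
extract_features <- function(backbone, batch) {
  fm <- backbone$forward(batch, training = FALSE)
  attr(fm, "stride") <- backbone$stride
  fm
}

#' Global average pooling of a feature map
#'
#' Per-channel spatial mean, producing one fixed-length descriptor per image.
#'
#' @param fm feature map of dim `(C, Hc, Wc, N)`.
#' @return a `C x N` matrix.
#' @export
global_pool <- function(fm) {
  d <- dim(fm)
  if (length(d) != 4L) stop("global_pool: expected a (C,Hc,Wc,N) array")
  if (d[2] * d[3] == 0L) stop("global_pool: empty spatial extent")
  layer_global_pool("avg")$forward(fm)
}
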