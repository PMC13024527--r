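# Output heads on the fused feature map: lesion classification via
# pool -> FC head -> softmax, and single-box localization via
# pool -> FC -> sigmoid yielding normalized (cx, cy, w, h).

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

#' Classification head constructor
#'
#' The full model uses a two-layer fully connected head (hidden width
#' `Cc / 4` with ReLU); the shallow ablation variant uses a single linear
#' layer. Either way the output is a softmax probability vector per image.
#'
#' @param cc fused-map channel count.
#' @param K number of classes (>= 2).
#' @param depth 1 (single linear layer) or 2 (bottleneck + ReLU + linear).
#' @param pool `"avg"` or `"max"` global pooling ahead of the head.
#' @return head layer with `$forward(fused, training)` returning logits
#'   (`K x N`) and `$backward(dlogits)`.
#' @export
classification_head <- function(cc, K, depth = 2L, pool = "avg") {
  if (K < 2L) stop("classification_head: need at least 2 classes")
  if (!depth %in% c(1L, 2L)) stop("classification_head: depth must be 1 or 2")
  l <- new_layer("cls_head")
  gp <- layer_global_pool(pool)
  if (depth == 2L) {
    hidden <- max(2L, cc %/% 4L)
    net <- layer_seq(layer_linear(cc, hidden), layer_relu(),
                     layer_linear(hidden, K))
  } else {
    net <- layer_seq(layer_linear(cc, K))
  }
  l$children <- list(net)
  l$gp <- gp
  l$forward <- function(fused, training = FALSE) {
    net$forward(gp$forward(fused, training), training)
  }
  l$backward <- function(dlogits) gp$backward(net$backward(dlogits))
  l
}

#' Bounding-box regression head constructor
#'
#' Pools the fused map and maps it through a linear layer and a sigmoid to a
#' normalized `(cx, cy, w, h)` box, each component in `[0, 1]` as a fraction
#' of image size.
#'
#' @inheritParams classification_head
#' @return head layer with `$forward(fused, training)` returning a `4 x N`
#'   matrix and `$backward(dbox_pre)` taking gradients w.r.t. the
#'   pre-sigmoid activations.
#' @export
bbox_head <- function(cc, pool = "avg") {
  l <- new_layer("bbox_head")
  gp <- layer_global_pool(pool)
  lin <- layer_linear(cc, 4L)
  l$children <- list(lin)
  l$gp <- gp
  l$forward <- function(fused, training = FALSE) {
    z <- lin$forward(gp$forward(fused, training), training)
    out <- 1 / (1 + exp(-z))
    if (training) l$sig <- out
    out
  }
  l$backward <- function(dbox) {
    dz <- dbox * l$sig * (1 - l$sig)
    l$sig <- NULL
    gp$backward(lin$backward(dz))
  }
  l
}

#' Classify a fused feature map
#'
#' Applies a classification head in inference mode and returns softmax
#' probabilities (columns sum to 1).
#'
#' @param head a [classification_head()].
#' @param fused fused map `(Cc, H, W, N)` (a single image `(Cc, H, W)` is
#'   promoted to a batch of one).
#' @return `K x N` probability matrix.
#' @export
classify <- function(head, fused) {
  if (length(dim(fused)) == 3L) dim(fused) <- c(dim(fused), 1L)
  softmax_cols(head$forward(fused, training = FALSE))
}

#' Regress a normalized bounding box
#'
#' Applies a box head in inference mode; all four components lie in `[0, 1]`
#' by the sigmoid output transform.
#'
#' @param head a [bbox_head()].
#' @param fused fused map, as in [classify()].
#' @return `4 x N` matrix with rows `(cx, cy, w, h)`.
#' @export
regress_bbox <- function(head, fused) {
  if (length(dim(fused)) == 3L) dim(fused) <- c(dim(fused), 1L)
  out <- head$forward(fused, training = FALSE)
  rownames(out) <- c("cx", "cy", "w", "h")
  out
}
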