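#' Default run configuration
#'
#' Two bundled profiles: `"full"` is the deployment-scale geometry
#' (224x224 input, full-width backbone, 2048-channel feature map, 256
#' primary-capsule channels); `"desk"` is a width-reduced geometry
#' (64x64 input, width multiplier 0.25, 512-channel feature map) sized so
#' training runs on a single CPU; `"micro"` shrinks further (48x48, fewer
#' capsules) for fast multi-seed trend checks. The reduced profiles document
#' their own channel counts - the 2048-channel contract applies to `"full"`
#' only.
#'
#' @param profile one of `"desk"`, `"full"`, `"micro"`.
#' @return nested configuration list.
#' @export
default_config <- function(profile = c("desk", "full", "micro")) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    K = 3L,
    class_names = c("normal", "erosion_like", "polyp_like"),
    image_size = 64L,
    width_mult = 0.25,
    capsule = list(n_caps = 8L, d = 8L, dprime = 16L, r = 3L,
                   respatialize = "broadcast"),
    fusion = list(mode = "attention", reduction = 16L, alpha = 0.5),
    head = list(depth = 2L, pool = "avg"),
    loss = list(lambda = 1, class_weights = "auto", eps = 1e-12),
    variant = "A0"
  )
  if (profile == "full") {
    base$image_size <- 224L
    base$width_mult <- 1
    base$capsule$n_caps <- 32L   # 32 x 8 = 256 primary-capsule channels
  } else if (profile == "micro") {
    base$image_size <- 48L
    base$width_mult <- 0.25
    base$capsule$n_caps <- 4L
    base$fusion$reduction <- 8L
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' Run configurations are nested lists (see [default_config()]); the YAML
#' form is the on-disk interface used by the command-line wrapper. Reading
#' merges the file over the named profile's defaults, so a file only needs
#' to state what it overrides.
#'
#' @param path YAML file path.
#' @param config configuration list to write.
#' @return `read_run_config` returns the merged configuration list.
#' @export
read_run_config <- function(path) {
  ov <- yaml::read_yaml(path)
  base <- default_config(ov$profile %||% "desk")
  merge_cfg <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_cfg(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge_cfg(base, ov)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Ablation variant catalogue
#'
#' The seven architectural variants of the ablation harness: A0 is the full
#' model; each other variant removes or replaces exactly one component.
#'
#' @return data frame with columns `id` and `description`.
#' @export
variant_specs <- function() {
  data.frame(
    id = paste0("A", 0:6),
    description = c(
      "Full dual-branch model (attention fusion, two-layer FC head)",
      "Remove capsule branch (heads on the convolutional map)",
      "Remove convolutional branch (capsule branch on a small image stem)",
      "Replace attention fusion with summation",
      "Replace attention fusion with concatenation",
      "Replace pre-head and gate pooling with global max pooling",
      "Replace two-layer FC head with a single linear layer"),
    stringsAsFactors = FALSE
  )
}

#' Build a model variant
#'
#' Materializes one of the seven ablation variants by patching the base
#' configuration: A0 applies no patch; A1 drops the capsule branch; A2 drops
#' the convolutional branch and feeds the capsule branch from a two-layer
#' stride-2 convolutional stem; A3/A4 swap the fusion mode; A5 switches all
#' head-facing and gate pooling to global max pooling (the backbone's
#' internal stem max pool is already max); A6 uses a single-layer
#' classification head.
#'
#' Weights are drawn from the current RNG state: call `set.seed()` first for
#' reproducible initialization.
#'
#' @param variant variant id, `"A0"` to `"A6"`.
#' @param config base configuration from [default_config()].
#' @return model object; see [model_forward()].
#' @export
build_variant <- function(variant = "A0", config = default_config()) {
  if (!variant %in% paste0("A", 0:6)) stop("unknown variant id: ", variant)
  cfg <- config
  cfg$variant <- variant
  if (variant == "A3") cfg$fusion$mode <- "sum"
  if (variant == "A4") cfg$fusion$mode <- "concat"
  if (variant == "A5") cfg$head$pool <- "max"
  if (variant == "A6") cfg$head$depth <- 1L

  m <- new_layer("duodet_model")
  m$config <- cfg
  K <- cfg$K
  cp <- cfg$capsule
  kids <- list()

  if (variant != "A2") {
    m$backbone <- resnet_backbone(3L, cfg$width_mult)
    cc <- m$backbone$out_channels
    kids <- c(kids, list(m$backbone))
  } else {
    # small image-fed stem: two 3x3 stride-2 convolutions
    stem_c <- max(8L, as.integer(round(64 * cfg$width_mult)))
    m$stem <- layer_seq(
      layer_conv2d(3L, stem_c, k = 3L, stride = 2L, pad = 1L),
      layer_bn2d(stem_c), layer_relu(),
      layer_conv2d(stem_c, stem_c, k = 3L, stride = 2L, pad = 1L),
      layer_bn2d(stem_c), layer_relu())
    cc <- stem_c
    kids <- c(kids, list(m$stem))
  }

  if (variant != "A1") {
    caps_in <- cc
    m$capsule <- capsule_branch(caps_in, n_caps = cp$n_caps, d = cp$d,
                                dprime = cp$dprime, K = K, r = cp$r)
    kids <- c(kids, list(m$capsule))
  }

  dual <- !variant %in% c("A1", "A2")
  if (dual) {
    m$fusion <- fusion_layer(cc, m$capsule$out_channels,
                             mode = cfg$fusion$mode,
                             reduction = cfg$fusion$reduction,
                             alpha = cfg$fusion$alpha,
                             pool = cfg$head$pool)
    kids <- c(kids, list(m$fusion))
    head_c <- cc
  } else if (variant == "A1") {
    head_c <- cc
  } else {
    head_c <- m$capsule$out_channels
  }

  m$cls_head <- classification_head(head_c, K, depth = cfg$head$depth,
                                    pool = cfg$head$pool)
  m$box_head <- bbox_head(head_c, pool = cfg$head$pool)
  kids <- c(kids, list(m$cls_head, m$box_head))
  m$children <- kids
  m$variant <- variant
  m$head_channels <- head_c

  m$forward <- function(x, training = FALSE) {
    v <- m$variant
    if (v == "A2") {
      fm <- m$stem$forward(x, training)
      feat <- m$capsule$forward(fm, training)
    } else {
      Fc <- m$backbone$forward(x, training)
      if (v == "A1") {
        feat <- Fc
      } else {
        Fv <- m$capsule$forward(Fc, training)
        feat <- m$fusion$forward_pair(Fc, Fv, training)
      }
    }
    logits <- m$cls_head$forward(feat, training)
    bbox <- m$box_head$forward(feat, training)
    list(logits = logits, probs = softmax_cols(logits), bbox = bbox)
  }

  m$backward <- function(dlogits, dbox) {
    dfeat <- m$cls_head$backward(dlogits) + m$box_head$backward(dbox)
    v <- m$variant
    if (v == "A2") {
      dmap <- m$capsule$backward(dfeat)
      m$stem$backward(dmap)
    } else if (v == "A1") {
      m$backbone$backward(dfeat)
    } else {
      fb <- m$fusion$backward(dfeat)
      dFc <- fb$dFc + m$capsule$backward(fb$dFv)
      m$backbone$backward(dFc)
    }
    invisible(NULL)
  }
  m
}

#' Forward pass of an assembled model
#'
#' Runs the network in inference mode on an image batch; deterministic given
#' fixed weights. Large batches are processed in chunks to bound memory.
#'
#' @param model object from [build_variant()].
#' @param x image tensor `(3, H, W, N)` (a single `(3, H, W)` image is
#'   promoted to a batch of one).
#' @param chunk maximum images per internal forward pass.
#' @return list with `probs` (`K x N`, columns summing to 1) and `bbox`
#'   (`4 x N` normalized boxes).
#' @export
model_forward <- function(model, x, chunk = 64L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  n <- d[4]
  probs <- matrix(0, model$config$K, n)
  bbox <- matrix(0, 4L, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out <- model$forward(x[, , , i:j, drop = FALSE], training = FALSE)
    probs[, i:j] <- out$probs
    bbox[, i:j] <- out$bbox
    i <- j + 1L
  }
  rownames(probs) <- model$config$class_names
  rownames(bbox) <- c("cx", "cy", "w", "h")
  list(probs = probs, bbox = bbox)
}

# One optimization step on a batch; returns the loss breakdown.
model_train_step <- function(model, x, labels, bbox_true, lesion_mask,
                             class_weights = NULL) {
  cfg <- model$config
  out <- model$forward(x, training = TRUE)
  probs <- out$probs
  n <- ncol(probs)
  K <- nrow(probs)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  cls <- cross_entropy_loss(labels, probs, class_weights, cfg$loss$eps)
  reg <- bbox_regression_loss(out$bbox, bbox_true, lesion_mask)
  lb <- total_loss(cls, reg, cfg$loss$lambda)

  onehot <- matrix(0, K, n)
  onehot[cbind(labels, seq_len(n))] <- 1
  w <- class_weights[labels]
  dlogits <- (probs - onehot) * rep(w, each = K) / n
  dbox <- matrix(0, 4L, n)
  if (any(lesion_mask)) {
    dmask <- out$bbox[, lesion_mask, drop = FALSE] -
      bbox_true[, lesion_mask, drop = FALSE]
    dbox[, lesion_mask] <- cfg$loss$lambda *
      smooth_l1_grad(dmask) / (4 * sum(lesion_mask))
  }
  model$backward(dlogits, dbox)
  lb
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding a format version, the
#' model configuration and all parameter arrays (including batch-norm
#' running statistics), sufficient to rebuild the network exactly.
#'
#' @param model model object.
#' @param path file path.
#' @return `load_checkpoint` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format_version = 1L, config = model$config,
               variant = model$variant, state = get_state(model)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version)) stop("not a recognized checkpoint file")
  model <- build_variant(ck$variant, ck$config)
  set_state(model, ck$state)
  model
}
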