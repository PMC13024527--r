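# Seeded generator of endoscopy-like frames with ground-truth classes and
# boxes. Frames are (3, H, W) arrays in [0, 1]: a smooth reddish mucosa
# texture (low-frequency noise + vignette) optionally carrying one lesion:
# an irregular darker erosion-like patch with a texture discontinuity, or a
# bright shaded polyp-like ellipse with a specular highlight.

#' Synthetic dataset specification
#'
#' Defaults mirror the class mix of the emulated screening dataset: 56%
#' normal frames, with lesion frames split 3:1 between erosion-like
#' (non-tumor) and polyp-like (polypoid) appearances.
#'
#' @param n_images number of frames to generate.
#' @param image_size side length in pixels.
#' @param class_probs probabilities over (normal, erosion_like, polyp_like);
#'   must sum to 1.
#' @param pose_jitter list with `rotation` (degrees), `translation`
#'   (fraction of image size) and `scale` (range) governing lesion pose
#'   variability.
#' @param brightness_jitter multiplicative per-frame illumination range.
#' @param seed RNG seed; generation is byte-identical given the same spec
#'   (Mersenne-Twister, pinned).
#' @return spec list.
#' @export
synth_spec <- function(n_images, image_size = 64L,
                       class_probs = c(normal = 0.56, erosion_like = 0.33,
                                       polyp_like = 0.11),
                       pose_jitter = list(rotation = 25, translation = 0.12,
                                          scale = c(0.8, 1.25)),
                       brightness_jitter = c(0.9, 1.1),
                       seed = 1L) {
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("synth_spec: class_probs must sum to 1")
  list(n_images = as.integer(n_images), image_size = as.integer(image_size),
       class_probs = class_probs, pose_jitter = pose_jitter,
       brightness_jitter = brightness_jitter, seed = as.integer(seed))
}

# bilinear upsampling of a coarse grid to size x size
upsample_grid <- function(g, size) {
  k <- nrow(g)
  u <- seq(1, k, length.out = size)
  i0 <- pmin(floor(u), k - 1L); f <- u - i0
  a <- g[i0, , drop = FALSE] * (1 - f) + g[i0 + 1L, , drop = FALSE] * f
  b <- t(a)[i0, , drop = FALSE] * (1 - f) + t(a)[i0 + 1L, , drop = FALSE] * f
  t(b)
}

#' Render one synthetic frame
#'
#' Draws texture detail from the current RNG state; identical RNG state,
#' class and pose yield identical pixels. The pose rotates the lesion center
#' about the image center, then translates and scales it; the bounding box
#' follows the same transform.
#'
#' @param class `"normal"`, `"erosion_like"` or `"polyp_like"`.
#' @param size image side in pixels.
#' @param pose list with `center` (pre-rotation, fractions), `rotation`
#'   (degrees), `translation` (fractions), `scale`; missing entries default
#'   to an unjittered pose.
#' @return labeled image: list with `pixels` `(3, size, size)`, `label`,
#'   `bbox` (normalized `(cx, cy, w, h)`, `NULL` for normal frames).
#' @export
render_image <- function(class = c("normal", "erosion_like", "polyp_like"),
                         size = 64L, pose = list()) {
  class <- match.arg(class)
  pose <- utils::modifyList(
    list(center = c(0.5, 0.5), rotation = 0, translation = c(0, 0),
         scale = 1, brightness = 1), pose)
  s <- size
  xs <- matrix(rep(seq_len(s), each = s), s, s)   # column (width) coord
  ys <- matrix(rep(seq_len(s), times = s), s, s)  # row (height) coord
  # mucosa base: reddish tint + low-frequency texture + vignette
  tint <- c(0.70, 0.42, 0.36) + stats::rnorm(3, 0, 0.03)
  lowf <- upsample_grid(matrix(stats::rnorm(49, 0, 1), 7, 7), s) * 0.06
  cx0 <- (s + 1) / 2
  r2 <- ((xs - cx0)^2 + (ys - cx0)^2) / (2 * cx0^2)
  vign <- 1 - 0.35 * r2
  fine <- matrix(stats::rnorm(s * s, 0, 0.015), s, s)
  base <- lowf + fine
  # all spatial fields below are (H, W) = (row, col) matrices, matching
  # px[ch, , ]
  px <- array(0, dim = c(3L, s, s))
  for (ch in 1:3) px[ch, , ] <- tint[ch] * vign + base * (1 + 0.2 * ch)

  bbox <- NULL
  if (class != "normal") {
    th <- pose$rotation * pi / 180
    ctr <- pose$center - 0.5
    ctr <- c(cos(th) * ctr[1] - sin(th) * ctr[2],
             sin(th) * ctr[1] + cos(th) * ctr[2]) + 0.5 + pose$translation
    ctr <- pmin(pmax(ctr, 0.2), 0.8)
    rx <- stats::runif(1, 0.10, 0.16) * pose$scale
    ry <- stats::runif(1, 0.08, 0.14) * pose$scale
    ang <- stats::runif(1, 0, pi)
    dx <- (xs / s - ctr[1]); dy <- (ys / s - ctr[2])
    u <- cos(ang) * dx + sin(ang) * dy
    v <- -sin(ang) * dx + cos(ang) * dy
    if (class == "polyp_like") {
      d2 <- (u / rx)^2 + (v / ry)^2
      mask <- pmax(1 - d2, 0)                    # smooth shading to the rim
      spot <- exp(-(((u + 0.35 * rx)^2 + (v + 0.35 * ry)^2) / (0.12 * rx * ry)))
      gain <- c(0.30, 0.22, 0.18)
      for (ch in 1:3)
        px[ch, , ] <- px[ch, , ] + gain[ch] * mask + 0.25 * spot * mask
      inside <- d2 <= 1
    } else {
      phi <- atan2(v, u)
      wob <- 1 + 0.25 * sin(3 * phi + stats::runif(1, 0, 2 * pi)) +
        0.15 * sin(5 * phi + stats::runif(1, 0, 2 * pi))
      d2 <- (u / rx)^2 + (v / ry)^2
      inside <- d2 <= wob
      rough <- matrix(stats::rnorm(s * s, 0, 0.05), s, s)
      drop <- c(0.28, 0.16, 0.14)
      for (ch in 1:3) {
        layer <- matrix(px[ch, , ], s, s)
        layer[inside] <- layer[inside] - drop[ch] + rough[inside]
        px[ch, , ] <- layer
      }
    }
    ii <- which(inside, arr.ind = TRUE)     # (row, col) in image space
    if (nrow(ii) == 0L) ii <- matrix(round(ctr[c(2, 1)] * s), 1L)
    x0 <- (min(ii[, 2]) - 1) / s; x1 <- max(ii[, 2]) / s
    y0 <- (min(ii[, 1]) - 1) / s; y1 <- max(ii[, 1]) / s
    bbox <- c(cx = (x0 + x1) / 2, cy = (y0 + y1) / 2, w = x1 - x0, h = y1 - y0)
  }
  px <- pmin(pmax(px * pose$brightness, 0), 1)
  list(pixels = px, label = class, bbox = bbox)
}

#' Generate a synthetic labeled dataset
#'
#' Draws per-frame classes from `class_probs`, renders each frame with a
#' jittered pose, and (optionally) writes PNG images plus CSV and JSON
#' manifests. Regeneration with the same spec is byte-identical.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory for PNGs and manifests.
#' @return list with `x` (`(3, size, size, n)` tensor), `labels` (integer,
#'   1 = normal), `bbox` (`4 x n`, zeros for normal frames), `mask` (logical
#'   lesion indicator), `manifest` (data frame: path, label, cx, cy, w, h,
#'   seed), `class_names`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  cls_names <- names(spec$class_probs)
  n <- spec$n_images
  s <- spec$image_size
  labels <- sample.int(length(cls_names), n, replace = TRUE,
                       prob = spec$class_probs)
  x <- array(0, dim = c(3L, s, s, n))
  bbox <- matrix(0, 4L, n)
  rows <- vector("list", n)
  pj <- spec$pose_jitter
  for (i in seq_len(n)) {
    pose <- list(
      center = c(stats::runif(1, 0.35, 0.65), stats::runif(1, 0.35, 0.65)),
      rotation = stats::runif(1, -pj$rotation, pj$rotation),
      translation = stats::runif(2, -pj$translation, pj$translation),
      scale = stats::runif(1, pj$scale[1], pj$scale[2]),
      brightness = stats::runif(1, spec$brightness_jitter[1],
                                spec$brightness_jitter[2]))
    im <- render_image(cls_names[labels[i]], s, pose)
    x[, , , i] <- im$pixels
    if (!is.null(im$bbox)) bbox[, i] <- im$bbox
    rows[[i]] <- data.frame(
      path = sprintf("img_%05d.png", i), label = im$label,
      cx = if (is.null(im$bbox)) NA_real_ else im$bbox[1],
      cy = if (is.null(im$bbox)) NA_real_ else im$bbox[2],
      w = if (is.null(im$bbox)) NA_real_ else im$bbox[3],
      h = if (is.null(im$bbox)) NA_real_ else im$bbox[4],
      seed = spec$seed)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      png::writePNG(aperm(x[, , , i], c(2L, 3L, 1L)),
                    file.path(dir, manifest$path[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", na = "null", digits = NA)
  }
  list(x = x, labels = labels, bbox = bbox,
       mask = labels != match("normal", cls_names),
       manifest = manifest, class_names = cls_names)
}

#' Perturb a labeled image
#'
#' The robustness-protocol operators: multiplicative brightness scaling,
#' contrast scaling about the per-image mean (both clipped to `[0, 1]`;
#' magnitude 1 is the identity), and random basic transformations
#' (horizontal/vertical flips and a small rotation) with the bounding box
#' updated coherently and kept inside the image.
#'
#' @param image labeled image from [render_image()] (list with `pixels`,
#'   `label`, `bbox`).
#' @param kind `"brightness"`, `"contrast"` or `"random_transform"`.
#' @param magnitude scale factor for brightness/contrast; maximum rotation
#'   in degrees for `"random_transform"`.
#' @param transform optional explicit list `(flip_h, flip_v, angle)` for
#'   `"random_transform"`; drawn from the RNG when omitted.
#' @return perturbed labeled image.
#' @export
perturb <- function(image, kind = c("brightness", "contrast",
                                    "random_transform"),
                    magnitude = 1, transform = NULL) {
  kind <- match.arg(kind)
  px <- image$pixels
  bbox <- image$bbox
  if (kind == "brightness") {
    if (magnitude != 1) px <- pmin(pmax(px * magnitude, 0), 1)
  } else if (kind == "contrast") {
    if (magnitude != 1) {
      m <- mean(px)
      px <- pmin(pmax(m + magnitude * (px - m), 0), 1)
    }
  } else {
    if (is.null(transform)) {
      transform <- list(flip_h = stats::runif(1) < 0.5,
                        flip_v = stats::runif(1) < 0.5,
                        angle = stats::runif(1, -magnitude, magnitude))
    }
    transform <- utils::modifyList(
      list(flip_h = FALSE, flip_v = FALSE, angle = 0), transform)
    s <- dim(px)[2]
    if (isTRUE(transform$flip_h)) {
      px <- px[, , s:1, drop = FALSE]
      if (!is.null(bbox)) bbox[1] <- 1 - bbox[1]
    }
    if (isTRUE(transform$flip_v)) {
      px <- px[, s:1, , drop = FALSE]
      if (!is.null(bbox)) bbox[2] <- 1 - bbox[2]
    }
    if (abs(transform$angle) > 1e-12) {
      th <- transform$angle * pi / 180
      ctr <- (s + 1) / 2
      rows <- matrix(rep(seq_len(s), times = s), s, s)
      cols <- matrix(rep(seq_len(s), each = s), s, s)
      # inverse map target -> source, nearest neighbor
      sc <- cos(th) * (cols - ctr) + sin(th) * (rows - ctr) + ctr
      sr <- -sin(th) * (cols - ctr) + cos(th) * (rows - ctr) + ctr
      sc <- round(pmin(pmax(sc, 1), s))
      sr <- round(pmin(pmax(sr, 1), s))
      for (ch in 1:3) {
        layer <- matrix(px[ch, , ], s, s)
        px[ch, , ] <- matrix(layer[cbind(as.vector(sr), as.vector(sc))], s, s)
      }
      if (!is.null(bbox)) {
        c0 <- bbox[1:2] - 0.5
        bbox[1:2] <- c(cos(th) * c0[1] - sin(th) * c0[2],
                       sin(th) * c0[1] + cos(th) * c0[2]) + 0.5
        wh <- c(bbox[3] * abs(cos(th)) + bbox[4] * abs(sin(th)),
                bbox[3] * abs(sin(th)) + bbox[4] * abs(cos(th)))
        bbox[3:4] <- wh
      }
    }
    if (!is.null(bbox)) {
      # clip the box into the image
      x0 <- max(bbox[1] - bbox[3] / 2, 0); x1 <- min(bbox[1] + bbox[3] / 2, 1)
      y0 <- max(bbox[2] - bbox[4] / 2, 0); y1 <- min(bbox[2] + bbox[4] / 2, 1)
      bbox <- c(cx = (x0 + x1) / 2, cy = (y0 + y1) / 2,
                w = max(x1 - x0, 0), h = max(y1 - y0, 0))
    }
  }
  list(pixels = px, label = image$label, bbox = bbox)
}

# Apply a perturbation to every frame of a dataset tensor (labels/boxes
# carried through).
perturb_dataset <- function(data, kind, magnitude = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- dim(data$x)[4]
  x <- data$x
  bbox <- data$bbox
  for (i in seq_len(n)) {
    im <- list(pixels = data$x[, , , i],
               label = data$class_names[data$labels[i]],
               bbox = if (data$mask[i]) data$bbox[, i] else NULL)
    out <- perturb(im, kind, magnitude)
    x[, , , i] <- out$pixels
    if (!is.null(out$bbox)) bbox[, i] <- out$bbox
  }
  res <- data
  res$x <- x
  res$bbox <- bbox
  res
}
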