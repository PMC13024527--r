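test_that("dataset generation is byte-identical given the same spec", {
  spec <- synth_spec(12, image_size = 32, seed = 7)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$manifest, d2$manifest)
  # written PNGs are byte-identical across regenerations
  dir1 <- tempfile(); dir2 <- tempfile()
  generate_dataset(spec, dir1)
  generate_dataset(spec, dir2)
  for (f in list.files(dir1, pattern = "png$")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("class frequencies follow the configured screening mix", {
  d <- generate_dataset(synth_spec(1000, image_size = 16, seed = 11))
  n_normal <- sum(d$labels == 1L)
  # binomial sigma = sqrt(1000 * .56 * .44) ~ 15.7; 3 sigma band around 560
  expect_lt(abs(n_normal - 560), 3 * sqrt(1000 * 0.56 * 0.44))
  # lesion split ~ 3:1 erosion-like : polyp-like
  expect_gt(sum(d$labels == 2L), sum(d$labels == 3L))
})

test_that("lesion frames carry boxes inside the image; normal frames do not", {
  d <- generate_dataset(synth_spec(200, image_size = 32, seed = 3))
  lesion <- d$labels != 1L
  expect_identical(unname(d$mask), unname(lesion))
  expect_true(all(is.na(d$manifest$cx[!lesion])))
  expect_true(all(!is.na(d$manifest$cx[lesion])))
  b <- d$bbox[, lesion, drop = FALSE]
  expect_true(all(b[1, ] - b[3, ] / 2 >= -1e-9))
  expect_true(all(b[1, ] + b[3, ] / 2 <= 1 + 1e-9))
  expect_true(all(b[2, ] - b[4, ] / 2 >= -1e-9))
  expect_true(all(b[2, ] + b[4, ] / 2 <= 1 + 1e-9))
  expect_true(all(b[3, ] > 0 & b[4, ] > 0))
})

test_that("rendering is deterministic and lesions brighten/darken their box", {
  set.seed(5)
  s1 <- .Random.seed
  im1 <- render_image("polyp_like", 32)
  .Random.seed <<- s1
  im2 <- render_image("polyp_like", 32)
  expect_identical(im1$pixels, im2$pixels)
  # polyp-like frames are brighter inside the box than outside (many seeds)
  brighter <- 0
  for (k in 1:100) {
    set.seed(k)
    im <- render_image("polyp_like", 32)
    b <- im$bbox
    cols <- pmax(1, round((b[1] - b[3] / 2) * 32)):pmin(32, ceiling((b[1] + b[3] / 2) * 32))
    rows <- pmax(1, round((b[2] - b[4] / 2) * 32)):pmin(32, ceiling((b[2] + b[4] / 2) * 32))
    inside <- mean(im$pixels[, rows, cols])
    tot <- mean(im$pixels)
    outside <- (tot * 32 * 32 - inside * length(rows) * length(cols)) /
      (32 * 32 - length(rows) * length(cols))
    if (inside > outside) brighter <- brighter + 1
  }
  expect_gt(brighter, 95)
})

test_that("rotating the pose rotates the lesion center coherently", {
  pose0 <- list(center = c(0.65, 0.5), rotation = 0, scale = 1)
  pose90 <- list(center = c(0.65, 0.5), rotation = 90, scale = 1)
  set.seed(9)
  im0 <- render_image("polyp_like", 64, pose0)
  set.seed(9)
  im90 <- render_image("polyp_like", 64, pose90)
  # center (0.65, 0.5) offset (0.15, 0) rotates to offset (0, 0.15)
  expect_equal(unname(im0$bbox[1:2]), c(0.65, 0.5), tolerance = 0.06)
  expect_equal(unname(im90$bbox[1:2]), c(0.5, 0.65), tolerance = 0.06)
})

test_that("brightness/contrast at magnitude 1 are identities; flips involute", {
  set.seed(6)
  im <- render_image("erosion_like", 32)
  expect_identical(perturb(im, "brightness", 1)$pixels, im$pixels)
  expect_identical(perturb(im, "contrast", 1)$pixels, im$pixels)
  tf <- list(flip_h = TRUE, flip_v = FALSE, angle = 0)
  once <- perturb(im, "random_transform", transform = tf)
  twice <- perturb(once, "random_transform", transform = tf)
  expect_identical(twice$pixels, im$pixels)
  expect_equal(unname(twice$bbox), unname(im$bbox), tolerance = 1e-12)
  # flipped box is mirrored
  expect_equal(unname(once$bbox[1]), 1 - unname(im$bbox[1]), tolerance = 1e-12)
})

test_that("boxes remain inside the image after every perturbation", {
  set.seed(7)
  for (k in 1:25) {
    im <- render_image(sample(c("erosion_like", "polyp_like"), 1), 32,
                       pose = list(center = runif(2, 0.3, 0.7),
                                   rotation = runif(1, -30, 30)))
    out <- perturb(im, "random_transform", magnitude = 20)
    b <- out$bbox
    expect_gte(b[1] - b[3] / 2, -1e-9)
    expect_lte(b[1] + b[3] / 2, 1 + 1e-9)
    expect_gte(b[2] - b[4] / 2, -1e-9)
    expect_lte(b[2] + b[4] / 2, 1 + 1e-9)
  }
})

test_that("classes are separable by a simple intensity threshold", {
  # guarantees training-smoke tests are meaningful: thresholding the
  # brightest 3x3 local mean relative to the per-frame median (which cancels
  # global illumination) must separate polyp-like from normal frames at
  # > 80% accuracy
  d <- generate_dataset(synth_spec(
    300, image_size = 32, seed = 13,
    class_probs = c(normal = 0.5, erosion_like = 0, polyp_like = 0.5)))
  sel <- d$labels %in% c(1L, 3L)
  local_peak <- function(a) {
    g <- (a[1, , ] + a[2, , ] + a[3, , ]) / 3
    s <- nrow(g)
    m <- -Inf
    for (i in 1:(s - 2)) for (j in 1:(s - 2))
      m <- max(m, mean(g[i:(i + 2), j:(j + 2)]))
    m - stats::median(g)
  }
  stat <- apply(d$x[, , , sel, drop = FALSE], 4, local_peak)
  is_polyp <- d$labels[sel] == 3L
  th <- youden_threshold(stat, is_polyp)
  acc <- mean((stat >= th$threshold) == is_polyp)
  expect_gt(acc, 0.8)
})
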