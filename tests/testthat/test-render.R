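test_that("fully transparent volumes render as pure background", {
  st <- image_stack(array(0, c(4, 4, 4, 4)))
  v <- view_spec(background = c(30, 60, 90), width = 5, height = 5,
                 pixel_pitch = 1)
  img <- render_stack(st, v)$image
  expect_true(all(img[, , 1] == 30))
  expect_true(all(img[, , 2] == 60))
  expect_true(all(img[, , 3] == 90))
})

test_that("an opaque voxel nearest the eye sets the pixel to its color", {
  d <- array(0, c(1, 1, 4, 2))
  d[1, 1, , 2] <- c(70, 140, 210, 255)  # nearest the eye for direction -z
  st <- image_stack(d)
  v <- view_spec(direction = c(0, 0, -1), up = c(0, -1, 0), sample_step = 1,
                 width = 1, height = 1, pixel_pitch = 1,
                 interpolation = "nearest")
  expect_equal(render_stack(st, v)$image[1, 1, ], c(70, 140, 210))
})

test_that("two-sample rays match the closed-form over-operator compositing", {
  set.seed(28)
  for (k in 1:5) {
    rgba1 <- sample(0:255, 4, replace = TRUE)
    rgba2 <- sample(0:255, 4, replace = TRUE)
    bg <- sample(0:255, 3, replace = TRUE)
    d <- array(0, c(1, 1, 4, 2))
    d[1, 1, , 1] <- rgba1   # far voxel (z = 0)
    d[1, 1, , 2] <- rgba2   # near voxel for direction -z
    st <- image_stack(d)
    v <- view_spec(direction = c(0, 0, -1), up = c(0, -1, 0),
                   sample_step = 1, width = 1, height = 1, pixel_pitch = 1,
                   background = bg, interpolation = "nearest")
    img <- render_stack(st, v)$image[1, 1, ]
    a1 <- rgba2[4] / 255; a2 <- rgba1[4] / 255
    c1 <- rgba2[1:3] / 255; c2 <- rgba1[1:3] / 255
    expected <- quantize8(255 * (a1 * c1 + (1 - a1) * a2 * c2 +
                                   (1 - a1) * (1 - a2) * bg / 255))
    expect_lte(max(abs(img - expected)), 1)
  }
})

test_that("compositing is order-correct: back-to-front reproduces front-to-back", {
  set.seed(29)
  n <- 6
  alphas <- runif(n)
  cols <- matrix(runif(3 * n), n, 3)
  bg <- runif(3)
  # front-to-back accumulation
  Cf <- c(0, 0, 0); Af <- 0
  for (i in 1:n) {
    Cf <- Cf + (1 - Af) * alphas[i] * cols[i, ]
    Af <- Af + (1 - Af) * alphas[i]
  }
  Cf <- Cf + (1 - Af) * bg
  # back-to-front over operator
  Cb <- bg
  for (i in n:1) Cb <- alphas[i] * cols[i, ] + (1 - alphas[i]) * Cb
  expect_equal(Cf, Cb, tolerance = 1e-12)
})

test_that("opacity step correction makes homogeneous renders step-invariant", {
  d <- array(120, c(6, 6, 4, 6))
  st <- image_stack(d, spacing = c(1, 1, 1))
  v1 <- view_spec(sample_step = 1, width = 4, height = 4, pixel_pitch = 1)
  v2 <- view_spec(sample_step = 0.5, width = 4, height = 4, pixel_pitch = 1)
  i1 <- render_stack(st, v1)$image
  i2 <- render_stack(st, v2)$image
  expect_lte(max(abs(i1 - i2)), 2)
})

test_that("raising voxel alphas never lowers accumulated pixel opacity", {
  set.seed(30)
  d <- array(sample(0:200, 5 * 5 * 4 * 5, replace = TRUE), c(5, 5, 4, 5))
  st_lo <- image_stack(d)
  d2 <- d
  d2[, , 4, ] <- pmin(255, d[, , 4, ] + 40)
  st_hi <- image_stack(d2)
  # black emission isolates opacity: brighter background shows through less
  d[, , 1:3, ] <- 0; d2[, , 1:3, ] <- 0
  v <- view_spec(background = c(255, 255, 255), width = 6, height = 6,
                 pixel_pitch = 1)
  lo <- render_stack(image_stack(d), v)$image
  hi <- render_stack(image_stack(d2), v)$image
  expect_true(all(hi <= lo))
})

test_that("region-of-interest cropping suppresses outside voxels", {
  d <- array(0, c(4, 4, 4, 4))
  d[, , 4, ] <- 255
  d[, , 1, ] <- 200  # opaque red volume
  st <- image_stack(d)
  v <- view_spec(direction = c(0, 0, -1), up = c(0, -1, 0), width = 4,
                 height = 4, pixel_pitch = 1, interpolation = "nearest",
                 background = c(0, 50, 0))
  full <- render_stack(st, v)$image
  expect_true(all(full[, , 1] == 200))
  crop <- render_stack(st, v, roi(0, 2, 0, 4, 0, 4))$image
  # pixels over the cropped-away half show pure background
  expect_true(any(crop[, , 2] == 50))
  expect_error(render_stack(st, v, roi(0, 5, 0, 4, 0, 4)), "extent")
  expect_error(roi(2, 2, 0, 4, 0, 4), "low < high")
})

test_that("snapshot re-inversion is an involution recovering stain colors", {
  img <- structure(list(image = array(sample(0:255, 48, replace = TRUE),
                                      c(4, 4, 3)),
                        view = view_spec()), class = "rendered_image")
  re <- reinvert_snapshot(img)
  expect_equal(re$image, 255 - img$image)
  expect_equal(reinvert_snapshot(re)$image, img$image)
  black <- structure(list(image = array(0, c(2, 2, 3)), view = view_spec()),
                     class = "rendered_image")
  expect_true(all(reinvert_snapshot(black)$image == 255))
})

test_that("opaque phantom renders re-invert to the original stain colors", {
  ext <- c(24, 24, 8)
  ph <- generate_phantom(test_phantom_spec(ext, seed = 33))
  inv <- invert_stack(ph$truth$clean)
  rgba <- apply_transfer(luminance_alpha(inv),
                         transfer_function("threshold", t = 10))
  v <- view_spec(direction = c(0, 0, -1), up = c(0, -1, 0), width = 24,
                 height = 24, pixel_pitch = 1, interpolation = "nearest")
  re <- reinvert_snapshot(render_stack(rgba, v))
  # the wall tube runs the full depth: its first-hit voxels are opaque and
  # the re-inverted pixel must show the wall stain
  wall <- c(70, 60, 160)
  mid_y <- 12
  hit <- which(ph$truth$clean$data[mid_y, , 1, ext[3]] == wall[1])[1]
  expect_false(is.na(hit))
  expect_lte(max(abs(re$image[mid_y, hit, ] - wall)), 2)
})

test_that("turntable frames equal pre-rotated single renders", {
  ext <- c(16, 16, 8)
  ph <- generate_phantom(test_phantom_spec(ext, seed = 34))
  rgba <- luminance_alpha(invert_stack(ph$truth$clean))
  base <- view_spec(direction = c(1, 0, 0), up = c(0, 0, 1), width = 10,
                    height = 10, pixel_pitch = 2)
  frames <- turntable(rgba, base, n_frames = 4, axis = c(0, 0, 1))
  expect_length(frames, 4)
  expect_identical(frames[[1]]$image, render_stack(rgba, base)$image)
  # frame k equals a render with the base view pre-rotated by k*90 deg
  ang <- pi / 2
  v2 <- base
  v2$direction <- sectionvr:::rotate_about(base$direction, c(0, 0, 1), ang)
  v2$up <- sectionvr:::rotate_about(base$up, c(0, 0, 1), ang)
  expect_identical(frames[[2]]$image, render_stack(rgba, v2)$image)
})

test_that("degenerate view parameters are rejected", {
  expect_error(view_spec(direction = c(0, 0, 0)), "non-zero")
  expect_error(view_spec(direction = c(0, 0, 1), up = c(0, 0, -2)),
               "parallel")
  expect_error(view_spec(sample_step = -1), "positive")
})
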