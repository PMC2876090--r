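test_that("transfer families reproduce their defining expressions", {
  # linear / gamma
  lin <- transfer_function("linear_gamma", gamma = 1)
  expect_equal(tf_eval(lin, 0:255), 0:255)
  g2 <- transfer_function("linear_gamma", gamma = 2)
  expect_equal(tf_eval(g2, 64), 16)           # 64^2/255 = 16.06
  expect_equal(tf_eval(g2, c(0, 255)), c(0, 255))
  # threshold 255*(A > t), strict
  th <- transfer_function("threshold", t = 10)
  expect_equal(tf_eval(th, 128), 255)
  expect_equal(tf_eval(th, 10), 0)
  expect_equal(tf_eval(th, 0), 0)
  # cubic increasing pow(A,3)/pow(255,2)
  pi3 <- transfer_function("power_increasing", x = 3)
  expect_equal(tf_eval(pi3, 255), 255)
  expect_equal(tf_eval(pi3, 0), 0)
  expect_equal(tf_eval(pi3, 128), 32)         # 128^3/255^2 = 32.25
  # cubic decreasing 255 - pow(255-A,3)/pow(255,2)
  pd3 <- transfer_function("power_decreasing", x = 3)
  expect_equal(tf_eval(pd3, c(0, 255)), c(0, 255))
  expect_equal(tf_eval(pd3, 128), 223)        # 255 - 127^3/255^2 = 223.499
})

test_that("all transfer kinds are monotone and fix the endpoints", {
  tfs <- list(
    transfer_function("linear_gamma", gamma = 0.4),
    transfer_function("linear_gamma", gamma = 2.5),
    transfer_function("threshold", t = 40),
    transfer_function("power_increasing", x = 2),
    transfer_function("power_decreasing", x = 4),
    transfer_function("piecewise",
                      points = rbind(c(0, 0), c(64, 10), c(200, 240),
                                     c(255, 255)))
  )
  for (tf in tfs) {
    v <- tf_eval(tf, 0:255)
    expect_true(all(diff(v) >= 0))
    expect_equal(v[1], 0)
    expect_equal(v[256], 255)
    expect_true(all(v >= 0 & v <= 255))
  }
})

test_that("power families are symmetric and reduce to identity at x = 1", {
  A <- 0:255
  x <- 3
  inc <- tf_eval(transfer_function("power_increasing", x = x), A)
  dec <- tf_eval(transfer_function("power_decreasing", x = x), A)
  expect_equal(dec, 255 - rev(inc))
  expect_equal(tf_eval(transfer_function("power_increasing", x = 1), A), A)
  expect_equal(tf_eval(transfer_function("power_decreasing", x = 1), A), A)
})

test_that("invalid transfer parameters are rejected", {
  expect_error(transfer_function("linear_gamma", gamma = 0), "gamma")
  expect_error(transfer_function("threshold", t = 255), "\\[0, 255\\)")
  expect_error(transfer_function("power_increasing", x = 0.5), ">= 1")
  expect_error(transfer_function("piecewise",
                                 points = rbind(c(0, 0), c(100, 90),
                                                c(120, 50), c(255, 255))),
               "monotone")
})

test_that("luminance alpha equals the grayscale conversion voxelwise", {
  st <- random_stack(5, 6, 3, 3, seed = 25, inverted = TRUE)
  la <- luminance_alpha(st)
  expect_equal(la$semantics, "RGBA")
  expect_equal(la$data[, , 1:3, ], st$data)
  expect_equal(la$data[, , 4, ], to_grayscale(st)$data[, , 1, ])
  # black background voxels become fully transparent
  d <- array(0, c(1, 2, 3, 1))
  d[1, 2, , 1] <- c(0, 255, 0)
  la2 <- luminance_alpha(image_stack(d, inverted = TRUE))
  expect_equal(la2$data[1, 1, 4, 1], 0)
  expect_equal(la2$data[1, 2, 4, 1], 150)
  expect_error(luminance_alpha(la), "RGB")
})

test_that("transfer application touches only the alpha channel", {
  st <- luminance_alpha(random_stack(6, 6, 3, 4, seed = 26))
  th <- transfer_function("threshold", t = 10)
  out <- apply_transfer(st, th)
  expect_identical(out$data[, , 1:3, ], st$data[, , 1:3, ])
  expect_true(all(out$data[, , 4, ] %in% c(0, 255)))
  # identity transfer leaves the stack unchanged
  id <- apply_transfer(st, transfer_function("linear_gamma", gamma = 1))
  expect_identical(id$data, st$data)
})

test_that("the glow colormap is a monotone-luminance clipped ramp", {
  map <- colormap("glow", clip_top = 16)
  expect_equal(dim(map$rgb), c(256, 3))
  lum <- ntsc_luminance(map$rgb[, 1], map$rgb[, 2], map$rgb[, 3])
  expect_true(all(diff(lum) >= 0))
  expect_equal(unname(map$rgb[1, ]), c(0, 0, 0))
  # clipped top: the last 16 entries are all the 240th entry's color
  for (i in 241:256) expect_equal(map$rgb[i, ], map$rgb[240, ])
})

test_that("colormap application pairs map colors with transfer alphas", {
  vol <- array(c(0, 128, 255), c(1, 3, 1, 1))
  st <- image_stack(vol)
  map <- colormap("glow")
  lin <- transfer_function("linear_gamma", gamma = 1)
  out <- apply_colormap(st, map, lin)
  expect_equal(out$semantics, "RGBA")
  expect_equal(out$data[1, 1, , 1], c(map$rgb[1, ], 0))
  expect_equal(out$data[1, 2, , 1], c(map$rgb[129, ], 128))
  expect_equal(out$data[1, 3, , 1], c(map$rgb[256, ], 255))
  expect_error(apply_colormap(out, map, lin), "GRAY")
})

test_that("colormap and transfer inversion are involutions", {
  map <- colormap("glow")
  expect_equal(invert_colormap(invert_colormap(map))$rgb, map$rgb)
  tf <- transfer_function("linear_gamma", gamma = 1)
  itf <- invert_transfer(tf)
  expect_equal(tf_eval(itf, 255), 0)
  expect_equal(tf_eval(itf, 0), 255)
  back <- invert_transfer(itf)
  expect_equal(tf_eval(back, 0:255), tf_eval(tf, 0:255))
})

test_that("rendering inverted data with (map, tf) equals rendering the
           original with the inverted pair", {
  set.seed(27)
  vol <- array(sample(0:255, 4^3, replace = TRUE), c(4, 4, 1, 4))
  gray <- image_stack(vol)
  gray_inv <- invert_stack(gray)
  map <- colormap("glow")
  tf <- transfer_function("linear_gamma", gamma = 1)
  a <- apply_colormap(gray_inv, map, tf)
  b <- apply_colormap(gray, invert_colormap(map), invert_transfer(tf))
  expect_identical(a$data, b$data)
  v <- view_spec(width = 8, height = 8, pixel_pitch = 1)
  ia <- render_stack(a, v)
  ib <- render_stack(b, v)
  expect_identical(ia$image, ib$image)
})

test_that("colormaps round-trip through the plain-text table format", {
  map <- colormap("glow")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_colormap(map, path)
  back <- read_colormap(path)
  expect_equal(unname(back$rgb), unname(map$rgb))
})
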