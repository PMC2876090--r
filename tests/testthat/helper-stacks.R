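# Fixture builders shared across the test files. Everything is generated in
# code under fixed seeds; no binary fixtures are stored.

# Random 8-bit stack of the given shape.
random_stack <- function(h = 4, w = 4, c = 3, z = 3, spacing = c(1, 1, 1),
                         seed = 1, inverted = FALSE) {
  set.seed(seed)
  image_stack(array(sample(0:255, h * w * c * z, replace = TRUE),
                    c(h, w, c, z)),
              spacing = spacing, inverted = inverted)
}

# Smooth synthetic slice: a sum of Gaussian blobs, good content for
# registration (smooth, asymmetric, non-periodic).
blob_slice <- function(h = 64, w = 64, seed = 1, n_blobs = 6) {
  set.seed(seed)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  m <- matrix(0, h, w)
  for (k in seq_len(n_blobs)) {
    cx <- runif(1, w * 0.25, w * 0.75)
    cy <- runif(1, h * 0.25, h * 0.75)
    sg <- runif(1, 3, 8)
    amp <- runif(1, 80, 255)
    m <- m + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2))
  }
  quantize8(255 * m / max(m))
}

# Two-phase axial step volume (low | high along x), for edge-retention and
# diffusion checks.
step_volume <- function(n = 8, lo = 40, hi = 200) {
  v <- array(lo, c(n, n, n))
  v[, (n %/% 2 + 1):n, ] <- hi
  v
}

as_gray_stack <- function(vol, spacing = c(1, 1, 1)) {
  d <- dim(vol)
  image_stack(array(vol, c(d[1], d[2], 1, d[3])), spacing = spacing)
}

# z-uniform phantom geometry (full-depth tubes only): adjacent clean slices
# are identical, so ground-truth rigid transforms are the unique optimum of
# the registration objective.
z_uniform_geometry <- function(extent) {
  Filter(function(p) p$type == "tube", sectionvr:::default_geometry(extent))
}

# Standard test phantom spec with selected artifact classes enabled.
test_phantom_spec <- function(extent = c(64, 64, 40), seed = 11,
                              jitter = c(0, 0), elastic = c(0, 8),
                              stain_gain = 0, bleach_rate = 0, speckle = 0,
                              geometry = NULL) {
  if (is.null(geometry)) {
    phantom_spec(extent = extent, jitter = jitter, elastic = elastic,
                 stain_gain = stain_gain, bleach_rate = bleach_rate,
                 speckle = speckle, seed = seed)
  } else {
    phantom_spec(extent = extent, geometry = geometry, jitter = jitter,
                 elastic = elastic, stain_gain = stain_gain,
                 bleach_rate = bleach_rate, speckle = speckle, seed = seed)
  }
}

# Brute-force (non-separable) 3D Gaussian convolution with symmetric
# boundaries: the independent oracle for gaussian_smooth.
brute_gauss3d <- function(vol, k, sigma) {
  w1 <- sectionvr:::gauss_kernel1d(k, sigma)
  h <- (k - 1) / 2
  n <- dim(vol)
  refl <- function(i, nn) ifelse(i < 1, 1 - i, ifelse(i > nn, 2 * nn + 1 - i, i))
  out <- array(0, n)
  for (y in seq_len(n[1])) for (x in seq_len(n[2])) for (z in seq_len(n[3])) {
    acc <- 0
    for (a in -h:h) for (b in -h:h) for (cc in -h:h) {
      acc <- acc + w1[a + h + 1] * w1[b + h + 1] * w1[cc + h + 1] *
        vol[refl(y + a, n[1]), refl(x + b, n[2]), refl(z + cc, n[3])]
    }
    out[y, x, z] <- acc
  }
  out
}

# Independent explicit-scheme nonlinear diffusion oracle: plain loops, same
# mathematical definition as the implementation but coded from the update
# equations directly (per-voxel neighbour sums, no vectorized shifts).
oracle_diffusion <- function(vol, contrast, sigma, step, stop) {
  n_outer <- floor(stop / step)
  if (n_outer < 1) return(vol)
  n <- dim(vol)
  r_pre <- min(ceiling(2 * sigma), floor((min(n) - 1) / 2))
  clampi <- function(i, nn) min(max(i, 1), nn)
  for (it in seq_len(n_outer)) {
    us <- brute_gauss3d(vol, 2 * r_pre + 1, sigma)
    g <- array(0, n)
    for (y in seq_len(n[1])) for (x in seq_len(n[2])) for (z in seq_len(n[3])) {
      gx <- (us[y, clampi(x + 1, n[2]), z] - us[y, clampi(x - 1, n[2]), z]) / 2
      gy <- (us[clampi(y + 1, n[1]), x, z] - us[clampi(y - 1, n[1]), x, z]) / 2
      gz <- (us[y, x, clampi(z + 1, n[3])] - us[y, x, clampi(z - 1, n[3])]) / 2
      g[y, x, z] <- exp(-((sqrt(gx^2 + gy^2 + gz^2)) / contrast)^2)
    }
    t_done <- 0
    while (t_done < step - 1e-12) {
      dt <- min(1 / 6, step - t_done)
      nv <- vol
      for (y in seq_len(n[1])) for (x in seq_len(n[2])) for (z in seq_len(n[3])) {
        acc <- 0
        nb <- list(c(y + 1, x, z), c(y - 1, x, z), c(y, x + 1, z),
                   c(y, x - 1, z), c(y, x, z + 1), c(y, x, z - 1))
        for (q in nb) {
          yy <- clampi(q[1], n[1]); xx <- clampi(q[2], n[2])
          zz <- clampi(q[3], n[3])
          gh <- (g[yy, xx, zz] + g[y, x, z]) / 2
          acc <- acc + gh * (vol[yy, xx, zz] - vol[y, x, z])
        }
        nv[y, x, z] <- vol[y, x, z] + dt * acc
      }
      vol <- nv
      t_done <- t_done + dt
    }
  }
  vol
}
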