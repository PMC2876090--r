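# Seeded synthetic serial-section stacks with ground truth.
#
# The generator rasterizes simple stained "tissue" geometry onto a white
# background (micrograph convention) and then degrades each slice with the
# three artifact classes that plague real section series: rigid
# misalignment (translation + rotation jitter), smooth geometric distortion
# (band-limited elastic displacement), and staining variation (per-slice
# multiplicative gain, cumulative bleaching, salt-and-pepper speckles).
# Every random draw comes from per-artifact seeded streams derived from one
# root seed, so disabling one artifact class leaves the draws of the others
# unchanged and the recorded ground truth is exact.

#' Phantom specification
#'
#' @param extent `(width, height, n_slices)` in voxels.
#' @param spacing `(sx, sy, sz)` in micrometers.
#' @param geometry List of primitives from [phantom_ellipsoid()],
#'   [phantom_tube()], [phantom_shell()], [phantom_box()]; drawn in order,
#'   later primitives over earlier ones (nesting).
#' @param jitter `(sigma_t px, sigma_theta deg)` rigid misalignment scale.
#' @param elastic `(amplitude px, smoothness px)` of the per-slice smooth
#'   displacement field.
#' @param stain_gain Standard deviation of the per-slice multiplicative
#'   intensity gain (gains ~ Normal(1, sigma), truncated positive).
#' @param bleach_rate Per-slice multiplicative decay of stain saturation
#'   toward white (slice i is faded by factor `(1 - bleach_rate)^i`).
#' @param speckle Expected fraction of pixels per slice hit by dark
#'   speckles (dust/precipitate emulation).
#' @param seed Integer root seed; identical specs give identical stacks.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(extent = c(64, 64, 40), spacing = c(1, 1, 2),
                         geometry = default_geometry(extent),
                         jitter = c(2, 1), elastic = c(1.5, 8),
                         stain_gain = 0.05, bleach_rate = 0.003,
                         speckle = 0, seed = 1L) {
  extent <- as.integer(extent)
  if (any(extent <= 0)) stop("extent must be positive")
  if (any(c(jitter, elastic, stain_gain, bleach_rate, speckle) < 0)) {
    stop("artifact magnitudes must be >= 0")
  }
  structure(
    list(extent = extent, spacing = as.numeric(spacing), geometry = geometry,
         jitter = jitter, elastic = elastic, stain_gain = stain_gain,
         bleach_rate = bleach_rate, speckle = speckle,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Phantom geometry primitives
#'
#' Primitives are defined in 0-based voxel coordinates (x = column,
#' y = row, z = slice) with an RGB stain color emulating a histological
#' stain. `phantom_ellipsoid()` fills an axis-aligned ellipsoid;
#' `phantom_tube()` an elliptical cylinder along z; `phantom_shell()` an
#' ellipsoidal shell of given relative thickness; `phantom_box()` an
#' axis-aligned box (a constant-thickness slab is the cleanest object for
#' path-length-independent renderings).
#'
#' @param center Length-3 center (voxels).
#' @param radii Length-3 semi-axes (voxels); for tubes only x and y apply.
#' @param color RGB stain color, values 0-255.
#' @param zrange For tubes: inclusive `(z0, z1)` slice range.
#' @param thickness For shells: relative shell thickness in (0, 1).
#' @param half Length-3 box half-widths (voxels).
#' @return A `phantom_primitive` list.
#' @name phantom_primitives
NULL

#' @rdname phantom_primitives
#' @export
phantom_ellipsoid <- function(center, radii, color) {
  structure(list(type = "ellipsoid", center = center, radii = radii,
                 color = color), class = "phantom_primitive")
}

#' @rdname phantom_primitives
#' @export
phantom_tube <- function(center, radii, zrange, color) {
  structure(list(type = "tube", center = center, radii = radii,
                 zrange = zrange, color = color),
            class = "phantom_primitive")
}

#' @rdname phantom_primitives
#' @export
phantom_shell <- function(center, radii, thickness, color) {
  structure(list(type = "shell", center = center, radii = radii,
                 thickness = thickness, color = color),
            class = "phantom_primitive")
}

#' @rdname phantom_primitives
#' @export
phantom_box <- function(center, half, color) {
  structure(list(type = "box", center = center, half = half, color = color),
            class = "phantom_primitive")
}

# Two-tone "stained specimen": a full-depth elliptical body wall (ring),
# pale interior tissue, an inner organ, and two off-center full-depth
# ducts. Mostly z-uniform — adjacent sections of real tissue at a few
# micrometers spacing are nearly identical — and deliberately
# non-rotation-symmetric so slice rotation is identifiable from content.
default_geometry <- function(extent) {
  w <- extent[1]; h <- extent[2]; nz <- extent[3]
  c0 <- c((w - 1) / 2, (h - 1) / 2, (nz - 1) / 2)
  zfull <- c(0, nz - 1)
  list(
    phantom_tube(c0, c(w * 0.42, h * 0.32), zfull,
                 color = c(70, 60, 160)),   # toluidine-blue-like wall
    phantom_tube(c0, c(w * 0.35, h * 0.26), zfull,
                 color = c(215, 185, 195)), # pale interior tissue
    phantom_ellipsoid(c0, c(w * 0.26, h * 0.18, nz * 0.42),
                      color = c(190, 120, 140)), # eosin-like organ
    phantom_tube(c0 + c(w * 0.14, -h * 0.05, 0), c(w * 0.07, h * 0.05),
                 zfull, color = c(170, 60, 80)),  # strongly stained duct
    phantom_tube(c0 + c(-w * 0.12, h * 0.08, 0), c(w * 0.05, h * 0.07),
                 zfull, color = c(90, 110, 60)),  # second duct
    # scattered darkly stained "nuclei" columns: the fine texture of real
    # tissue, and what pins down slice rotation during registration
    nuclei_columns(c0, w, h, zfull)
  ) |> flatten_geometry()
}

nuclei_columns <- function(c0, w, h, zfull) {
  ang <- (seq_len(14) - 1) * 2.399963  # golden-angle spiral, fixed layout
  rad <- sqrt(seq_len(14) / 14)
  lapply(seq_len(14), function(k) {
    phantom_tube(
      c(c0[1] + 0.30 * w * rad[k] * cos(ang[k]),
        c0[2] + 0.22 * h * rad[k] * sin(ang[k]), 0),
      c(max(1, w * 0.02), max(1, h * 0.02)), zfull,
      color = c(60, 40, 120)
    )
  })
}

flatten_geometry <- function(g) {
  out <- list()
  for (el in g) {
    if (inherits(el, "phantom_primitive")) out[[length(out) + 1]] <- el
    else out <- c(out, el)
  }
  out
}

# Rasterize one z-slice of the clean volume: white background, primitives
# in order. Returns H x W x 3.
rasterize_slice <- function(spec, z) {
  w <- spec$extent[1]; h <- spec$extent[2]
  xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1, w), h, w)
  slice <- array(255, c(h, w, 3))
  for (p in spec$geometry) {
    inside <- switch(
      p$type,
      ellipsoid = ((xs - p$center[1]) / p$radii[1])^2 +
        ((ys - p$center[2]) / p$radii[2])^2 +
        ((z - p$center[3]) / p$radii[3])^2 <= 1,
      tube = if (z >= p$zrange[1] && z <= p$zrange[2]) {
        ((xs - p$center[1]) / p$radii[1])^2 +
          ((ys - p$center[2]) / p$radii[2])^2 <= 1
      } else matrix(FALSE, h, w),
      shell = {
        q <- ((xs - p$center[1]) / p$radii[1])^2 +
          ((ys - p$center[2]) / p$radii[2])^2 +
          ((z - p$center[3]) / p$radii[3])^2
        q <= 1 & q >= (1 - p$thickness)^2
      },
      box = abs(xs - p$center[1]) <= p$half[1] &
        abs(ys - p$center[2]) <= p$half[2] &
        abs(z - p$center[3]) <= p$half[3]
    )
    if (!any(inside)) next
    for (ch in 1:3) {
      v <- slice[, , ch]
      v[inside] <- p$color[ch]
      slice[, , ch] <- v
    }
  }
  slice
}

# Independent seeded streams per artifact class (offsets keep every derived
# seed well below 2^31).
artifact_seed <- function(root, k) (root %% 100000L) * 7919L + k

#' Generate a synthetic serial-section stack with ground truth
#'
#' Builds the clean volume from the spec geometry and degrades it slice by
#' slice with the spec's artifact cascade; all random draws are recorded in
#' the returned truth object.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `stack` (degraded RGB `image_stack`), `truth`
#'   (`phantom_truth` with `clean` stack, per-slice `transforms`, `gains`,
#'   `bleach`, `elastic_fields` and `speckles`), both deterministic in the
#'   seed.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_geometry(spec)
  nz <- spec$extent[3]
  arr <- array(0, c(spec$extent[2], spec$extent[1], 3L, nz))
  for (i in seq_len(nz)) arr[, , , i] <- rasterize_slice(spec, i - 1)
  clean <- image_stack(arr, spacing = spec$spacing, inverted = FALSE)
  deg <- degrade_only(clean, spec)
  deg$truth$clean <- clean
  deg
}

check_geometry <- function(spec) {
  w <- spec$extent[1]; h <- spec$extent[2]; nz <- spec$extent[3]
  for (p in spec$geometry) {
    ext <- switch(p$type,
                  ellipsoid = , shell = p$radii,
                  tube = c(p$radii[1:2], 0),
                  box = p$half)
    lo <- p$center - ext
    hi <- p$center + ext
    if (any(lo < -0.5) || hi[1] > w - 0.5 || hi[2] > h - 0.5 ||
        (p$type %in% c("ellipsoid", "shell", "box") && hi[3] > nz - 0.5)) {
      stop("phantom primitive '", p$type, "' extends outside the extent")
    }
  }
  invisible(TRUE)
}

#' Degrade an existing stack with the phantom artifact cascade
#'
#' Applies, per slice `i` (0-based): the elastic displacement field, the
#' rigid jitter transform, the stain gain, the cumulative bleach factor
#' `(1 - bleach_rate)^i`, and dark speckles. Lets tests corrupt a
#' known-aligned input and check recovery.
#'
#' @param stack An RGB `image_stack` (non-inverted, white background).
#' @param spec A [phantom_spec()] whose extent matches the stack.
#' @return A list with `stack` (degraded) and `truth` (a `phantom_truth`).
#' @export
degrade_only <- function(stack, spec) {
  stopifnot(inherits(stack, "image_stack"), inherits(spec, "phantom_spec"))
  nz <- n_slices(stack)
  h <- dim(stack$data)[1]; w <- dim(stack$data)[2]

  # --- draws, one seeded stream per artifact class ---
  withr_seed <- function(k, expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(artifact_seed(spec$seed, k))
    expr
  }
  jit <- withr_seed(1L, list(
    tx = stats::rnorm(nz), ty = stats::rnorm(nz), th = stats::rnorm(nz)
  ))
  ncx <- max(2L, ceiling(w / max(spec$elastic[2], 1)) + 1L)
  ncy <- max(2L, ceiling(h / max(spec$elastic[2], 1)) + 1L)
  ela <- withr_seed(2L, lapply(seq_len(nz), function(i) {
    list(dx = matrix(stats::rnorm(ncy * ncx), ncy, ncx),
         dy = matrix(stats::rnorm(ncy * ncx), ncy, ncx))
  }))
  gains <- withr_seed(3L, pmax(0.05, 1 + spec$stain_gain * stats::rnorm(nz)))
  if (spec$stain_gain == 0) gains <- rep(1, nz)
  spk <- withr_seed(4L, lapply(seq_len(nz), function(i) {
    n_spk <- stats::rpois(1, spec$speckle * h * w)
    if (n_spk == 0) return(cbind(x = integer(0), y = integer(0)))
    cbind(x = sample.int(w, n_spk, replace = TRUE) - 1L,
          y = sample.int(h, n_spk, replace = TRUE) - 1L)
  }))

  transforms <- vector("list", nz)
  bleach <- (1 - spec$bleach_rate)^(seq_len(nz) - 1)
  fields <- vector("list", nz)
  out <- stack
  for (i in seq_len(nz)) {
    s <- get_slice(stack, i)
    # elastic distortion (smooth displacement, white fill)
    if (spec$elastic[1] > 0) {
      f <- upsample_field(ela[[i]], h, w, spec$elastic[1])
      fields[[i]] <- f
      s <- warp_slice(s, f$dx, f$dy, fill = 255)
    } else {
      fields[[i]] <- NULL
    }
    # rigid jitter
    tf <- rigid_transform(spec$jitter[2] * jit$th[i],
                          spec$jitter[1] * jit$tx[i],
                          spec$jitter[1] * jit$ty[i])
    transforms[[i]] <- tf
    if (spec$jitter[1] > 0 || spec$jitter[2] > 0) {
      s <- resample_slice(s, tf, fill_value = 255)
    }
    # staining variation: multiplicative gain on values, bleach toward white
    s <- quantize8(s * gains[i])
    if (spec$bleach_rate > 0) {
      s <- quantize8(255 - bleach[i] * (255 - s))
    }
    if (nrow(spk[[i]]) > 0) {
      for (ch in 1:3) {
        v <- s[, , ch]
        v[cbind(spk[[i]][, "y"] + 1, spk[[i]][, "x"] + 1)] <- 40
        s[, , ch] <- v
      }
    }
    out <- set_slice(out, i, s)
  }
  truth <- structure(
    list(transforms = transforms, gains = gains, bleach = bleach,
         elastic_fields = fields, speckles = spk, spec = spec),
    class = "phantom_truth"
  )
  list(stack = out, truth = truth)
}

# Bilinear upsampling of a coarse displacement grid to h x w, scaled to the
# requested RMS amplitude.
upsample_field <- function(grid, h, w, amplitude) {
  up <- function(m) {
    ny <- nrow(m); nx <- ncol(m)
    ys <- seq(1, ny, length.out = h)
    xs <- seq(1, nx, length.out = w)
    y0 <- pmin(floor(ys), ny - 1); x0 <- pmin(floor(xs), nx - 1)
    fy <- ys - y0; fx <- xs - x0
    m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y0 + 1, x0, drop = FALSE]
    m01 <- m[y0, x0 + 1, drop = FALSE]; m11 <- m[y0 + 1, x0 + 1, drop = FALSE]
    wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
    (1 - wy) * (1 - wx) * m00 + wy * (1 - wx) * m10 +
      (1 - wy) * wx * m01 + wy * wx * m11
  }
  dx <- up(grid$dx); dy <- up(grid$dy)
  sc <- amplitude / max(sqrt(mean(dx^2 + dy^2) / 2), 1e-12)
  list(dx = dx * sc, dy = dy * sc)
}

# Backward warp of an H x W x C slice by a displacement field (bilinear).
warp_slice <- function(s, dx, dy, fill = 255) {
  h <- dim(s)[1]; w <- dim(s)[2]
  qx <- matrix(rep(seq_len(w) - 1, each = h), h, w) + dx
  qy <- matrix(rep(seq_len(h) - 1, w), h, w) + dy
  out <- s
  for (ch in seq_len(dim(s)[3])) {
    out[, , ch] <- bilinear_gather(s[, , ch], qx, qy, fill)
  }
  quantize8(out)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:", length(x$transforms), "slices;",
      "mean |t| =", round(mean(abs(vapply(x$transforms, function(t) {
        sqrt(t$tx^2 + t$ty^2)
      }, numeric(1)))), 3), "px\n")
  invisible(x)
}
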