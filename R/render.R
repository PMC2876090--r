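# Orthographic emission-absorption ray casting.
#
# Each image pixel casts a ray through the volume in physical (micrometer)
# space. RGBA samples are taken at `sample_step` intervals by trilinear (or
# nearest-neighbour) interpolation, stored alpha is converted to per-sample
# opacity with the step-size correction a' = 1 - (1 - A/255)^(step/ref),
# and samples are composited front-to-back with the over operator. The
# background color is blended only after ray exit, so region-of-interest
# cropping exposes interior structure.

#' Viewing specification for the ray caster
#'
#' @param direction Length-3 vector: ray direction (from the eye into the
#'   volume) in physical space; normalized internally, must be non-zero.
#' @param up Length-3 vector not parallel to `direction`; fixes the image
#'   orientation.
#' @param sample_step Ray sampling interval in micrometers (> 0). Default:
#'   the smallest voxel edge of the rendered stack.
#' @param width,height Output image size in pixels; default chosen to cover
#'   the volume at `pixel_pitch`.
#' @param pixel_pitch Physical size of an output pixel in micrometers.
#' @param background RGB background color (0-255), blended after ray exit.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A `view_spec` object.
#' @export
view_spec <- function(direction = c(0, 0, -1), up = c(0, -1, 0),
                      sample_step = NULL, width = NULL, height = NULL,
                      pixel_pitch = NULL, background = c(0, 0, 0),
                      interpolation = c("trilinear", "nearest")) {
  direction <- as.numeric(direction)
  up <- as.numeric(up)
  nd <- sqrt(sum(direction^2))
  if (length(direction) != 3 || nd < 1e-12) {
    stop("`direction` must be a non-zero length-3 vector")
  }
  direction <- direction / nd
  cr <- c(up[2] * direction[3] - up[3] * direction[2],
          up[3] * direction[1] - up[1] * direction[3],
          up[1] * direction[2] - up[2] * direction[1])
  if (length(up) != 3 || sqrt(sum(cr^2)) < 1e-9) {
    stop("`up` must be a length-3 vector not parallel to `direction`")
  }
  if (!is.null(sample_step) && sample_step <= 0) {
    stop("`sample_step` must be positive")
  }
  structure(
    list(direction = direction, up = up, sample_step = sample_step,
         width = width, height = height, pixel_pitch = pixel_pitch,
         background = as.numeric(background),
         interpolation = match.arg(interpolation)),
    class = "view_spec"
  )
}

#' Region of interest
#'
#' Half-open voxel-index box `[x0, x1) x [y0, y1) x [z0, z1)`, 0-based.
#' Voxels outside the box contribute nothing to the rendering.
#'
#' @param x0,x1,y0,y1,z0,z1 Integer bounds with `0 <= low < high`.
#' @return An `roi` object.
#' @export
roi <- function(x0, x1, y0, y1, z0, z1) {
  b <- c(x0, x1, y0, y1, z0, z1)
  if (any(b != trunc(b)) || x0 < 0 || y0 < 0 || z0 < 0 ||
      x1 <= x0 || y1 <= y0 || z1 <= z0) {
    stop("ROI bounds must be integers with 0 <= low < high on each axis")
  }
  structure(list(x0 = x0, x1 = x1, y0 = y0, y1 = y1, z0 = z0, z1 = z1),
            class = "roi")
}

#' Render an RGBA stack by emission-absorption ray casting
#'
#' Orthographic front-to-back compositing: along each ray,
#' `C <- C + (1 - alpha) * a' * c` and `alpha <- alpha + (1 - alpha) * a'`,
#' with early termination at accumulated opacity 0.995 and background
#' blending after exit. Grayscale stacks must pass through
#' [apply_colormap()] first.
#'
#' @param stack An RGBA `image_stack`.
#' @param view A [view_spec()].
#' @param region An [roi()] or `NULL` for the full volume.
#' @param early_termination Accumulated-opacity cutoff, default 0.995.
#' @return A `rendered_image`: 8-bit `H x W x 3` RGB array with the view
#'   attached.
#' @export
render_stack <- function(stack, view = view_spec(), region = NULL,
                         early_termination = 0.995) {
  stopifnot(inherits(stack, "image_stack"), inherits(view, "view_spec"))
  if (stack$semantics != "RGBA") {
    stop("render_stack() needs an RGBA stack; use apply_colormap() or ",
         "luminance_alpha() first")
  }
  d <- stack$data
  dims <- dim(d)
  nx <- dims[2]; ny <- dims[1]; nz <- dims[4]
  sp <- stack$spacing
  if (!is.null(region)) {
    stopifnot(inherits(region, "roi"))
    if (region$x1 > nx || region$y1 > ny || region$z1 > nz) {
      stop("ROI exceeds the volume extent")
    }
  }
  ref_step <- min(sp)
  step <- view$sample_step %||% ref_step
  pitch <- view$pixel_pitch %||% min(sp["sx"], sp["sy"])

  # physical extents; voxel centers at index * spacing, 0-based
  ex <- (nx - 1) * sp["sx"]; ey <- (ny - 1) * sp["sy"]
  ez <- (nz - 1) * sp["sz"]
  center <- c(ex, ey, ez) / 2
  diag_len <- sqrt(sum(c(ex + sp["sx"], ey + sp["sy"], ez + sp["sz"])^2))
  wpx <- view$width %||% max(2L, ceiling(diag_len / pitch))
  hpx <- view$height %||% wpx

  f <- view$direction
  r <- vcross(f, view$up)
  r <- r / sqrt(sum(r^2))
  u <- vcross(r, f)

  # pixel grid on the image plane through the volume center
  xs <- (seq_len(wpx) - (wpx + 1) / 2) * pitch
  ys <- ((hpx + 1) / 2 - seq_len(hpx)) * pitch
  npx <- wpx * hpx
  px <- rep(xs, each = hpx)
  py <- rep(ys, wpx)
  origin <- cbind(center[1] + px * r[1] + py * u[1] - diag_len / 2 * f[1],
                  center[2] + px * r[2] + py * u[2] - diag_len / 2 * f[2],
                  center[3] + px * r[3] + py * u[3] - diag_len / 2 * f[3])

  n_steps <- ceiling(diag_len / step) + 1L
  Cacc <- matrix(0, npx, 3)
  Aacc <- rep(0, npx)
  active <- seq_len(npx)
  rch <- as.vector(d[, , 1, ]); gch <- as.vector(d[, , 2, ])
  bch <- as.vector(d[, , 3, ]); ach <- as.vector(d[, , 4, ])
  vol <- list(r = rch, g = gch, b = bch, a = ach, ny = ny, nx = nx, nz = nz)
  expo <- step / ref_step

  for (k in seq_len(n_steps + 1L) - 1L) {
    if (length(active) == 0) break
    t_k <- k * step
    pos <- origin[active, , drop = FALSE]
    pos[, 1] <- pos[, 1] + t_k * f[1]
    pos[, 2] <- pos[, 2] + t_k * f[2]
    pos[, 3] <- pos[, 3] + t_k * f[3]
    s <- sample_rgba(vol, pos[, 1] / sp["sx"], pos[, 2] / sp["sy"],
                     pos[, 3] / sp["sz"], view$interpolation, region)
    a <- 1 - (1 - s$a / 255)^expo
    w <- (1 - Aacc[active]) * a
    Cacc[active, 1] <- Cacc[active, 1] + w * s$r / 255
    Cacc[active, 2] <- Cacc[active, 2] + w * s$g / 255
    Cacc[active, 3] <- Cacc[active, 3] + w * s$b / 255
    Aacc[active] <- Aacc[active] + w
    active <- active[Aacc[active] < early_termination]
  }
  bg <- view$background / 255
  for (ch in 1:3) Cacc[, ch] <- Cacc[, ch] + (1 - Aacc) * bg[ch]
  img <- array(0, c(hpx, wpx, 3))
  for (ch in 1:3) img[, , ch] <- matrix(quantize8(255 * Cacc[, ch]),
                                        hpx, wpx)
  structure(list(image = img, view = view), class = "rendered_image")
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Trilinear / nearest RGBA sampling at continuous voxel coordinates
# (0-based, voxel centers at integers). Outside the volume or the ROI the
# sample is fully transparent.
sample_rgba <- function(vol, vx, vy, vz, interpolation, region) {
  nx <- vol$nx; ny <- vol$ny; nz <- vol$nz
  n <- length(vx)
  zero <- list(r = numeric(n), g = numeric(n), b = numeric(n),
               a = numeric(n))
  if (interpolation == "nearest") {
    ix <- round(vx); iy <- round(vy); iz <- round(vz)
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny & iz >= 0 & iz < nz
    if (!is.null(region)) {
      ok <- ok & ix >= region$x0 & ix < region$x1 &
        iy >= region$y0 & iy < region$y1 &
        iz >= region$z0 & iz < region$z1
    }
    out <- zero
    if (any(ok)) {
      lin <- 1 + iy[ok] + ny * (ix[ok] + nx * iz[ok])
      out$r[ok] <- vol$r[lin]; out$g[ok] <- vol$g[lin]
      out$b[ok] <- vol$b[lin]; out$a[ok] <- vol$a[lin]
    }
    return(out)
  }
  ok <- vx >= 0 & vx <= nx - 1 & vy >= 0 & vy <= ny - 1 &
    vz >= 0 & vz <= nz - 1
  if (!is.null(region)) {
    # a sample position belongs to the ROI of its nearest voxel
    ix <- round(vx); iy <- round(vy); iz <- round(vz)
    ok <- ok & ix >= region$x0 & ix < region$x1 &
      iy >= region$y0 & iy < region$y1 &
      iz >= region$z0 & iz < region$z1
  }
  out <- zero
  if (!any(ok)) return(out)
  vx <- vx[ok]; vy <- vy[ok]; vz <- vz[ok]
  x0 <- pmin(pmax(floor(vx), 0), max(nx - 2, 0))
  y0 <- pmin(pmax(floor(vy), 0), max(ny - 2, 0))
  z0 <- pmin(pmax(floor(vz), 0), max(nz - 2, 0))
  fx <- vx - x0; fy <- vy - y0; fz <- vz - z0
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  z1 <- pmin(z0 + 1, nz - 1)
  lin <- function(ix, iy, iz) 1 + iy + ny * (ix + nx * iz)
  corners <- list(
    list(i = lin(x0, y0, z0), w = (1 - fx) * (1 - fy) * (1 - fz)),
    list(i = lin(x1, y0, z0), w = fx * (1 - fy) * (1 - fz)),
    list(i = lin(x0, y1, z0), w = (1 - fx) * fy * (1 - fz)),
    list(i = lin(x1, y1, z0), w = fx * fy * (1 - fz)),
    list(i = lin(x0, y0, z1), w = (1 - fx) * (1 - fy) * fz),
    list(i = lin(x1, y0, z1), w = fx * (1 - fy) * fz),
    list(i = lin(x0, y1, z1), w = (1 - fx) * fy * fz),
    list(i = lin(x1, y1, z1), w = fx * fy * fz)
  )
  rr <- gg <- bb <- aa <- numeric(length(vx))
  for (cn in corners) {
    rr <- rr + cn$w * vol$r[cn$i]
    gg <- gg + cn$w * vol$g[cn$i]
    bb <- bb + cn$w * vol$b[cn$i]
    aa <- aa + cn$w * vol$a[cn$i]
  }
  out$r[ok] <- rr; out$g[ok] <- gg; out$b[ok] <- bb; out$a[ok] <- aa
  out
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("rendered_image: %d x %d px\n", dim(x$image)[1],
              dim(x$image)[2]))
  invisible(x)
}

#' Re-invert a snapshot
#'
#' Maps every channel value to `255 - v`, recovering the original stain
#' colors in renderings produced from color-inverted stacks.
#'
#' @param img A `rendered_image` or an `H x W x 3` array.
#' @return Same type as the input.
#' @export
reinvert_snapshot <- function(img) {
  if (inherits(img, "rendered_image")) {
    img$image <- 255 - img$image
    img
  } else {
    255 - img
  }
}

#' Write a snapshot as PNG
#'
#' 8-bit RGB PNG plus a plain-text sidecar recording the view parameters.
#'
#' @param img A `rendered_image`.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_snapshot <- function(img, path) {
  stopifnot(inherits(img, "rendered_image"))
  png::writePNG(img$image / 255, path)
  v <- img$view
  side <- sub("\\.png$", "_view.yml", path)
  yaml::write_yaml(list(
    direction = v$direction, up = v$up,
    sample_step = v$sample_step, pixel_pitch = v$pixel_pitch,
    background = v$background, interpolation = v$interpolation
  ), side)
  invisible(path)
}

#' Turntable rendering
#'
#' Renders `n_frames` views at equally spaced azimuthal rotations of the
#' base view about the given physical axis; frame 1 is the base view.
#'
#' @param stack An RGBA `image_stack`.
#' @param view Base [view_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param axis Length-3 rotation axis in physical space, default z.
#' @param region Optional [roi()].
#' @return A list of `rendered_image`s.
#' @export
turntable <- function(stack, view = view_spec(c(1, 0, 0), c(0, 0, 1)),
                      n_frames = 8, axis = c(0, 0, 1), region = NULL) {
  stopifnot(n_frames >= 1)
  axis <- axis / sqrt(sum(axis^2))
  lapply(seq_len(n_frames) - 1L, function(k) {
    ang <- k * 2 * pi / n_frames
    v2 <- view
    v2$direction <- rotate_about(view$direction, axis, ang)
    v2$up <- rotate_about(view$up, axis, ang)
    render_stack(stack, v2, region)
  })
}

# Rodrigues rotation of vector v about unit axis by angle (radians).
rotate_about <- function(v, axis, angle) {
  v * cos(angle) + vcross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}
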