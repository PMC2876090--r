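# Pre-alignment editing: automated, reproducible replacements for the manual
# retouching steps of the classical serial-section workflow.

#' Color-invert a stack
#'
#' Maps every color channel value `v` to `255 - v` and toggles the
#' `inverted` flag. An alpha channel, if present, is left untouched.
#' Inversion turns white-background micrographs into the dark-background
#' convention that volume viewers and default colormaps expect.
#'
#' @param stack An `image_stack`.
#' @return The inverted stack.
#' @export
invert_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack$data
  nc <- dim(d)[3]
  color <- seq_len(min(nc, 3L))
  d[, , color, ] <- 255 - d[, , color, ]
  with_data(stack, d, inverted = !stack$inverted)
}

#' Normalize slice backgrounds to the white point
#'
#' Estimates each slice's white point as an upper percentile of its values
#' (per channel) and linearly rescales values above a preserved dark anchor
#' (the slice's 1st percentile) so the white point maps to 255. Background
#' regions become uniformly white within rounding, giving the homogeneous
#' white background the alignment and rendering stages assume. Operates on
#' the non-inverted (white background) convention.
#'
#' @param stack A non-inverted `image_stack`.
#' @param background_percentile Fraction in (0.5, 1\]; the upper percentile
#'   used as the white-point estimate. Default 0.95.
#' @return The normalized stack, with per-slice white points attached as
#'   attribute `"white_points"` (slices x channels matrix).
#' @export
normalize_background <- function(stack, background_percentile = 0.95) {
  stopifnot(inherits(stack, "image_stack"))
  if (background_percentile <= 0.5 || background_percentile > 1) {
    stop("`background_percentile` must lie in (0.5, 1]")
  }
  if (stack$inverted) {
    stop("normalize_background() operates on non-inverted stacks")
  }
  d <- stack$data
  nc <- min(dim(d)[3], 3L)
  nz <- dim(d)[4]
  wp <- matrix(NA_real_, nz, nc)
  for (i in seq_len(nz)) {
    for (ch in seq_len(nc)) {
      v <- d[, , ch, i]
      w <- stats::quantile(v, background_percentile, names = FALSE)
      lo <- stats::quantile(v, 0.01, names = FALSE)
      wp[i, ch] <- w
      if (w <= lo) {
        warning("slice ", i - 1, " channel ", ch,
                ": zero dynamic range, passed through unchanged")
        next
      }
      hi <- v > lo
      v[hi] <- lo + (v[hi] - lo) * (255 - lo) / (w - lo)
      d[, , ch, i] <- quantize8(v)
    }
  }
  out <- with_data(stack, d)
  attr(out, "white_points") <- wp
  out
}

#' Equalize staining intensity across slices
#'
#' Compensates slice-to-slice staining variation (including bleaching in
#' historical material) by gain-adjusting every slice so its mean foreground
#' luminance matches the stack-wide median of slice foreground means.
#' Foreground pixels are those with luminance below `fg_threshold` times the
#' slice white point (an upper percentile); the same multiplicative gain is
#' applied to all channels and clamped to \[0, 255\].
#'
#' @param stack A non-inverted `image_stack` with at least 2 slices.
#' @param background_percentile White-point percentile, as in
#'   [normalize_background()].
#' @param fg_threshold Fraction of the white point below which a pixel is
#'   classified as foreground. Default 0.9.
#' @return The equalized stack with the per-slice gains attached as
#'   attribute `"gains"`.
#' @export
equalize_slices <- function(stack, background_percentile = 0.95,
                            fg_threshold = 0.9) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  if (nz < 2) stop("equalize_slices() needs at least 2 slices")
  lum <- stack_luminance(stack)
  means <- rep(NA_real_, nz)
  masks <- vector("list", nz)
  for (i in seq_len(nz)) {
    li <- lum[, , i]
    w <- stats::quantile(li, background_percentile, names = FALSE)
    masks[[i]] <- li < fg_threshold * w
    if (any(masks[[i]])) means[i] <- mean(li[masks[[i]]])
  }
  target <- stats::median(means, na.rm = TRUE)
  gains <- rep(1, nz)
  d <- stack$data
  for (i in seq_len(nz)) {
    if (is.na(means[i]) || means[i] <= 0) {
      warning("slice ", i - 1, ": no foreground pixels, gain kept at 1")
      next
    }
    gains[i] <- target / means[i]
    d[, , , i] <- quantize8(d[, , , i] * gains[i])
  }
  out <- with_data(stack, d)
  attr(out, "gains") <- gains
  out
}

# Luminance volume (H x W x Z, double) for any semantics.
stack_luminance <- function(stack) {
  d <- stack$data
  if (dim(d)[3] == 1) {
    l <- d
    dim(l) <- dim(d)[c(1, 2, 4)]
    l
  } else {
    l <- ntsc_luminance(d[, , 1, , drop = FALSE], d[, , 2, , drop = FALSE],
                        d[, , 3, , drop = FALSE])
    dim(l) <- dim(d)[c(1, 2, 4)]
    l
  }
}

#' Downsample a stack in-plane by area averaging
#'
#' Resamples each slice to a coarser in-plane pixel size by exact area
#' averaging (integral-image implementation, so non-integer factors are
#' supported). The section axis is untouched: downsizing serves the rule
#' that section thickness should not exceed about three pixel edge-lengths.
#'
#' @param stack An `image_stack`.
#' @param target_xy_spacing Desired in-plane pixel size in micrometers; must
#'   be at least the current `sx` and `sy`.
#' @return The resampled stack with updated spacing.
#' @export
downsample_stack <- function(stack, target_xy_spacing) {
  stopifnot(inherits(stack, "image_stack"))
  sx <- stack$spacing["sx"]; sy <- stack$spacing["sy"]
  if (target_xy_spacing < sx || target_xy_spacing < sy) {
    stop("target spacing is finer than the source; refusing to upsample")
  }
  fx <- target_xy_spacing / sx
  fy <- target_xy_spacing / sy
  if (abs(fx - 1) < 1e-12 && abs(fy - 1) < 1e-12) return(stack)
  d <- stack$data
  h <- dim(d)[1]; w <- dim(d)[2]
  nh <- max(1L, floor(h / fy)); nw <- max(1L, floor(w / fx))
  out <- array(0, c(nh, nw, dim(d)[3], dim(d)[4]))
  for (i in seq_len(dim(d)[4])) {
    for (ch in seq_len(dim(d)[3])) {
      out[, , ch, i] <- quantize8(area_average(d[, , ch, i], nh, nw, fy, fx))
    }
  }
  image_stack(out, spacing = c(target_xy_spacing, target_xy_spacing,
                               stack$spacing["sz"]),
              inverted = stack$inverted)
}

# Exact area-average resampling of a 2D matrix to nh x nw with scale factors
# fy, fx (>= 1). Uses a summed-area table with fractional box edges.
area_average <- function(m, nh, nw, fy, fx) {
  h <- nrow(m); w <- ncol(m)
  # summed-area table with a zero first row/col: S[i+1, j+1] = sum m[1:i,1:j]
  S <- matrix(0, h + 1, w + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  # integral of m over [0, y] x [0, x] for fractional y, x (pixel i covers
  # [i-1, i)): bilinear interpolation of S is exact for box integrals
  lookup <- function(ys, xs) {
    yi <- pmin(pmax(floor(ys), 0), h); xi <- pmin(pmax(floor(xs), 0), w)
    yf <- pmin(ys, h) - yi; xf <- pmin(xs, w) - xi
    idx <- function(r, c) S[cbind(r + 1, c + 1)]
    # row direction first, then column
    g <- expand.grid(y = seq_along(ys), x = seq_along(xs))
    r0 <- yi[g$y]; c0 <- xi[g$x]; ry <- yf[g$y]; rx <- xf[g$x]
    r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
    v <- (1 - ry) * (1 - rx) * idx(r0, c0) +
      (1 - ry) * rx * idx(r0, c1) +
      ry * (1 - rx) * idx(r1, c0) +
      ry * rx * idx(r1, c1)
    matrix(v, length(ys), length(xs))
  }
  y_edges <- seq(0, by = fy, length.out = nh + 1)
  x_edges <- seq(0, by = fx, length.out = nw + 1)
  II <- lookup(y_edges, x_edges)
  box <- II[-1, -1, drop = FALSE] - II[-1, -(nw + 1), drop = FALSE] -
    II[-(nh + 1), -1, drop = FALSE] + II[-(nh + 1), -(nw + 1), drop = FALSE]
  areas <- outer(diff(pmin(y_edges, h)), diff(pmin(x_edges, w)))
  box / areas
}

#' Check the section-thickness anisotropy rule
#'
#' Computes the ratio of section thickness to the larger in-plane pixel
#' edge, `sz / max(sx, sy)`, and passes when it does not exceed
#' `max_anisotropy` (inclusive bound, default 3). Larger ratios yield
#' elongated voxels and visibly anisotropic renderings.
#'
#' @param spacing Length-3 positive numeric `(sx, sy, sz)` in micrometers,
#'   or an `image_stack`.
#' @param max_anisotropy Maximum admissible ratio, default 3.
#' @return A list with `ratio`, `max_anisotropy` and logical `pass`.
#' @export
#' @examples
#' check_anisotropy(c(0.25, 0.25, 0.5)) # ratio 2, pass
check_anisotropy <- function(spacing, max_anisotropy = 3) {
  if (inherits(spacing, "image_stack")) spacing <- spacing$spacing
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive values")
  }
  if (max_anisotropy < 1) stop("`max_anisotropy` must be >= 1")
  ratio <- spacing[3] / max(spacing[1], spacing[2])
  list(ratio = ratio, max_anisotropy = max_anisotropy,
       pass = ratio <= max_anisotropy)
}

#' Suppress isolated speckles in slice backgrounds
#'
#' Automated stand-in for manual retouching of dust and staining
#' precipitates: replaces background-classified pixels (luminance at or
#' above `fg_threshold` of the slice white point in the median-filtered
#' image) by a square median filter of the given radius. Foreground
#' structure is untouched. Default off in the pipeline.
#'
#' @param stack A non-inverted `image_stack`.
#' @param radius Median window radius in pixels (window `2r+1` square).
#' @param background_percentile,fg_threshold As in [equalize_slices()].
#' @return The despeckled stack.
#' @export
despeckle <- function(stack, radius = 1, background_percentile = 0.95,
                      fg_threshold = 0.9) {
  stopifnot(inherits(stack, "image_stack"), radius >= 1)
  d <- stack$data
  nz <- dim(d)[4]; nc <- dim(d)[3]
  for (i in seq_len(nz)) {
    med <- array(0, dim(d)[1:3])
    for (ch in seq_len(nc)) med[, , ch] <- median2d(d[, , ch, i], radius)
    ml <- if (nc == 1) med[, , 1] else {
      ntsc_luminance(med[, , 1], med[, , 2], med[, , 3])
    }
    w <- stats::quantile(ml, background_percentile, names = FALSE)
    bg <- ml >= fg_threshold * w
    for (ch in seq_len(nc)) {
      v <- d[, , ch, i]
      v[bg] <- med[, , ch][bg]
      d[, , ch, i] <- v
    }
  }
  with_data(stack, d)
}

# Square median filter with edge replication; small windows only.
median2d <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h + 2 * r) - r, 1), h)
  ci <- pmin(pmax(seq_len(w + 2 * r) - r, 1), w)
  p <- m[ri, ci]
  k <- 2 * r + 1
  stackv <- vapply(seq_len(k^2), function(s) {
    dy <- (s - 1) %% k
    dx <- (s - 1) %/% k
    as.vector(p[dy + seq_len(h), dx + seq_len(w)])
  }, numeric(h * w))
  matrix(apply(stackv, 1, stats::median), h, w)
}
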