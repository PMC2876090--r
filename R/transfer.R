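# Transparency transfer functions and colormaps.
#
# A transfer function is a monotone non-decreasing map from stored 8-bit
# alpha to 8-bit opacity with f(0) = 0 and f(255) = 255. The four
# parametric families mirror the arithmetic expressions of the classical
# workflow: linear/gamma, hard threshold, power-law with increasing slope
# (pow(A, x)/pow(255, x-1)), power-law with decreasing slope
# (255 - pow(255 - A, x)/pow(255, x-1)), plus monotone piecewise-linear
# control points.

#' Construct a transparency transfer function
#'
#' @param kind One of `"linear_gamma"`, `"threshold"`, `"power_increasing"`,
#'   `"power_decreasing"`, `"piecewise"`.
#' @param gamma Exponent for `linear_gamma` (> 0; 1 is the identity,
#'   > 1 softer, < 1 harder).
#' @param t Threshold 0-254 for `threshold`: output 255 strictly above `t`,
#'   else 0.
#' @param x Exponent >= 1 for the power kinds (default 3, the demonstrated
#'   cubic).
#' @param points For `piecewise`: a 2-column matrix of monotone
#'   (alpha, opacity) control points including (0, 0) and (255, 255).
#' @return A `transfer_function` object; evaluate with [tf_eval()].
#' @export
transfer_function <- function(kind = c("linear_gamma", "threshold",
                                       "power_increasing",
                                       "power_decreasing", "piecewise"),
                              gamma = 1, t = 10, x = 3, points = NULL) {
  kind <- match.arg(kind)
  tf <- switch(
    kind,
    linear_gamma = {
      if (gamma <= 0) stop("`gamma` must be > 0")
      list(kind = kind, gamma = gamma)
    },
    threshold = {
      if (t < 0 || t >= 255) stop("threshold `t` must lie in [0, 255)")
      list(kind = kind, t = t)
    },
    power_increasing = ,
    power_decreasing = {
      if (x < 1) stop("exponent `x` must be >= 1")
      list(kind = kind, x = x)
    },
    piecewise = {
      p <- as.matrix(points)
      if (is.null(points) || ncol(p) != 2) {
        stop("`points` must be a 2-column (alpha, opacity) matrix")
      }
      if (is.unsorted(p[, 1], strictly = TRUE) || is.unsorted(p[, 2])) {
        stop("piecewise control points must be monotone non-decreasing")
      }
      if (p[1, 1] != 0 || p[nrow(p), 1] != 255 ||
          p[1, 2] != 0 || p[nrow(p), 2] != 255) {
        stop("piecewise control points must span (0,0) to (255,255)")
      }
      list(kind = kind, points = p)
    }
  )
  structure(tf, class = "transfer_function")
}

#' Evaluate a transfer function
#'
#' Maps stored alpha values (0-255) to opacity values (0-255) under the
#' package rounding rule.
#'
#' @param tf A [transfer_function()].
#' @param A Numeric vector/array of alpha values in \[0, 255\].
#' @return Quantized opacities, same shape as `A`.
#' @export
#' @examples
#' tf_eval(transfer_function("threshold", t = 10), c(0, 10, 128)) # 0 0 255
#' tf_eval(transfer_function("power_increasing", x = 3), 255)     # 255
tf_eval <- function(tf, A) {
  stopifnot(inherits(tf, "transfer_function"))
  switch(
    tf$kind,
    linear_gamma = quantize8(255 * (A / 255)^tf$gamma),
    threshold = 255 * (A > tf$t),
    power_increasing = quantize8(A^tf$x / 255^(tf$x - 1)),
    power_decreasing = quantize8(255 - (255 - A)^tf$x / 255^(tf$x - 1)),
    piecewise = quantize8(stats::approx(tf$points[, 1], tf$points[, 2],
                                        xout = A, rule = 2)$y),
    mirrored = tf_eval_mirrored(tf, A)
  )
}

#' @export
print.transfer_function <- function(x, ...) {
  par <- switch(x$kind,
                linear_gamma = paste0("gamma = ", x$gamma),
                threshold = paste0("t = ", x$t),
                power_increasing = ,
                power_decreasing = paste0("x = ", x$x),
                piecewise = paste0(nrow(x$points), " control points"))
  cat("transfer_function:", x$kind, "(", par, ")\n")
  invisible(x)
}

#' Mirror a transfer function for non-inverted stacks
#'
#' Returns the function `A -> f(255 - A)`, so that bright-background
#' (non-inverted) stacks can be rendered without inverting the data.
#'
#' @param tf A [transfer_function()].
#' @return A `transfer_function` of kind `mirrored` tabulating the
#'   mirrored map (monotone non-increasing; mirroring twice restores the
#'   original values).
#' @export
invert_transfer <- function(tf) {
  vals <- tf_eval(tf, 255 - (0:255))
  structure(list(kind = "mirrored", table = vals, base = tf),
            class = "transfer_function")
}

# mirrored kind: direct table lookup
tf_eval_mirrored <- function(tf, A) tf$table[quantize8(A) + 1]

#' Build an RGBA stack with a luminance-derived alpha channel
#'
#' Replaces the (implicitly all-white) alpha channel of an RGB stack by the
#' NTSC grayscale conversion of its color channels — the linear transparency
#' function. On inverted stacks the black background receives alpha 0 and
#' becomes almost totally transparent in the rendering.
#'
#' @param stack An RGB `image_stack`.
#' @return An RGBA `image_stack`.
#' @export
luminance_alpha <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$semantics != "RGB") {
    stop("luminance_alpha() needs RGB semantics, got ", stack$semantics)
  }
  d <- stack$data
  dims <- dim(d)
  out <- array(0, c(dims[1], dims[2], 4L, dims[4]))
  out[, , 1:3, ] <- d
  out[, , 4, ] <- quantize8(ntsc_luminance(d[, , 1, ], d[, , 2, ],
                                           d[, , 3, ]))
  with_data(stack, out)
}

#' Transform the alpha channel of an RGBA stack
#'
#' Applies a transfer function voxelwise to the alpha channel; the three
#' color channels pass through unchanged.
#'
#' @param stack An RGBA `image_stack`.
#' @param tf A [transfer_function()].
#' @return The stack with transformed alpha.
#' @export
apply_transfer <- function(stack, tf) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$semantics != "RGBA") {
    stop("apply_transfer() needs RGBA semantics, got ", stack$semantics)
  }
  d <- stack$data
  A <- d[, , 4, ]
  d[, , 4, ] <- if (tf$kind == "mirrored") tf_eval_mirrored(tf, A) else {
    tf_eval(tf, A)
  }
  with_data(stack, d)
}

#' Colormaps for grayscale rendering
#'
#' A colormap is a 256-entry RGB lookup (values 0-255), optionally with a
#' per-entry opacity column. The built-in `"glow"` map is a
#' black - dark-red - orange - pale-yellow - white ramp with the top
#' `clip_top` entries flattened to the last unclipped color, preventing
#' glare at the bright end; its luminance is non-decreasing.
#'
#' @param name `"glow"` or `"gray"`.
#' @param clip_top Number of highest entries flattened (glow only).
#' @return A `colormap` object: list with `name`, `rgb` (256 x 3) and
#'   optional `opacity` (length 256).
#' @export
colormap <- function(name = c("glow", "gray"), clip_top = 16) {
  name <- match.arg(name)
  rgb <- switch(
    name,
    gray = cbind(0:255, 0:255, 0:255),
    glow = {
      anchors <- rbind(
        c(0, 0, 0),
        c(128, 0, 0),
        c(255, 128, 0),
        c(255, 255, 128),
        c(255, 255, 255)
      )
      pos <- seq(0, 255, length.out = nrow(anchors))
      m <- vapply(1:3, function(ch) {
        stats::approx(pos, anchors[, ch], xout = 0:255)$y
      }, numeric(256))
      quantize8(m)
    }
  )
  if (name == "glow" && clip_top > 0) {
    keep <- 256 - clip_top
    rgb[(keep + 1):256, ] <- rep(rgb[keep, ], each = clip_top)
  }
  structure(list(name = name, rgb = rgb, opacity = NULL,
                 clip_top = if (name == "glow") clip_top else 0),
            class = "colormap")
}

#' @export
print.colormap <- function(x, ...) {
  cat("colormap:", x$name, "(256 entries",
      if (x$clip_top > 0) paste0(", top ", x$clip_top, " clipped"), ")\n")
  invisible(x)
}

#' Reverse a colormap
#'
#' Entry `i` becomes entry `255 - i`; together with [invert_transfer()] this
#' renders non-inverted stacks as if they had been color-inverted.
#'
#' @param map A [colormap()].
#' @return The reversed colormap.
#' @export
invert_colormap <- function(map) {
  stopifnot(inherits(map, "colormap"))
  map$rgb <- map$rgb[256:1, , drop = FALSE]
  if (!is.null(map$opacity)) map$opacity <- rev(map$opacity)
  map$name <- paste0(map$name, "_inverted")
  map
}

#' Apply a colormap and transfer function to a grayscale stack
#'
#' Per voxel, the RGB color is the colormap entry for the gray value and
#' the alpha is the transfer function of the gray value, producing the RGBA
#' stack the renderer consumes.
#'
#' @param stack A grayscale `image_stack`.
#' @param map A [colormap()] (default the glow ramp).
#' @param tf A [transfer_function()] (default linear, gamma 1).
#' @return An RGBA `image_stack`.
#' @export
apply_colormap <- function(stack, map = colormap("glow"),
                           tf = transfer_function("linear_gamma", gamma = 1)) {
  stopifnot(inherits(stack, "image_stack"), inherits(map, "colormap"))
  if (stack$semantics != "GRAY") {
    stop("apply_colormap() needs GRAY semantics, got ", stack$semantics)
  }
  d <- stack$data
  dims <- dim(d)
  out <- array(0, c(dims[1], dims[2], 4L, dims[4]))
  for (i in seq_len(dims[4])) {
    gi <- as.vector(d[, , 1, i]) + 1
    out[, , 1, i] <- map$rgb[gi, 1]
    out[, , 2, i] <- map$rgb[gi, 2]
    out[, , 3, i] <- map$rgb[gi, 3]
    a <- if (tf$kind == "mirrored") tf_eval_mirrored(tf, gi - 1) else {
      tf_eval(tf, gi - 1)
    }
    if (!is.null(map$opacity)) {
      a <- quantize8(a * map$opacity[gi] / 255)
    }
    out[, , 4, i] <- a
  }
  with_data(stack, out)
}

#' Read or write a colormap as a plain-text table
#'
#' 256-row table with columns `index, r, g, b` and optionally `a`.
#'
#' @param map A [colormap()].
#' @param path File path.
#' @return `write_colormap()`: the path, invisibly; `read_colormap()`: a
#'   `colormap`.
#' @export
write_colormap <- function(map, path) {
  tab <- data.frame(index = 0:255, r = map$rgb[, 1], g = map$rgb[, 2],
                    b = map$rgb[, 3])
  if (!is.null(map$opacity)) tab$a <- map$opacity
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_colormap
#' @export
read_colormap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  if (nrow(tab) != 256) stop("colormap table must have 256 rows")
  structure(list(name = basename(path),
                 rgb = as.matrix(tab[, c("r", "g", "b")]),
                 opacity = if ("a" %in% names(tab)) tab$a else NULL,
                 clip_top = 0),
            class = "colormap")
}
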