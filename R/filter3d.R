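# Volumetric smoothing.
#
# Two filters: separable 3D Gaussian convolution, and edge-preserving
# smoothing interpreted as Perona-Malik-type nonlinear diffusion with
# exponential conductance g(m) = exp(-(m / contrast)^2) driven by the
# gradient of a Gaussian-presmoothed field. Internal arithmetic is floating
# point; quantization to 8-bit happens once at the end.

#' Gaussian smoothing parameters
#'
#' @param kernel Kernel size in voxels per axis, length 1 or 3. Even sizes
#'   have no center voxel and are promoted to the next odd size with a
#'   message (the nominal size stays in the configuration).
#' @param sigma Gaussian scale in voxels per axis, length 1 or 3.
#' @return A `gauss_params` list.
#' @export
gauss_params <- function(kernel = c(6, 6, 6), sigma = c(1, 1, 1)) {
  kernel <- rep(as.integer(kernel), length.out = 3)
  sigma <- rep(as.numeric(sigma), length.out = 3)
  if (any(kernel < 1) || any(sigma <= 0)) {
    stop("kernel sizes must be >= 1 and sigmas > 0")
  }
  structure(list(kernel = kernel, sigma = sigma), class = "gauss_params")
}

#' Edge-preserving smoothing parameters
#'
#' `contrast` is the gray-value edge threshold of the conductance,
#' `sigma` the gradient presmoothing scale in voxels, `step` the nominal
#' time increment per iteration and `stop` the total diffusion time
#' (`floor(stop/step)` iterations; the defaults give 5).
#'
#' @param contrast,sigma,step,stop Positive numerics; `stop >= step` for
#'   any smoothing to occur.
#' @return An `edge_preserve_params` list.
#' @export
edge_preserve_params <- function(contrast = 3.5, sigma = 3, step = 5,
                                 stop = 25) {
  if (any(c(contrast, sigma, step, stop) <= 0)) {
    stop("all edge-preserving parameters must be positive")
  }
  structure(list(contrast = contrast, sigma = sigma, step = step,
                 stop = stop),
            class = "edge_preserve_params")
}

# 1D convolution along one axis of a 3D array with symmetric (reflective)
# boundaries, implemented as a sum of shifted slabs.
conv_axis3 <- function(a, w, axis) {
  h <- (length(w) - 1) / 2
  n <- dim(a)[axis]
  idx <- reflect_idx(n, h)
  out <- array(0, dim(a))
  for (j in seq_along(w)) {
    sel <- idx[j:(j + n - 1)]
    shifted <- switch(axis,
                      a[sel, , , drop = FALSE],
                      a[, sel, , drop = FALSE],
                      a[, , sel, drop = FALSE])
    out <- out + w[j] * shifted
  }
  out
}

# Separable Gaussian on a 3D double array (no quantization).
gauss3d_raw <- function(vol, kernel, sigma) {
  kernel <- ifelse(kernel %% 2 == 0, kernel + 1L, kernel)
  for (ax in 1:3) {
    if (kernel[ax] > 1) {
      if (kernel[ax] > dim(vol)[ax]) {
        stop("kernel (", kernel[ax], ") larger than volume extent (",
             dim(vol)[ax], ") along axis ", ax)
      }
      vol <- conv_axis3(vol, gauss_kernel1d(kernel[ax], sigma[ax]), ax)
    }
  }
  vol
}

#' 3D Gaussian smoothing of a grayscale stack
#'
#' Separable convolution with a sampled, truncated, normalized Gaussian per
#' axis, reflective boundary handling, in voxel units. Even kernel sizes are
#' promoted to the next odd size to avoid a half-voxel phase shift. Defaults
#' are the paraffin-profile kernel (nominal 6x6x6, sigma 1); the
#' resin profile uses 3x3x3.
#'
#' @param stack A grayscale `image_stack`.
#' @param params A [gauss_params()].
#' @return The smoothed stack, quantized once at the end.
#' @export
gaussian_smooth <- function(stack, params = gauss_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "gauss_params"))
  if (stack$semantics != "GRAY") {
    stop("gaussian_smooth() expects a grayscale stack; see filter_rgb()")
  }
  if (any(params$kernel %% 2 == 0)) {
    message("even kernel size(s) ", paste(params$kernel, collapse = "x"),
            " promoted to next odd size")
  }
  vol <- stack$data
  dim(vol) <- dim(vol)[c(1, 2, 4)]
  vol <- gauss3d_raw(vol, params$kernel, params$sigma)
  with_data(stack, quantize8(vol))
}

# Explicit Perona-Malik scheme on a 3D double array. The conductance field
# is recomputed every outer step (every `step` time units) from the
# sigma-presmoothed gradient; each outer step is integrated with stable
# sub-steps dt <= 1/6 (g <= 1 keeps the explicit scheme contractive, which
# also enforces the maximum principle). Zero-flux boundaries.
diffuse3d_raw <- function(vol, contrast, sigma, step, stop) {
  n_outer <- floor(stop / step)
  if (n_outer < 1) return(vol)
  dmax <- dim(vol)
  # presmoothing kernel truncated at ~2 sigma, capped to fit the volume
  r_pre <- min(ceiling(2 * sigma), floor((min(dmax) - 1) / 2))
  k_pre <- 2L * r_pre + 1L
  for (it in seq_len(n_outer)) {
    us <- gauss3d_raw(vol, rep(k_pre, 3), rep(sigma, 3))
    g <- exp(-(grad_mag3(us) / contrast)^2)
    t_done <- 0
    while (t_done < step - 1e-12) {
      dt <- min(1 / 6, step - t_done)
      vol <- vol + dt * pm_divergence(vol, g)
      t_done <- t_done + dt
    }
  }
  vol
}

# Central-difference gradient magnitude with edge replication.
grad_mag3 <- function(u) {
  gx2 <- (shift3(u, 2, 1) - shift3(u, 2, -1))^2
  gy2 <- (shift3(u, 1, 1) - shift3(u, 1, -1))^2
  gz2 <- (shift3(u, 3, 1) - shift3(u, 3, -1))^2
  sqrt((gx2 + gy2 + gz2) / 4)
}

# Shift a 3D array by `by` along `axis` with edge replication.
shift3 <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1), n)
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# div( g * grad u ) with face conductances as averages of voxel
# conductances and zero-flux boundaries (edge-replicated shifts make the
# boundary differences vanish).
pm_divergence <- function(u, g) {
  acc <- array(0, dim(u))
  for (ax in 1:3) {
    up <- shift3(u, ax, 1) - u
    dn <- shift3(u, ax, -1) - u
    gp <- (shift3(g, ax, 1) + g) / 2
    gn <- (shift3(g, ax, -1) + g) / 2
    acc <- acc + gp * up + gn * dn
  }
  acc
}

#' Edge-preserving smoothing of a grayscale stack
#'
#' Nonlinear (Perona-Malik-type) diffusion: the volume is iterated under
#' `u <- u + dt * div( g(|grad u_sigma|) * grad u )` with conductance
#' `g(m) = exp(-(m/contrast)^2)` computed from the Gaussian-presmoothed
#' field, for `floor(stop/step)` conductance updates covering total time
#' `stop`. Smooths within regions while stalling diffusion across
#' gray-value edges stronger than `contrast`. The output value range never
#' exceeds the input range.
#'
#' @param stack A grayscale `image_stack`.
#' @param params An [edge_preserve_params()]; the defaults
#'   (contrast 3.5, sigma 3, step 5, stop 25) are the paraffin profile.
#' @return The smoothed stack, quantized once at the end.
#' @export
edge_preserving_smooth <- function(stack, params = edge_preserve_params()) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(params, "edge_preserve_params"))
  if (stack$semantics != "GRAY") {
    stop("edge_preserving_smooth() expects a grayscale stack; see filter_rgb()")
  }
  vol <- stack$data
  dim(vol) <- dim(vol)[c(1, 2, 4)]
  vol <- diffuse3d_raw(vol, params$contrast, params$sigma, params$step,
                       params$stop)
  with_data(stack, quantize8(vol))
}

#' Filter a color stack channel by channel
#'
#' Splits an RGB(A) stack into its R, G, B channels, applies the given
#' filter to each with identical parameters, recombines, and recomputes the
#' alpha channel from the filtered channels by NTSC luminance — the
#' recombination behavior of the classical color workflow, which yields a
#' linear transparency function with no manual adjustment.
#'
#' @param stack An RGB or RGBA `image_stack` (a pre-existing alpha channel
#'   is discarded and recomputed).
#' @param params A [gauss_params()] or [edge_preserve_params()].
#' @return An RGBA `image_stack`.
#' @export
filter_rgb <- function(stack, params = gauss_params()) {
  stopifnot(inherits(stack, "image_stack"))
  if (!stack$semantics %in% c("RGB", "RGBA")) {
    stop("filter_rgb() expects a color stack, got ", stack$semantics)
  }
  d <- stack$data
  dims <- dim(d)
  out <- array(0, c(dims[1], dims[2], 4L, dims[4]))
  for (ch in 1:3) {
    vol <- d[, , ch, , drop = FALSE]
    dim(vol) <- dims[c(1, 2, 4)]
    vol <- if (inherits(params, "gauss_params")) {
      gauss3d_raw(vol, params$kernel, params$sigma)
    } else if (inherits(params, "edge_preserve_params")) {
      diffuse3d_raw(vol, params$contrast, params$sigma, params$step,
                    params$stop)
    } else {
      stop("`params` must be gauss_params or edge_preserve_params")
    }
    out[, , ch, ] <- quantize8(vol)
  }
  out[, , 4, ] <- quantize8(ntsc_luminance(out[, , 1, ], out[, , 2, ],
                                           out[, , 3, ]))
  with_data(stack, out)
}

#' Named filter presets
#'
#' `"paraffin"`: 6x6x6 sigma-1 Gaussian followed by edge-preserving
#' smoothing (contrast 3.5, sigma 3, step 5, stop 25) — for wax sections
#' with stretching distortion. `"resin"`: a modest 3x3x3 sigma-1 Gaussian
#' (resin sections are geometrically stable; `"none"` skips filtering
#' entirely).
#'
#' @param preset One of `"paraffin"`, `"resin"`, `"none"`.
#' @return A list of parameter objects (possibly empty) to apply in order.
#' @export
filter_preset <- function(preset = c("paraffin", "resin", "none")) {
  preset <- match.arg(preset)
  switch(preset,
         paraffin = list(gauss_params(c(6, 6, 6), 1),
                         edge_preserve_params(3.5, 3, 5, 25)),
         resin = list(gauss_params(c(3, 3, 3), 1)),
         none = list())
}
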