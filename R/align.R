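# Rigid slice-to-slice registration by least squares.
#
# The objective is the mean squared gray-value difference between a fixed
# slice and the rigidly resampled moving slice over their overlap region.
# The optimizer is an exhaustive coarse grid on an image pyramid followed by
# derivative-free local refinement (Nelder-Mead); if refinement ever ends
# worse than the identity, the identity is returned, so the fit can never be
# worse than doing nothing.

#' Rigid 2D transform
#'
#' Rotation `theta` (degrees counterclockwise in image coordinates, about
#' the image center) followed by translation `(tx, ty)` in pixels.
#'
#' @param theta Rotation in degrees; normalized to (-180, 180].
#' @param tx,ty Translation in pixels (x = column, y = row).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0) {
  theta <- ((theta + 180) %% 360) - 180
  if (theta == -180) theta <- 180
  structure(list(theta = theta, tx = tx, ty = ty), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: theta %.4f deg, t (%.4f, %.4f) px\n",
              x$theta, x$tx, x$ty))
  invisible(x)
}

#' @rdname rigid_transform
#' @param a,b Transforms; `compose_transform(a, b)` is "apply `b`, then `a`"
#'   about the same image center.
#' @export
compose_transform <- function(a, b) {
  # p -> Ra (Rb (p - c) + c + tb - c) + c + ta
  th <- a$theta + b$theta
  ra <- a$theta * pi / 180
  R <- matrix(c(cos(ra), sin(ra), -sin(ra), cos(ra)), 2, 2)
  t2 <- R %*% c(b$tx, b$ty) + c(a$tx, a$ty)
  rigid_transform(th, t2[1], t2[2])
}

#' @rdname rigid_transform
#' @param tf A `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  r <- -tf$theta * pi / 180
  R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  t2 <- -R %*% c(tf$tx, tf$ty)
  rigid_transform(-tf$theta, t2[1], t2[2])
}

#' Resample a slice under a rigid transform
#'
#' Applies the transform (rotation about the image center, then translation)
#' with bilinear interpolation. Output pixels whose source location falls
#' outside the slice receive `fill_value`; the workflow default is 0 (black)
#' for inverted stacks and 255 (white) for non-inverted stacks, so that
#' corners exposed by rotation blend into the background.
#'
#' @param slice `H x W` matrix or `H x W x C` array, values 0-255.
#' @param transform A [rigid_transform()].
#' @param fill_value Value for out-of-bounds pixels, 0-255.
#' @return The resampled slice, quantized to 8-bit.
#' @export
resample_slice <- function(slice, transform, fill_value = 0) {
  was_matrix <- is.matrix(slice)
  if (was_matrix) dim(slice) <- c(dim(slice), 1L)
  h <- dim(slice)[1]; w <- dim(slice)[2]; nc <- dim(slice)[3]
  q <- inverse_map(transform, h, w)
  out <- array(fill_value, dim(slice))
  for (ch in seq_len(nc)) {
    out[, , ch] <- bilinear_gather(slice[, , ch], q$x, q$y, fill_value)
  }
  out <- quantize8(out)
  if (was_matrix) dim(out) <- c(h, w)
  out
}

# Source coordinates (0-based, x = col, y = row) for every output pixel.
inverse_map <- function(tf, h, w) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  px <- matrix(rep(seq_len(w) - 1, each = h), h, w) - cx - tf$tx
  py <- matrix(rep(seq_len(h) - 1, w), h, w) - cy - tf$ty
  r <- -tf$theta * pi / 180
  list(x = cos(r) * px - sin(r) * py + cx,
       y = sin(r) * px + cos(r) * py + cy)
}

# Vectorized bilinear sampling of matrix m at 0-based coords (qx, qy);
# out-of-range locations get `fill` (or NA to mark them).
bilinear_gather <- function(m, qx, qy, fill = NA) {
  h <- nrow(m); w <- ncol(m)
  valid <- qx >= 0 & qx <= w - 1 & qy >= 0 & qy <= h - 1
  x0 <- pmin(pmax(floor(qx), 0), max(w - 2, 0))
  y0 <- pmin(pmax(floor(qy), 0), max(h - 2, 0))
  fx <- qx - x0; fy <- qy - y0
  i00 <- cbind(as.vector(y0) + 1, as.vector(x0) + 1)
  v <- (1 - fy) * (1 - fx) * m[i00] +
    (1 - fy) * fx * m[cbind(i00[, 1], pmin(i00[, 2] + 1, w))] +
    fy * (1 - fx) * m[cbind(pmin(i00[, 1] + 1, h), i00[, 2])] +
    fy * fx * m[cbind(pmin(i00[, 1] + 1, h), pmin(i00[, 2] + 1, w))]
  v[!valid] <- fill
  out <- matrix(v, h, w)
  out
}

# Mean squared difference between fixed and transformed moving over the
# overlap region (out-of-bounds samples excluded). Inf when no overlap.
register_objective <- function(fixed, moving, par) {
  q <- inverse_map(rigid_transform(par[1], par[2], par[3]),
                   nrow(fixed), ncol(fixed))
  mv <- bilinear_gather(moving, q$x, q$y, NA)
  d <- (fixed - mv)^2
  if (all(is.na(d))) return(Inf)
  mean(d, na.rm = TRUE)
}

# "Half" of a rigid transform: H with H o H equal to the input.
half_transform <- function(par) {
  thh <- par[1] / 2
  r <- thh * pi / 180
  Rh <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  th <- solve(diag(2) + Rh, par[2:3])
  rigid_transform(thh, th[1], th[2])
}

# Symmetric form of the objective: both images are resampled by half the
# transform (fixed backward, moving forward), which balances the
# interpolation blur between the two and removes most of the sub-pixel
# bias of the one-sided objective. Used for the final refinement only.
register_objective_sym <- function(fixed, moving, par) {
  H <- half_transform(par)
  qa <- inverse_map(invert_transform(H), nrow(fixed), ncol(fixed))
  qb <- inverse_map(H, nrow(moving), ncol(moving))
  a <- bilinear_gather(fixed, qa$x, qa$y, NA)
  b <- bilinear_gather(moving, qb$x, qb$y, NA)
  d <- (a - b)^2
  if (all(is.na(d))) return(Inf)
  mean(d, na.rm = TRUE)
}

#' Register one slice to another by least squares
#'
#' Finds the rigid transform minimizing the mean squared gray-value
#' difference between `fixed` and the resampled `moving` slice, within the
#' given search bounds. Multi-resolution: an exhaustive integer-step grid at
#' the coarsest pyramid level, then Nelder-Mead refinement up the pyramid.
#' The returned transform maps `moving` into the frame of `fixed`, i.e.
#' `resample_slice(moving, tf)` best overlays `fixed`.
#'
#' @param fixed,moving Grayscale slices (`H x W` matrices, 0-255) of equal
#'   size. Color slices should be registered on their luminance.
#' @param search List with `tx`, `ty` (pixels) and `theta` (degrees) giving
#'   symmetric search bounds; defaults `±15 px`, `±10°`.
#' @param presmooth Gaussian scale (pixels) applied to both images before
#'   matching; equalizes resampling blur between the pair and reduces the
#'   subpixel bias of the interpolated objective. 0 disables. The returned
#'   transform always refers to the original images.
#' @return A [rigid_transform()] with attributes `objective` (MSD at the
#'   optimum) and `objective_identity`.
#' @export
register_pair <- function(fixed, moving,
                          search = list(tx = 15, ty = 15, theta = 10),
                          presmooth = 2) {
  stopifnot(is.matrix(fixed), is.matrix(moving),
            all(dim(fixed) == dim(moving)))
  if (any(unlist(search) <= 0)) stop("search bounds must be positive")
  if (presmooth > 0) {
    fixed <- smooth2d(fixed, presmooth)
    moving <- smooth2d(moving, presmooth)
  }
  id_obj <- register_objective(fixed, moving, c(0, 0, 0))
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0) {
    warning("constant image(s): objective is flat, returning identity")
    out <- rigid_transform(0, 0, 0)
    attr(out, "objective") <- id_obj
    attr(out, "objective_identity") <- id_obj
    return(out)
  }

  # pyramid by factor-2 block means down to ~32 px on the short side
  pyr <- list(list(f = fixed, m = moving, s = 1))
  while (min(dim(pyr[[length(pyr)]]$f)) >= 64) {
    lv <- pyr[[length(pyr)]]
    pyr[[length(pyr) + 1]] <- list(f = halve(lv$f), m = halve(lv$m),
                                   s = lv$s * 2)
  }
  coarse <- pyr[[length(pyr)]]
  sc <- coarse$s
  txs <- seq(-search$tx, search$tx, by = sc) / sc
  tys <- seq(-search$ty, search$ty, by = sc) / sc
  ths <- seq(-search$theta, search$theta, by = max(1, sc))
  best <- c(0, 0, 0); best_obj <- Inf
  for (th in ths) {
    for (tx in txs) {
      for (ty in tys) {
        o <- register_objective(coarse$f, coarse$m, c(th, tx, ty))
        if (o < best_obj) {
          best_obj <- o
          best <- c(th, tx, ty)
        }
      }
    }
  }
  par <- best
  for (lv in rev(seq_along(pyr))) {
    level <- pyr[[lv]]
    start <- c(par[1], par[2] * sc / level$s, par[3] * sc / level$s)
    fit <- stats::optim(
      start,
      function(p) register_objective(level$f, level$m, p),
      method = "Nelder-Mead",
      control = list(reltol = 1e-10, maxit = 400)
    )
    par <- fit$par
    sc <- level$s
  }
  # final polish under the symmetric (half-transform) objective
  fit <- stats::optim(
    par,
    function(p) register_objective_sym(fixed, moving, p),
    method = "Nelder-Mead",
    control = list(reltol = 1e-10, maxit = 400)
  )
  par <- fit$par
  obj <- register_objective(fixed, moving, par)
  if (obj > id_obj) {
    par <- c(0, 0, 0)
    obj <- id_obj
  }
  out <- rigid_transform(par[1], par[2], par[3])
  attr(out, "objective") <- obj
  attr(out, "objective_identity") <- id_obj
  out
}

# Separable 2D Gaussian with symmetric boundaries (double precision).
smooth2d <- function(m, sigma) {
  w <- gauss_kernel1d(2 * ceiling(2 * sigma) + 1, sigma)
  h <- (length(w) - 1) / 2
  if (h > min(dim(m))) return(m)
  p <- m[reflect_idx(nrow(m), h), reflect_idx(ncol(m), h)]
  tmp <- matrix(0, nrow(m) + 2 * h, ncol(m))
  for (j in seq_along(w)) tmp <- tmp + w[j] * p[, j:(j + ncol(m) - 1)]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(w)) out <- out + w[j] * tmp[j:(j + nrow(m) - 1), ]
  out
}

halve <- function(m) {
  h <- nrow(m) %/% 2; w <- ncol(m) %/% 2
  m <- m[seq_len(2 * h), seq_len(2 * w)]
  0.25 * (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
            m[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
            m[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
            m[seq(2, 2 * h, 2), seq(2, 2 * w, 2)])
}

#' Align a stack by sequential pairwise registration
#'
#' Registers each slice to its aligned predecessor (slice 0 is the fixed
#' reference): the relative transform of each adjacent pair is estimated
#' between the original slices — equivalent to matching against the
#' aligned predecessor but without resampling the reference a second
#' time — then composed cumulatively and applied once per slice. Color
#' stacks are registered on their NTSC luminance; the transform is applied
#' to all channels identically. Per-slice manual overrides replace
#' estimation for those slices (the "corrected manually" escape hatch of
#' the classical workflow, driven here by the reported residuals).
#'
#' @param stack An `image_stack` with at least 2 slices.
#' @param fill_value Out-of-bounds fill; default 0 for inverted stacks,
#'   255 for non-inverted ones.
#' @param search Search bounds, as in [register_pair()].
#' @param overrides Optional list: `overrides[[i]]` (1-based slice index) a
#'   [rigid_transform()] used as that slice's cumulative transform.
#' @return A list with `stack` (the aligned stack) and `result`, an
#'   `alignment_result` holding per-slice cumulative transforms and
#'   per-pair residual mean squared differences before/after.
#' @export
align_stack <- function(stack, fill_value = NULL,
                        search = list(tx = 15, ty = 15, theta = 10),
                        overrides = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  if (nz < 2) stop("align_stack() needs at least 2 slices")
  fill_value <- fill_value %||% if (stack$inverted) 0 else 255
  lum <- stack_luminance(stack)

  transforms <- vector("list", nz)
  transforms[[1]] <- rigid_transform(0, 0, 0)
  res_before <- res_after <- rep(NA_real_, nz - 1)
  out <- stack
  prev_lum <- lum[, , 1]
  for (i in 2:nz) {
    res_before[i - 1] <- mean((lum[, , i] - lum[, , i - 1])^2)
    if (!is.null(overrides) && length(overrides) >= i &&
        !is.null(overrides[[i]])) {
      tf <- overrides[[i]]
    } else {
      rel <- register_pair(lum[, , i - 1], lum[, , i], search = search)
      tf <- compose_transform(transforms[[i - 1]], rel)
    }
    transforms[[i]] <- tf
    out <- set_slice(out, i, resample_slice(get_slice(stack, i), tf,
                                            fill_value))
    q <- inverse_map(tf, nrow(prev_lum), ncol(prev_lum))
    new_lum <- bilinear_gather(lum[, , i], q$x, q$y, NA)
    res_after[i - 1] <- mean((prev_lum - new_lum)^2, na.rm = TRUE)
    new_lum[is.na(new_lum)] <- if (stack$inverted) 0 else 255
    prev_lum <- new_lum
  }
  result <- structure(
    list(transforms = transforms, residual_before = res_before,
         residual_after = res_after, fill_value = fill_value),
    class = "alignment_result"
  )
  list(stack = out, result = result)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("alignment_result:", length(x$transforms), "slices, fill",
      x$fill_value, "\n")
  cat(sprintf("  mean residual MSD before %.2f -> after %.2f\n",
              mean(x$residual_before), mean(x$residual_after)))
  invisible(x)
}

#' Serialize / import an alignment table
#'
#' The alignment result as a plain-text table (slice index, theta, tx, ty,
#' residuals before/after) that can be edited and re-imported as manual
#' overrides.
#'
#' @param result An `alignment_result`.
#' @param path Output TSV path.
#' @return `write_alignment()`: the path, invisibly. `read_alignment()`: a
#'   list of [rigid_transform()] suitable for `align_stack(overrides = )`.
#' @export
write_alignment <- function(result, path) {
  tab <- data.frame(
    slice = seq_along(result$transforms) - 1,
    theta = vapply(result$transforms, `[[`, numeric(1), "theta"),
    tx = vapply(result$transforms, `[[`, numeric(1), "tx"),
    ty = vapply(result$transforms, `[[`, numeric(1), "ty"),
    residual_before = c(NA, result$residual_before),
    residual_after = c(NA, result$residual_after)
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    rigid_transform(tab$theta[i], tab$tx[i], tab$ty[i])
  })
}
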