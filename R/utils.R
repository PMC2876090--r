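# Shared numeric conventions.
#
# All 8-bit arithmetic in the package follows one rule: evaluate in double
# precision, round to the nearest integer with ties away from zero, clamp to
# [0, 255]. Quantization happens once at operation boundaries; internal
# arithmetic stays in doubles.

#' Quantize to 8-bit
#'
#' Rounds double-precision values to the nearest integer (ties away from
#' zero) and clamps to the 8-bit range \[0, 255\]. This is the single
#' rounding rule used by every operation in the package.
#'
#' @param x Numeric vector or array.
#' @return Numeric object of the same shape with integer-valued entries in
#'   \[0, 255\].
#' @export
#' @examples
#' quantize8(c(-3, 127.5, 150.45, 300))
quantize8 <- function(x) {
  out <- pmin(255, pmax(0, trunc(x + 0.5 * sign(x))))
  dim(out) <- dim(x)
  out
}

#' NTSC luminance of RGB values
#'
#' The standard broadcast weighting `0.3 R + 0.59 G + 0.11 B` used throughout
#' the package for grayscale conversion, alpha-channel construction, and the
#' registration metric of color stacks. Returned in double precision;
#' quantize with [quantize8()] where an 8-bit result is needed.
#'
#' @param r,g,b Numeric vectors or arrays of equal shape, values in \[0, 255\].
#' @return Double-precision luminance, same shape as the inputs.
#' @export
#' @examples
#' ntsc_luminance(0, 255, 0) # 150.45
ntsc_luminance <- function(r, g, b) {
  0.3 * r + 0.59 * g + 0.11 * b
}

# Symmetric (edge-inclusive reflective) index vector for padding a dimension
# of length n by h on both sides. Requires h <= n.
reflect_idx <- function(n, h) {
  if (h > n) {
    stop("reflection pad (", h, ") exceeds axis extent (", n, ")")
  }
  c(rev(seq_len(h)), seq_len(n), n + 1 - seq_len(h))
}

# Sampled, truncated, normalized 1D Gaussian kernel of length k (odd).
gauss_kernel1d <- function(k, sigma) {
  stopifnot(k >= 1, sigma > 0)
  h <- (k - 1) / 2
  x <- seq(-h, h)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
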