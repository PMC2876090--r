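#' Construct an image stack
#'
#' The central volumetric object of the package: a z-ordered sequence of
#' equally-sized 8-bit slices with physical voxel spacing. Values are stored
#' as integer-valued doubles in \[0, 255\]; the channel count determines the
#' semantics (1 = GRAY, 3 = RGB, 4 = RGBA).
#'
#' The coordinate convention is x = column, y = row, z = slice index, all
#' 0-based in user-facing quantities (transforms, regions of interest), with
#' the image origin at the top-left. Internally the voxel data live in an
#' `H x W x C x Z` array.
#'
#' @param data Numeric array: `H x W x Z` (grayscale), or `H x W x C x Z`
#'   with `C` in `{1, 3, 4}`. Values must lie in \[0, 255\].
#' @param spacing Numeric length-3 vector `(sx, sy, sz)` in micrometers;
#'   `sz` is the section thickness. All entries must be positive.
#' @param inverted Logical; `TRUE` if voxel values are color-inverted
#'   relative to the original white-background micrographs.
#' @return An object of class `image_stack`.
#' @export
#' @examples
#' s <- image_stack(array(128, c(4, 4, 3)), spacing = c(1, 1, 2))
#' n_slices(s)
image_stack <- function(data, spacing = c(1, 1, 1), inverted = FALSE) {
  if (length(dim(data)) == 3) {
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  }
  if (length(dim(data)) != 4) {
    stop("`data` must be an H x W x Z or H x W x C x Z array")
  }
  storage.mode(data) <- "double"
  nc <- dim(data)[3]
  if (!nc %in% c(1L, 3L, 4L)) {
    stop("channel count must be 1 (GRAY), 3 (RGB) or 4 (RGBA), got ", nc)
  }
  if (anyNA(data) || min(data) < 0 || max(data) > 255) {
    stop("voxel values must lie in [0, 255] with no missing values")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive values (sx, sy, sz) in micrometers")
  }
  structure(
    list(
      data = data,
      spacing = c(sx = spacing[1], sy = spacing[2], sz = spacing[3]),
      semantics = c("GRAY", "RGB", "RGBA")[match(nc, c(1L, 3L, 4L))],
      inverted = isTRUE(inverted)
    ),
    class = "image_stack"
  )
}

#' @rdname image_stack
#' @param x An `image_stack`.
#' @export
n_slices <- function(x) dim(x$data)[4]

#' @rdname image_stack
#' @export
n_channels <- function(x) dim(x$data)[3]

#' @rdname image_stack
#' @export
stack_dims <- function(x) {
  d <- dim(x$data)
  c(height = d[1], width = d[2], channels = d[3], slices = d[4])
}

# One slice as an H x W x C array (C kept even when 1).
get_slice <- function(x, i) {
  s <- x$data[, , , i, drop = FALSE]
  dim(s) <- dim(s)[1:3]
  s
}

set_slice <- function(x, i, slice) {
  x$data[, , , i] <- slice
  x
}

# Replace voxel data, keeping metadata; re-derives semantics from channels.
with_data <- function(x, data, inverted = x$inverted) {
  image_stack(data, spacing = x$spacing, inverted = inverted)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- stack_dims(x)
  cat(sprintf(
    "image_stack: %d slice(s) of %d x %d, %s%s\n  spacing %.4g x %.4g x %.4g um\n",
    d["slices"], d["height"], d["width"], x$semantics,
    if (x$inverted) " (inverted)" else "",
    x$spacing["sx"], x$spacing["sy"], x$spacing["sz"]
  ))
  invisible(x)
}

#' Read a numbered section-image sequence as a stack
#'
#' Reads all files matched by a glob pattern (uncompressed 8-bit grayscale or
#' 24-bit RGB TIFF; PNG also accepted), orders them by zero-padded
#' lexicographic filename sort (or by trailing number with
#' `numeric_sort = TRUE`), and assembles them into an [image_stack()] with
#' the supplied physical spacing.
#'
#' @param path_pattern File glob (e.g. `"sections/slice_*.tif"`), or a
#'   character vector of explicit file paths.
#' @param spacing Physical voxel spacing `(sx, sy, sz)` in micrometers.
#' @param numeric_sort Order slices by the last integer in each filename
#'   instead of lexicographically.
#' @return An `image_stack`. Semantics are inferred from the channel count.
#' @export
read_stack <- function(path_pattern, spacing = c(1, 1, 1),
                       numeric_sort = FALSE) {
  files <- if (length(path_pattern) == 1 && !file.exists(path_pattern)) {
    Sys.glob(path_pattern)
  } else {
    path_pattern[file.exists(path_pattern)]
  }
  if (length(files) == 0) {
    stop("no files match '", paste(path_pattern, collapse = ", "), "'")
  }
  files <- if (numeric_sort) {
    nums <- suppressWarnings(as.numeric(sub(".*?(\\d+)\\D*$", "\\1",
                                            basename(files))))
    if (anyNA(nums)) stop("numeric_sort: some filenames carry no number")
    files[order(nums)]
  } else {
    sort(files)
  }
  slices <- lapply(files, read_slice_file)
  d <- lapply(slices, dim)
  ref <- d[[1]]
  bad <- which(vapply(d, function(di) !identical(di, ref), logical(1)))
  if (length(bad)) {
    stop(
      "dimension mismatch: '", basename(files[bad[1]]), "' is ",
      paste(d[[bad[1]]], collapse = "x"), " but '", basename(files[1]),
      "' is ", paste(ref, collapse = "x")
    )
  }
  arr <- array(0, c(ref[1], ref[2], ref[3], length(slices)))
  for (i in seq_along(slices)) arr[, , , i] <- slices[[i]]

  meta <- file.path(dirname(files[1]), "stack_meta.yml")
  inverted <- FALSE
  if (file.exists(meta)) {
    m <- yaml::read_yaml(meta)
    inverted <- isTRUE(m$inverted)
    if (missing(spacing) && !is.null(m$spacing)) {
      spacing <- as.numeric(m$spacing)
    }
  }
  image_stack(arr, spacing = spacing, inverted = inverted)
}

# Reads one TIFF or PNG as an H x W x C integer-valued array, C in {1, 3}.
read_slice_file <- function(path) {
  img <- tryCatch(
    {
      ext <- tolower(tools::file_ext(path))
      # suppressed: libtiff warns about RGBA samples written without an
      # ExtraSamples tag; the 4th channel is read back correctly
      if (ext == "png") png::readPNG(path) else {
        suppressWarnings(tiff::readTIFF(path))
      }
    },
    error = function(e) stop("cannot read '", path, "': ", conditionMessage(e))
  )
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3] == 2) img <- img[, , 1, drop = FALSE]      # gray + alpha
  quantize8(img * 255)
}

#' Write a stack as a numbered TIFF sequence
#'
#' Writes one uncompressed 8-bit TIFF per slice, named
#' `slice_000.tif, slice_001.tif, ...` (padding grows with the slice count),
#' plus a plain-text sidecar `stack_meta.yml` recording spacing, channel
#' semantics and the inverted flag, so that `read_stack()` reproduces the
#' stack bit-exactly.
#'
#' @param stack An `image_stack` with at least one slice.
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix, default `"slice_"`.
#' @return Invisibly, the vector of files written.
#' @export
write_stack <- function(stack, dir, prefix = "slice_") {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  if (nz == 0) stop("refusing to write an empty stack")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory '", dir, "'")
  width <- max(3L, nchar(as.character(nz - 1)))
  files <- file.path(dir, sprintf(
    paste0(prefix, "%0", width, "d.tif"), seq_len(nz) - 1
  ))
  for (i in seq_len(nz)) {
    s <- get_slice(stack, i)
    if (dim(s)[3] == 1) dim(s) <- dim(s)[1:2]
    tiff::writeTIFF(s / 255, files[i], bits.per.sample = 8L,
                    compression = "none")
  }
  meta <- list(
    spacing = as.numeric(stack$spacing),
    semantics = stack$semantics,
    inverted = stack$inverted,
    n_slices = nz
  )
  yaml::write_yaml(meta, file.path(dir, "stack_meta.yml"))
  invisible(files)
}

#' Convert an RGB stack to grayscale
#'
#' Applies the NTSC luminance weighting `gray = 0.3 R + 0.59 G + 0.11 B`
#' voxelwise, quantized by the package rounding rule. Spacing and the
#' inverted flag are preserved.
#'
#' @param stack An RGB `image_stack`.
#' @return A GRAY `image_stack`.
#' @export
to_grayscale <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$semantics != "RGB") {
    stop("to_grayscale() needs RGB semantics, got ", stack$semantics)
  }
  g <- quantize8(ntsc_luminance(
    stack$data[, , 1, , drop = FALSE],
    stack$data[, , 2, , drop = FALSE],
    stack$data[, , 3, , drop = FALSE]
  ))
  with_data(stack, g)
}

#' Summarize a stack
#'
#' Computes a `stack_report`: dimensions, spacing, the anisotropy ratio
#' (section thickness over largest in-plane pixel edge), channel semantics
#' and a value-histogram summary.
#'
#' @param stack An `image_stack`.
#' @return A `stack_report` list with a print method.
#' @export
stack_report <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack_dims(stack)
  v <- stack$data
  structure(
    list(
      n_slices = unname(d["slices"]),
      dims = d,
      spacing = stack$spacing,
      anisotropy_ratio = unname(stack$spacing["sz"] /
                                  max(stack$spacing["sx"], stack$spacing["sy"])),
      semantics = stack$semantics,
      inverted = stack$inverted,
      value_summary = c(
        min = min(v), q25 = unname(stats::quantile(v, 0.25)),
        median = stats::median(v),
        q75 = unname(stats::quantile(v, 0.75)), max = max(v),
        mean = mean(v)
      )
    ),
    class = "stack_report"
  )
}

#' @export
print.stack_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "stack_report\n  slices: %d   dims: %d x %d x %d ch\n",
      "  spacing: %.4g x %.4g x %.4g um   anisotropy sz/max(sx,sy): %.3g\n",
      "  semantics: %s%s\n  values: min %d, median %g, max %d, mean %.2f\n"
    ),
    x$n_slices, x$dims["height"], x$dims["width"], x$dims["channels"],
    x$spacing["sx"], x$spacing["sy"], x$spacing["sz"], x$anisotropy_ratio,
    x$semantics, if (x$inverted) " (inverted)" else "",
    x$value_summary["min"], x$value_summary["median"], x$value_summary["max"],
    x$value_summary["mean"]
  ))
  invisible(x)
}
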