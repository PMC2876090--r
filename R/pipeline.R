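# End-to-end orchestration of the two rendering pathways: grayscale
# (read -> edit -> invert -> align -> [filter] -> colormap -> render) and
# color (read -> edit -> invert -> align -> per-channel filter with
# luminance alpha -> transfer -> render + re-inverted snapshot). Every
# intermediate stack, the alignment table, and a manifest are written to
# the output directory.

#' Pipeline configuration
#'
#' @param input Input file glob for [read_stack()], or an `image_stack`
#'   supplied directly.
#' @param spacing Voxel spacing `(sx, sy, sz)` in micrometers.
#' @param pathway `"grayscale"` or `"color"`.
#' @param preset Embedding preset selecting the filter defaults:
#'   `"resin"` (no filtering for grayscale; modest 3x3x3 Gaussian option),
#'   `"paraffin"` (6x6x6 Gaussian then edge-preserving smoothing), or
#'   `"none"`.
#' @param normalize,equalize,align Logical stage switches.
#' @param despeckle_radius Median despeckle radius in px, or 0 for off.
#' @param background_percentile White-point percentile for preprocessing.
#' @param tf A [transfer_function()] applied to the alpha channel
#'   (color pathway) or paired with the colormap (grayscale pathway).
#' @param map A [colormap()] for the grayscale pathway.
#' @param view A [view_spec()] for the final rendering.
#' @param region Optional [roi()].
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed feeds any phantom generation driven from a
#'   config).
#' @param max_anisotropy Anisotropy bound checked before processing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, spacing = c(1, 1, 1),
                            pathway = c("color", "grayscale"),
                            preset = c("paraffin", "resin", "none"),
                            normalize = TRUE, equalize = TRUE, align = TRUE,
                            despeckle_radius = 0,
                            background_percentile = 0.95,
                            tf = transfer_function("linear_gamma", gamma = 1),
                            map = colormap("glow"),
                            view = view_spec(), region = NULL,
                            out_dir = tempfile("sectionvr_run_"),
                            seed = 1L, max_anisotropy = 3) {
  structure(
    list(input = input, spacing = spacing, pathway = match.arg(pathway),
         preset = match.arg(preset), normalize = normalize,
         equalize = equalize, align = align,
         despeckle_radius = despeckle_radius,
         background_percentile = background_percentile,
         tf = tf, map = map, view = view, region = region,
         out_dir = out_dir, seed = as.integer(seed),
         max_anisotropy = max_anisotropy),
    class = "pipeline_config"
  )
}

#' Run the full rendering pipeline
#'
#' Executes the configured stages in order, writing every intermediate
#' stack, the alignment table, final snapshot(s) and a manifest to
#' `config$out_dir`. Stage order: read, background normalization, stain
#' equalization, (despeckle), inversion, alignment, filtering per preset,
#' alpha/colormap construction, transfer, rendering. For the color pathway
#' a re-inverted snapshot is written alongside the direct one.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the final `stack`, `snapshot`(s),
#'   `alignment` result and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline_log.txt")
  logf <- function(...) {
    cat(paste0(format(Sys.time(), "%H:%M:%S"), "  ", ..., "\n"),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  manifest <- list(
    package = as.character(utils::packageVersion("sectionvr")),
    pathway = config$pathway, preset = config$preset, seed = config$seed
  )

  stk <- stage("read", {
    if (inherits(config$input, "image_stack")) config$input
    else read_stack(config$input, spacing = config$spacing)
  })
  logf("read: ", n_slices(stk), " slices ", stk$semantics)
  aniso <- check_anisotropy(stk$spacing, config$max_anisotropy)
  manifest$anisotropy_ratio <- aniso$ratio
  if (!aniso$pass) {
    warning(sprintf(
      "anisotropy ratio %.2f exceeds %.2f; consider thinner sections or coarser pixels",
      aniso$ratio, config$max_anisotropy
    ))
  }

  if (config$normalize) {
    stk <- stage("normalize", normalize_background(
      stk, config$background_percentile))
    logf("normalize: white points estimated at p",
         config$background_percentile)
  }
  if (config$equalize && n_slices(stk) >= 2) {
    stk <- stage("equalize", equalize_slices(
      stk, config$background_percentile))
    gains <- attr(stk, "gains")
    utils::write.table(
      data.frame(slice = seq_along(gains) - 1, gain = gains),
      file.path(config$out_dir, "equalize_gains.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    logf("equalize: gains in [", round(min(gains), 3), ", ",
         round(max(gains), 3), "]")
  }
  if (config$despeckle_radius > 0) {
    stk <- stage("despeckle", despeckle(stk, config$despeckle_radius))
    logf("despeckle: radius ", config$despeckle_radius)
  }

  stk <- stage("invert", invert_stack(stk))
  write_stack(stk, file.path(config$out_dir, "10_inverted"))

  alignment <- NULL
  if (config$align && n_slices(stk) >= 2) {
    al <- stage("align", align_stack(stk))
    stk <- al$stack
    alignment <- al$result
    write_alignment(alignment, file.path(config$out_dir, "alignment.tsv"))
    write_stack(stk, file.path(config$out_dir, "20_aligned"))
    logf("align: mean residual ", round(mean(alignment$residual_before), 2),
         " -> ", round(mean(alignment$residual_after), 2))
  }

  filters <- filter_preset(config$preset)
  if (config$pathway == "grayscale") {
    if (stk$semantics != "GRAY") stk <- stage("grayscale", to_grayscale(stk))
    if (length(filters) == 0) {
      manifest$filter <- "none"
      logf("filter: none (", config$preset, " preset)")
    } else {
      for (p in filters) {
        stk <- stage("filter", if (inherits(p, "gauss_params")) {
          gaussian_smooth(stk, p)
        } else {
          edge_preserving_smooth(stk, p)
        })
      }
      manifest$filter <- paste(vapply(filters, function(p) class(p)[1],
                                      character(1)), collapse = " + ")
      write_stack(stk, file.path(config$out_dir, "30_filtered"))
      logf("filter: ", manifest$filter)
    }
    rgba <- stage("colormap", apply_colormap(stk, config$map, config$tf))
    manifest$colormap <- config$map$name
  } else {
    if (length(filters) == 0) {
      manifest$filter <- "none"
      rgba <- stage("alpha", luminance_alpha(stk))
      logf("filter: none; alpha from luminance")
    } else {
      for (p in filters) {
        stk <- stage("filter_rgb", filter_rgb(stk, p))
        # filter_rgb returns RGBA; keep filtering on the RGB channels
      }
      manifest$filter <- paste0("per-channel ",
                                paste(vapply(filters, function(p) {
                                  class(p)[1]
                                }, character(1)), collapse = " + "),
                                "; alpha recomputed at recombine")
      rgba <- stk
      write_stack(rgba, file.path(config$out_dir, "30_filtered"))
      logf("filter: ", manifest$filter)
    }
    rgba <- stage("transfer", apply_transfer(rgba, config$tf))
  }

  snap <- stage("render", render_stack(rgba, config$view, config$region))
  write_snapshot(snap, file.path(config$out_dir, "snapshot.png"))
  out <- list(stack = rgba, snapshot = snap, alignment = alignment,
              out_dir = config$out_dir)
  if (config$pathway == "color") {
    re <- reinvert_snapshot(snap)
    write_snapshot(re, file.path(config$out_dir, "snapshot_reinverted.png"))
    out$snapshot_reinverted <- re
  }
  logf("render: ", paste(dim(snap$image)[1:2], collapse = " x "), " px")

  manifest$config_hash <- config_hash(config)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yml"))
  invisible(out)
}

# Stable hash of the configuration (md5 of its deparsed form).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "input")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from a YAML file
#'
#' Plain-text schema mirroring the arguments of [pipeline_config()];
#' transfer functions are given as `tf: {kind: ..., gamma/t/x: ...}` and
#' the view as `view: {direction: [...], up: [...], ...}`.
#'
#' @param path YAML config path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tf <- if (is.null(y$tf)) transfer_function("linear_gamma", gamma = 1) else {
    do.call(transfer_function, y$tf)
  }
  vw <- if (is.null(y$view)) view_spec() else do.call(view_spec, y$view)
  map <- if (is.null(y$colormap)) colormap("glow") else {
    do.call(colormap, y$colormap)
  }
  pipeline_config(
    input = y$input, spacing = y$spacing %||% c(1, 1, 1),
    pathway = y$pathway %||% "color", preset = y$preset %||% "paraffin",
    normalize = y$normalize %||% TRUE, equalize = y$equalize %||% TRUE,
    align = y$align %||% TRUE,
    despeckle_radius = y$despeckle_radius %||% 0,
    background_percentile = y$background_percentile %||% 0.95,
    tf = tf, map = map, view = vw,
    out_dir = y$out_dir %||% tempfile("sectionvr_run_"),
    seed = y$seed %||% 1L
  )
}
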