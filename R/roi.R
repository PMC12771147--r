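#' Build a region-of-interest layout table
#'
#' A layout is a tibble with one row per square ROI: `label`, `row0`, `col0`
#' and `edge`. Coordinates are 0-based with a top-left origin; the window is
#' half-open, covering pixel rows `[row0, row0 + edge)` and columns
#' `[col0, col0 + edge)`. The 45-pixel default edge matches the square
#' selection used on cuvette images in the acquisition chamber.
#'
#' @param label Character vector of ROI labels (e.g. `"blank"`, `"std_1"`).
#' @param row0,col0 Integer vectors of top-left pixel coordinates (0-based).
#' @param edge ROI edge length in pixels; recycled. Default 45.
#' @return A tibble with columns `label`, `row0`, `col0`, `edge`.
#' @export
roi_layout <- function(label, row0, col0, edge = 45L) {
  out <- tibble(label = as.character(label),
                row0 = as.integer(row0),
                col0 = as.integer(col0),
                edge = as.integer(edge))
  if (any(out$edge < 1L)) {
    abort("ROI `edge` must be at least 1 pixel.",
          class = "chromaquant_roi_error")
  }
  if (anyDuplicated(out$label)) {
    abort("ROI labels must be unique within a layout.",
          class = "chromaquant_roi_error")
  }
  out
}

#' Regular grid layout for a multi-cuvette chamber
#'
#' Convenience constructor for the common acquisition geometry: a 3 x 3 grid
#' of cuvettes photographed in one frame (blank + six standards + samples).
#' Cells are laid out row-major; each ROI is offset `margin` pixels into its
#' cell.
#'
#' @param labels Character vector of cell labels, row-major; its length sets
#'   how many of the `nrow * ncol` cells are used.
#' @param nrow,ncol Grid dimensions. Default 3 x 3.
#' @param edge ROI edge in pixels (default 45).
#' @param margin Pixels between the cell border and the ROI (default 8).
#' @return A tibble as in [roi_layout()].
#' @export
roi_grid <- function(labels, nrow = 3L, ncol = 3L, edge = 45L, margin = 8L) {
  if (length(labels) > nrow * ncol) {
    abort("More labels than grid cells.", class = "chromaquant_roi_error")
  }
  cell <- edge + 2L * margin
  idx <- seq_along(labels) - 1L
  roi_layout(label = labels,
             row0 = (idx %/% ncol) * cell + margin,
             col0 = (idx %% ncol) * cell + margin,
             edge = edge)
}

#' Read / write an ROI layout file
#'
#' Layouts are exchanged as JSON or YAML: a list of records with fields
#' `label`, `row0`, `col0` and optional `edge` (default 45).
#'
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return For `read_roi_layout()`, a layout tibble; for `write_roi_layout()`,
#'   `path` invisibly.
#' @export
read_roi_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  recs <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yml = ,
    yaml = {
      lst <- yaml::read_yaml(path)
      dplyr::bind_rows(lapply(lst, tibble::as_tibble_row))
    },
    abort("ROI layout files must be JSON or YAML.",
          class = "chromaquant_io_error")
  )
  recs <- as_tibble(recs)
  if (!all(c("label", "row0", "col0") %in% names(recs))) {
    abort("Layout records need `label`, `row0` and `col0` fields.",
          class = "chromaquant_io_error")
  }
  if (is.null(recs$edge)) recs$edge <- 45L
  recs$edge[is.na(recs$edge)] <- 45L
  roi_layout(recs$label, recs$row0, recs$col0, recs$edge)
}

#' @rdname read_roi_layout
#' @param layout A layout tibble from [roi_layout()].
#' @export
write_roi_layout <- function(layout, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(layout, path, dataframe = "rows"),
    yml = ,
    yaml = yaml::write_yaml(
      lapply(seq_len(nrow(layout)), function(i) as.list(layout[i, ])), path),
    abort("ROI layout files must be JSON or YAML.",
          class = "chromaquant_io_error")
  )
  invisible(path)
}

#' Extract a square ROI patch from an image
#'
#' @param image An [rgb_image].
#' @param row0,col0 Top-left corner of the window, 0-based.
#' @param edge Window edge in pixels.
#' @param label Optional label used in error messages.
#' @return An `edge` x `edge` x 3 [rgb_image] patch.
#' @export
extract_roi <- function(image, row0, col0, edge = 45L, label = NULL) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image)
  if (edge < 1L || row0 < 0L || col0 < 0L ||
      row0 + edge > d[1] || col0 + edge > d[2]) {
    abort(sprintf(
      "ROI%s at (%d, %d) with edge %d exceeds the %d x %d image bounds.",
      if (is.null(label)) "" else paste0(" '", label, "'"),
      row0, col0, edge, d[1], d[2]),
      class = "chromaquant_bounds_error")
  }
  rgb_image(unclass(image)[(row0 + 1L):(row0 + edge),
                           (col0 + 1L):(col0 + edge), , drop = FALSE])
}

#' Per-channel intensity histogram of a patch
#'
#' Tallies pixel values into 256 bins per channel. Each channel's counts sum
#' to the patch pixel count, so histogram-derived statistics are exactly
#' consistent with pixel-level ones.
#'
#' @param patch An [rgb_image], typically from [extract_roi()].
#' @return A tibble with columns `channel` (`"R"`, `"G"`, `"B"`),
#'   `intensity` (0-255) and `count`.
#' @export
roi_histogram <- function(patch) {
  stopifnot(inherits(patch, "rgb_image"))
  counts <- vapply(1:3, function(ch) {
    tabulate(unclass(patch)[, , ch] + 1L, nbins = 256L)
  }, integer(256L))
  tibble(channel = rep(c("R", "G", "B"), each = 256L),
         intensity = rep(0:255, times = 3L),
         count = as.integer(counts))
}

#' Mean channel intensities of a patch
#'
#' The ROI is summarised by the arithmetic mean of its pixels per channel —
#' linear in pixel values, which keeps the downstream least-squares
#' calibration assumptions intact.
#'
#' @param patch An [rgb_image].
#' @param label Optional label carried into the result.
#' @return A one-row tibble with `label`, `mean_r`, `mean_g`, `mean_b`.
#' @export
channel_means <- function(patch, label = NA_character_) {
  stopifnot(inherits(patch, "rgb_image"))
  px <- unclass(patch)
  tibble(label = label,
         mean_r = mean(px[, , 1]),
         mean_g = mean(px[, , 2]),
         mean_b = mean(px[, , 3]))
}

#' Blank-referenced reflectance signals
#'
#' Converts mean channel intensities into reflectance ratios against the
#' blank ROI of the same image: `refl_ch = mean_ch(sample) / mean_ch(blank)`.
#' The blank's reflectance against itself is exactly (1, 1, 1); values above
#' 1 (sample brighter than blank) are legitimate and preserved. An optional
#' effective-absorbance transform `-log10(reflectance)` is available for
#' Beer-Lambert-style linearisation.
#'
#' @param signals A tibble with columns `label`, `mean_r`, `mean_g`,
#'   `mean_b` (one row per ROI), as produced by [extract_signals()] or
#'   [channel_means()].
#' @param blank_label Label of the blank row. Default `"blank"`.
#' @param absorbance If `TRUE`, also add `abs_r`, `abs_g`, `abs_b` columns
#'   with `-log10(refl)`. Default `FALSE`.
#' @return The input tibble with `refl_r`, `refl_g`, `refl_b` columns added.
#' @export
reflectance_signals <- function(signals, blank_label = "blank",
                                absorbance = FALSE) {
  if (!blank_label %in% signals$label) {
    abort(sprintf("No ROI labelled '%s' to use as the blank.", blank_label),
          class = "chromaquant_blank_error")
  }
  blank <- signals[signals$label == blank_label, ]
  bl <- c(blank$mean_r[1], blank$mean_g[1], blank$mean_b[1])
  if (any(bl <= 0)) {
    abort("Blank channel means must be strictly positive to define reflectance.",
          class = "chromaquant_blank_error")
  }
  out <- dplyr::mutate(signals,
                       refl_r = .data$mean_r / bl[1],
                       refl_g = .data$mean_g / bl[2],
                       refl_b = .data$mean_b / bl[3])
  if (absorbance) {
    out <- dplyr::mutate(out,
                         abs_r = -log10(.data$refl_r),
                         abs_g = -log10(.data$refl_g),
                         abs_b = -log10(.data$refl_b))
  }
  out
}

#' Extract colour signals for every ROI of a layout
#'
#' The single-image workflow: one photograph carries the blank, the
#' calibration standards and the unknown samples; this walks the layout,
#' averages each ROI and (if a blank is present) appends blank-referenced
#' reflectance ratios.
#'
#' @param image An [rgb_image].
#' @param layout ROI layout tibble ([roi_layout()], [roi_grid()] or
#'   [read_roi_layout()]).
#' @param blank_label Label of the blank ROI, or `NULL` to skip reflectance
#'   referencing. Default `"blank"`.
#' @param absorbance Passed to [reflectance_signals()].
#' @return A tibble with one row per ROI: `label`, `mean_r`, `mean_g`,
#'   `mean_b` and, when referenced, `refl_r`, `refl_g`, `refl_b`.
#' @examples
#' scene <- render_scene(default_calibration_scene(seed = 1))
#' extract_signals(scene$image, scene$layout)
#' @export
extract_signals <- function(image, layout, blank_label = "blank",
                            absorbance = FALSE) {
  sig <- purrr::pmap_dfr(layout, function(label, row0, col0, edge, ...) {
    channel_means(extract_roi(image, row0, col0, edge, label), label = label)
  })
  if (!is.null(blank_label)) {
    sig <- reflectance_signals(sig, blank_label, absorbance = absorbance)
  }
  sig
}
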