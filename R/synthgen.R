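#' Beer-Lambert colour model for a red dye in solution
#'
#' Maps concentration to the mean RGB colour of a back-lit cuvette. Each
#' channel is attenuated exponentially,
#' `mean_ch(c) = blank_ch * 10^(-k_ch * path_scale * c)`, the image-domain
#' analogue of Beer-Lambert absorption. For a red dye absorbing near 504 nm
#' the green channel is attenuated hardest, so the defaults order the
#' apparent absorptivities `k_g > k_b > k_r`; over the working range
#' 2e-4 to 2e-2 mg/mL this spans roughly 1.2 decades of green transmittance
#' while the red channel barely moves — the qualitative structure of the
#' real system. The k values are synthesis parameters, not measured dye
#' properties.
#'
#' @param blank_rgb Mean RGB of the blank cuvette, near-white by default
#'   `c(245, 243, 240)`.
#' @param k Per-channel apparent absorptivity (mL/mg), named `r`, `g`, `b`.
#' @param path_scale Dimensionless optical-path multiplier (default 1).
#' @return A `dye_color_model` list.
#' @export
dye_color_model <- function(blank_rgb = c(245, 243, 240),
                            k = c(r = 6, g = 60, b = 18),
                            path_scale = 1) {
  stopifnot(length(blank_rgb) == 3, all(blank_rgb >= 0 & blank_rgb <= 255),
            length(k) == 3, all(k >= 0), path_scale > 0)
  structure(list(blank_rgb = unname(blank_rgb), k = unname(k),
                 path_scale = path_scale),
            class = "dye_color_model")
}

#' Noiseless cuvette colour at given concentrations
#'
#' @param model A [dye_color_model()].
#' @param conc Concentration vector (mg/mL), non-negative.
#' @return A tibble with `conc`, `mean_r`, `mean_g`, `mean_b` (real-valued,
#'   in \[0, 255\]).
#' @export
dye_channel_means <- function(model, conc) {
  stopifnot(inherits(model, "dye_color_model"), all(conc >= 0))
  tr <- outer(conc, model$k * model$path_scale,
              function(c, k) 10^(-k * c))
  tibble(conc = conc,
         mean_r = model$blank_rgb[1] * tr[, 1],
         mean_g = model$blank_rgb[2] * tr[, 2],
         mean_b = model$blank_rgb[3] * tr[, 3])
}

#' The six standard calibration levels
#'
#' The working design spans 2.00e-4 to 2.00e-2 mg/mL over six levels,
#' measured in triplicate in practice.
#'
#' @return Numeric vector of six concentrations (mg/mL).
#' @export
calibration_levels <- function() {
  c(2.00e-4, 5.00e-4, 1.00e-3, 5.00e-3, 1.00e-2, 2.00e-2)
}

#' Specify a synthetic cuvette-grid scene
#'
#' Describes the scene to render: a row-major grid of labelled cuvettes with
#' known concentrations, the ROI edge, per-pixel Gaussian noise and an
#' explicit seed. [default_calibration_scene()] builds the standard 3 x 3
#' layout (blank + six standards + two unknowns) mirroring a nine-cuvette
#' chamber photographed in one frame.
#'
#' @param assignments Tibble with columns `label` and `conc` (mg/mL),
#'   row-major grid order.
#' @param nrow,ncol Grid dimensions (default 3 x 3).
#' @param roi_edge ROI edge in pixels (default 45).
#' @param margin Pixels between cell border and ROI; must be at least 4 so
#'   cuvette patches (ROI + 3 px apron) never overlap (default 8).
#' @param noise_sd Gaussian pixel-noise SD in channel units (default 2).
#' @param seed Integer seed making the render deterministic.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(assignments, nrow = 3L, ncol = 3L, roi_edge = 45L,
                       margin = 8L, noise_sd = 2, seed = 1L) {
  stopifnot(is.data.frame(assignments),
            all(c("label", "conc") %in% names(assignments)),
            all(assignments$conc >= 0), noise_sd >= 0)
  if (nrow(assignments) > nrow * ncol) {
    abort("More cuvettes than grid cells.", class = "chromaquant_roi_error")
  }
  if (margin < 4L) {
    abort("`margin` below 4 px makes adjacent cuvette patches overlap.",
          class = "chromaquant_roi_error")
  }
  structure(list(assignments = as_tibble(assignments),
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 roi_edge = as.integer(roi_edge),
                 margin = as.integer(margin),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @param unknowns Named concentrations for the unknown cuvettes; defaults
#'   sit inside the calibration range (interpolation regime).
#' @export
default_calibration_scene <- function(unknowns = c(unknown_1 = 8.0e-4,
                                                   unknown_2 = 8.0e-3),
                                      roi_edge = 45L, noise_sd = 2,
                                      seed = 1L) {
  levels <- calibration_levels()
  assignments <- tibble(
    label = c("blank", paste0("std_", seq_along(levels)), names(unknowns)),
    conc = c(0, levels, unname(unknowns)))
  scene_spec(assignments, roi_edge = roi_edge, noise_sd = noise_sd,
             seed = seed)
}

#' Render a synthetic cuvette-grid image with known ground truth
#'
#' Draws each cuvette as a flat patch coloured by the Beer-Lambert model
#' (the patch extends 3 px beyond the ROI on every side, so ROI extraction
#' sees pure cuvette pixels), adds i.i.d. Gaussian noise per pixel per
#' channel, then rounds and clips to the 8-bit range. Rendering is
#' deterministic under the spec's seed.
#'
#' @param spec A [scene_spec()].
#' @param model A [dye_color_model()]; defaults to the standard red-dye
#'   model.
#' @param background Background RGB (default dark grey `c(40, 40, 40)`).
#' @return A list of class `dia_scene`: `image` (an [rgb_image]), `layout`
#'   (the ROI layout tibble) and `truth` (label, concentration and the
#'   noiseless mean RGB of every cuvette).
#' @examples
#' scene <- render_scene(default_calibration_scene(seed = 42))
#' scene$truth
#' @export
render_scene <- function(spec, model = dye_color_model(),
                         background = c(40, 40, 40)) {
  stopifnot(inherits(spec, "scene_spec"), inherits(model, "dye_color_model"))
  layout <- roi_grid(spec$assignments$label, nrow = spec$nrow,
                     ncol = spec$ncol, edge = spec$roi_edge,
                     margin = spec$margin)
  cell <- spec$roi_edge + 2L * spec$margin
  h <- spec$nrow * cell
  w <- spec$ncol * cell
  truth <- dye_channel_means(model, spec$assignments$conc)
  truth <- dplyr::bind_cols(tibble(label = spec$assignments$label), truth)

  img <- array(rep(background, each = h * w), dim = c(h, w, 3))
  pad <- 3L
  for (i in seq_len(nrow(layout))) {
    rows <- (layout$row0[i] - pad + 1L):(layout$row0[i] + layout$edge[i] + pad)
    cols <- (layout$col0[i] - pad + 1L):(layout$col0[i] + layout$edge[i] + pad)
    for (ch in 1:3) {
      img[rows, cols, ch] <- truth[[c("mean_r", "mean_g", "mean_b")[ch]]][i]
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + withr::with_seed(spec$seed,
                                  array(rnorm(length(img), 0, spec$noise_sd),
                                        dim = dim(img)))
  }
  img <- pmin(pmax(round(img), 0), 255)
  structure(list(image = rgb_image(img), layout = layout, truth = truth),
            class = "dia_scene")
}

#' Simulate replicate measurements with a target coefficient of variation
#'
#' Gaussian replicates with mean `true_mean` and SD `true_mean * cv_pct /
#' 100`, deterministic under `seed`. Feeds the recovery, precision and
#' paired-t machinery in tests and examples.
#'
#' @param true_mean True mean of the measurement.
#' @param cv_pct Coefficient of variation in percent (>= 0).
#' @param n Number of replicates (>= 2).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_replicates <- function(true_mean, cv_pct, n, seed = 1L) {
  stopifnot(cv_pct >= 0, n >= 2)
  withr::with_seed(seed, rnorm(n, true_mean, abs(true_mean) * cv_pct / 100))
}
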