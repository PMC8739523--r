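# Synthetic layered-OCT B-scan phantoms.
#
# The phantom reproduces the structural properties a joint layer + lesion
# segmenter exploits -- a stack of 7 ordered, smoothly undulating bands
# (NFL, GCL, IPL, INL, OPL, ONL, OPSL+RPE) over a dark background,
# multiplicative speckle, and an optional bright-ish CNV lesion seated at
# the OPSL+RPE band that lifts the overlying boundaries -- not OCT physics.
# Class ids: 0 background, 1..7 the layers in anatomical order, 8 CNV.

#' Class labels of the phantom scheme
#' @return Character vector of the 9 class names, in label order 0..8.
#' @export
class_scheme <- function() {
  c("background", "NFL", "GCL", "IPL", "INL", "OPL", "ONL", "OPSL+RPE", "CNV")
}

# per-layer thickness ranges in pixels at a 128-px-tall reference scan;
# scaled linearly with the configured height
.ref_thickness <- rbind(
  NFL = c(6, 10), GCL = c(8, 12), IPL = c(8, 12), INL = c(6, 10),
  OPL = c(5, 8), ONL = c(12, 18), `OPSL+RPE` = c(8, 12)
)

#' Phantom generator configuration
#'
#' @param width,height image extents in pixels (defaults 256 x 128; both
#'   kept divisible by 32 so phantoms feed the network directly).
#' @param thickness_range 7 x 2 matrix of per-layer thickness ranges in
#'   pixels (rows in anatomical order); default scales a 128-px reference
#'   plan to `height`.
#' @param intensity_mean mean gray level (0..255) per class, length 9.
#' @param speckle_strength standard deviation of the unit-mean
#'   multiplicative speckle factor (0 disables noise).
#' @param cnv_probability probability that a sample carries a lesion.
#' @param cnv_radius_range lesion radius interval in pixels.
#' @param cnv_lift maximum upward displacement (pixels) of the boundaries
#'   above a lesion.
#' @param seed integer seed used by [generate_dataset()].
#' @return A `dw_phantom_config` list.
#' @export
phantom_config <- function(width = 256L, height = 128L,
                           thickness_range = NULL,
                           intensity_mean = c(15, 200, 70, 150, 45,
                                              170, 95, 220, 120),
                           speckle_strength = 0.12,
                           cnv_probability = 0.5,
                           cnv_radius_range = c(6, 14),
                           cnv_lift = 10,
                           seed = 1L) {
  if (is.null(thickness_range)) {
    thickness_range <- .ref_thickness * height / 128
  }
  thickness_range <- as.matrix(thickness_range)
  stopifnot(nrow(thickness_range) == 7L, ncol(thickness_range) == 2L,
            length(intensity_mean) == 9L, speckle_strength >= 0,
            cnv_probability >= 0, cnv_probability <= 1,
            length(cnv_radius_range) == 2L, cnv_lift >= 0)
  if (any(thickness_range[, 1] < 1)) stop("thickness minima must be >= 1")
  if (0.25 * height + sum(thickness_range[, 2]) >= height) {
    stop("total maximum thickness too large for the image height")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    thickness_range = thickness_range,
    intensity_mean = intensity_mean,
    speckle_strength = speckle_strength,
    cnv_probability = cnv_probability,
    cnv_radius_range = cnv_radius_range,
    cnv_lift = cnv_lift,
    seed = as.integer(seed)
  ), class = "dw_phantom_config")
}

# smooth low-frequency curve over x = 1..W: a1 sin + a2 sin(2f) with random
# phases; zero mean
smooth_curve <- function(w, amplitude) {
  x <- seq_len(w) / w
  amplitude * (sin(2 * pi * x + stats::runif(1, 0, 2 * pi)) +
                 0.5 * sin(4 * pi * x + stats::runif(1, 0, 2 * pi))) / 1.5
}

#' Sample the 8 layer boundary curves of one phantom
#'
#' Boundary `b` (rows of the returned matrix) is the real-valued depth of
#' the top of layer `b` (`b = 1..7`) and of the bottom of the last layer
#' (`b = 8`), per image column.  Curves are smooth, strictly ordered in
#' depth, and per-layer thicknesses stay inside the configured ranges.
#'
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param cfg a `dw_phantom_config`.
#' @return 8 x width numeric matrix of boundary depths (pixels).
#' @export
sample_boundaries <- function(cfg) {
  w <- cfg$width; h <- cfg$height
  b <- matrix(0, 8L, w)
  ilm_base <- stats::runif(1, 0.10, 0.18) * h
  b[1, ] <- ilm_base + smooth_curve(w, stats::runif(1, 0.01, 0.03) * h)
  b[1, ] <- pmax(b[1, ], 1)
  for (l in 1:7) {
    lo <- cfg$thickness_range[l, 1]; hi <- cfg$thickness_range[l, 2]
    amp <- stats::runif(1, 0, 0.25 * (hi - lo))
    base <- stats::runif(1, lo + amp, hi - amp)
    b[l + 1L, ] <- b[l, ] + base + smooth_curve(w, amp)
  }
  if (any(b[8, ] >= h)) stop("sampled retina exceeds the image height")
  b
}

#' Implant a CNV lesion and deform the overlying boundaries
#'
#' With probability `cfg$cnv_probability` a circular lesion of radius drawn
#' from `cfg$cnv_radius_range` is seated at the OPSL+RPE band; all
#' boundaries above it are lifted upward by up to `cfg$cnv_lift` pixels
#' with a Gaussian falloff in the column distance from the lesion center,
#' which preserves their depth ordering.  The lesion never extends above
#' the inner limiting membrane.
#'
#' @param boundaries 8 x width matrix from [sample_boundaries()].
#' @param cfg a `dw_phantom_config`.
#' @return List with `boundaries` (possibly deformed), `lesion` (logical
#'   height x width mask) and `has_cnv`.
#' @export
implant_cnv <- function(boundaries, cfg) {
  w <- cfg$width; h <- cfg$height
  empty <- matrix(FALSE, h, w)
  if (stats::runif(1) >= cfg$cnv_probability) {
    return(list(boundaries = boundaries, lesion = empty, has_cnv = FALSE))
  }
  r <- stats::runif(1, cfg$cnv_radius_range[1], cfg$cnv_radius_range[2])
  if (2 * r >= h) stop("lesion radius exceeds the image depth")
  cx <- stats::runif(1, 0.2 * w, 0.8 * w)
  # lift the boundaries above the lesion (Gaussian decay along columns)
  lift_max <- min(cfg$cnv_lift, min(boundaries[1, ]) - 1)
  lift <- lift_max * exp(-((seq_len(w) - cx)^2) / (2 * r^2))
  deformed <- boundaries
  for (l in 1:7) deformed[l, ] <- boundaries[l, ] - lift
  cxi <- round(cx)
  cy <- (deformed[7, cxi] + deformed[8, cxi]) / 2
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rows <- matrix(seq_len(h), h, w)
  inside <- ((cols - cx) / r)^2 + ((rows - cy) / r)^2 <= 1
  ilm <- matrix(deformed[1, ], h, w, byrow = TRUE)
  inside <- inside & (rows > ilm)
  list(boundaries = deformed, lesion = inside, has_cnv = any(inside))
}

#' Render a phantom image and label mask from its geometry
#'
#' Pixels take the mean intensity of their class, multiplied by unit-mean
#' gamma speckle with standard deviation `cfg$speckle_strength`, rounded
#' and clipped to 0..255.  Lesion pixels override layer labels with
#' class 8.
#'
#' @param boundaries 8 x width boundary matrix.
#' @param lesion logical height x width lesion mask (or `NULL`).
#' @param cfg a `dw_phantom_config`.
#' @return List with `image` (integer matrix, 0..255), `mask` (integer
#'   matrix, labels 0..8), `has_cnv`, `cnv_pixel_count`.
#' @export
render_phantom <- function(boundaries, lesion, cfg) {
  w <- cfg$width; h <- cfg$height
  mask <- matrix(0L, h, w)
  rows <- seq_len(h) - 0.5  # pixel centers
  for (x in seq_len(w)) {
    fi <- findInterval(rows, boundaries[, x])
    fi[fi > 7L] <- 0L
    mask[, x] <- fi
  }
  if (!is.null(lesion) && any(lesion)) mask[lesion] <- 8L
  img <- matrix(cfg$intensity_mean[mask + 1L], h, w)
  if (cfg$speckle_strength > 0) {
    k <- 1 / cfg$speckle_strength^2
    img <- img * matrix(stats::rgamma(h * w, shape = k, rate = k), h, w)
  }
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), h, w)
  list(image = img, mask = mask, has_cnv = any(mask == 8L),
       cnv_pixel_count = sum(mask == 8L))
}

#' Draw one complete phantom sample
#'
#' Composes [sample_boundaries()], [implant_cnv()] and [render_phantom()]
#' using the current RNG state.
#'
#' @param cfg a `dw_phantom_config`.
#' @param volume_id identifier attached to the sample.
#' @return A `dw_phantom_sample` list: `image`, `mask`, `volume_id`,
#'   `has_cnv`, `cnv_pixel_count`.
#' @export
phantom_sample <- function(cfg, volume_id = "vol001") {
  b <- sample_boundaries(cfg)
  lz <- implant_cnv(b, cfg)
  rendered <- render_phantom(lz$boundaries, lz$lesion, cfg)
  structure(c(rendered[c("image", "mask")],
              list(volume_id = volume_id,
                   has_cnv = rendered$has_cnv,
                   cnv_pixel_count = rendered$cnv_pixel_count)),
            class = "dw_phantom_sample")
}

#' Generate a phantom dataset on disk
#'
#' Writes per-volume subdirectories of 8-bit grayscale image PNGs and
#' single-channel indexed mask PNGs, plus a `manifest.csv` listing
#' `(image_path, mask_path, volume_id, has_cnv)` with paths relative to
#' `out_dir`.  Lesion presence is decided per volume (all slices of a CNV
#' volume carry a lesion), mimicking grouped clinical volumes.  Fully
#' reproducible from `seed`.
#'
#' @param cfg a `dw_phantom_config`.
#' @param n_volumes number of volumes.
#' @param slices_per_volume integer interval `c(min, max)` of slices per
#'   volume.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed (default `cfg$seed`).
#' @return The manifest `data.frame`, invisibly.
#' @export
generate_dataset <- function(cfg, n_volumes, slices_per_volume = c(8L, 16L),
                             out_dir, seed = cfg$seed) {
  stopifnot(n_volumes >= 1L, length(slices_per_volume) == 2L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  rows <- list()
  for (v in seq_len(n_volumes)) {
    vid <- sprintf("vol%03d", v)
    vdir <- file.path(out_dir, vid)
    dir.create(vdir, showWarnings = FALSE)
    vol_cnv <- stats::runif(1) < cfg$cnv_probability
    cfg_v <- cfg
    cfg_v$cnv_probability <- as.numeric(vol_cnv)
    slice_choices <- slices_per_volume[1]:slices_per_volume[2]
    n_slices <- if (length(slice_choices) == 1L) slice_choices
                else sample(slice_choices, 1L)
    for (s in seq_len(n_slices)) {
      smp <- phantom_sample(cfg_v, volume_id = vid)
      ipath <- file.path(vid, sprintf("img_%03d.png", s))
      mpath <- file.path(vid, sprintf("mask_%03d.png", s))
      png::writePNG(smp$image / 255, file.path(out_dir, ipath))
      png::writePNG(smp$mask / 255, file.path(out_dir, mpath))
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = ipath, mask_path = mpath, volume_id = vid,
        has_cnv = smp$has_cnv)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
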