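#' Pipeline configuration for spheroid sprout quantification
#'
#' Collects every tunable of the segmentation and skeletonization pipeline
#' in one validated object. The defaults reproduce the published analysis
#' protocol for spheroid sprouting images acquired at 2 um per pixel: a
#' 1x1 (identity) noise median filter, contrast-limited adaptive histogram
#' equalization, Sobel edge segmentation, spreading of the edge mask by
#' convolution with a 100-pixel-wide Gaussian, a foreground threshold at
#' the median of the nonzero convolved values plus 0.3 sample standard
#' deviations, diamond dilation of radius 2 before re-skeletonization, and
#' removal of skeletal components smaller than 6 pixels.
#'
#' @param noise_median_kernel Odd integer, side of the square median filter
#'   applied before contrast enhancement, in pixels. The default 1 is the
#'   identity; raise it only for genuinely noisy acquisitions.
#' @param clahe_tiles Integer pair, the (rows, cols) tile grid of the
#'   adaptive histogram equalization.
#' @param clahe_clip Fraction in (0, 1], contrast clip limit of the
#'   equalization expressed as a fraction of the histogram bin count.
#' @param sobel_sensitivity Positive scalar multiplying the root-mean-square
#'   gradient magnitude to give the Sobel binarization threshold. The
#'   default 2.0 equals the classical automatic Sobel cutoff (four times
#'   the mean squared gradient magnitude, taken on the magnitude scale);
#'   lower values admit progressively more background texture as edges.
#' @param gauss_width Integer, side of the square Gaussian kernel used to
#'   spread the edge mask, in pixels.
#' @param gauss_sigma Positive scalar, standard deviation of that Gaussian
#'   in pixels. The spread's purpose is to close gaps at the scale of the
#'   structures themselves (a sprout half-width, one or two pixels at
#'   2 um per pixel) before thresholding and hole filling; a sigma of
#'   tens of pixels would fuse neighboring sprouts into one lobe and
#'   inflate every area measurement, so the default is 1 px regardless of
#'   the kernel support.
#' @param threshold_coeff Nonnegative scalar multiplying the standard
#'   deviation in the adaptive foreground threshold.
#' @param center_median_kernel Odd integer, side of the median filter used
#'   to smooth the image before locating the bright spheroid center.
#' @param center_bright_fraction Fraction of the smoothed-image maximum at
#'   or above which a pixel counts as part of the spheroid center.
#' @param center_dilate_radius Integer, radius in pixels of the disc used
#'   to expand the detected center over the core's dim rim.
#' @param skeleton_min_branch Integer, minimum branch length in pixels kept
#'   by the initial skeletonization (1 keeps every branch).
#' @param refine_prune_px Integer, minimum branch length in pixels kept
#'   when the skeleton is re-thinned after diamond dilation.
#' @param diamond_radius Integer, radius of the diamond (L1-ball)
#'   structuring element used to bridge skeleton gaps before re-thinning.
#' @param min_component_px Integer, skeletal components with fewer pixels
#'   than this are discarded as noise; components of exactly this size are
#'   kept.
#' @param connectivity 4 or 8, pixel connectivity used for component
#'   labelling throughout.
#' @param min_mask_area_px Integer, total-mask components with fewer
#'   pixels are discarded as segmentation noise. The default 50 is the
#'   approximate mask footprint of the smallest countable structure: a
#'   skeleton of `min_component_px` (6) pixels at minimal sprout width
#'   plus the edge fattening the segmentation adds, so anything smaller
#'   can never yield a valid sprout component. Must stay small enough to
#'   keep genuine detached (migrated) sprout fragments.
#' @param keep_largest_component Logical, whether the total-spheroid mask
#'   is reduced to its largest connected component. Off by default
#'   because detached (migrated) sprouts form their own mask components
#'   and would be erased; turn on for crops whose borders catch
#'   fragments of neighboring spheroids.
#' @param fill_holes Logical, whether holes in the total-spheroid mask are
#'   filled before measurement (the spheroid body is solid tissue).
#' @param pixel_size_um Physical pixel size in micrometers, used only to
#'   convert the cumulative sprout length to micrometers.
#' @param plane 1-based page index used when a multi-page TIFF is read;
#'   analysis is always single-plane.
#'
#' @return A list of class `sprout_config` with all fields validated.
#' @examples
#' cfg <- sprout_config()
#' cfg$threshold_coeff
#' sprout_config(pixel_size_um = 1.0)$pixel_size_um
#' @export
sprout_config <- function(noise_median_kernel = 1L,
                          clahe_tiles = c(8L, 8L),
                          clahe_clip = 0.01,
                          sobel_sensitivity = 2.0,
                          gauss_width = 100L,
                          gauss_sigma = 1.0,
                          threshold_coeff = 0.3,
                          center_median_kernel = 11L,
                          center_bright_fraction = 0.90,
                          center_dilate_radius = 5L,
                          skeleton_min_branch = 1L,
                          refine_prune_px = 10L,
                          diamond_radius = 2L,
                          min_component_px = 6L,
                          connectivity = 8L,
                          min_mask_area_px = 50L,
                          keep_largest_component = FALSE,
                          fill_holes = TRUE,
                          pixel_size_um = 2.0,
                          plane = 1L) {
  cfg <- list(
    noise_median_kernel = as.integer(noise_median_kernel),
    clahe_tiles = as.integer(rep_len(clahe_tiles, 2L)),
    clahe_clip = as.numeric(clahe_clip),
    sobel_sensitivity = as.numeric(sobel_sensitivity),
    gauss_width = as.integer(gauss_width),
    gauss_sigma = as.numeric(gauss_sigma),
    threshold_coeff = as.numeric(threshold_coeff),
    center_median_kernel = as.integer(center_median_kernel),
    center_bright_fraction = as.numeric(center_bright_fraction),
    center_dilate_radius = as.integer(center_dilate_radius),
    skeleton_min_branch = as.integer(skeleton_min_branch),
    refine_prune_px = as.integer(refine_prune_px),
    diamond_radius = as.integer(diamond_radius),
    min_component_px = as.integer(min_component_px),
    connectivity = as.integer(connectivity),
    min_mask_area_px = as.integer(min_mask_area_px),
    keep_largest_component = isTRUE(keep_largest_component),
    fill_holes = isTRUE(fill_holes),
    pixel_size_um = as.numeric(pixel_size_um),
    plane = as.integer(plane)
  )
  class(cfg) <- "sprout_config"
  validate_sprout_config(cfg)
  cfg
}

validate_sprout_config <- function(cfg) {
  stopifnot(inherits(cfg, "sprout_config"))
  odd <- function(k) k >= 1L && k %% 2L == 1L
  if (!odd(cfg$noise_median_kernel))
    stop("'noise_median_kernel' must be a positive odd integer", call. = FALSE)
  if (!odd(cfg$center_median_kernel))
    stop("'center_median_kernel' must be a positive odd integer", call. = FALSE)
  if (any(cfg$clahe_tiles < 1L))
    stop("'clahe_tiles' must be >= 1 in both axes", call. = FALSE)
  if (!(cfg$clahe_clip > 0 && cfg$clahe_clip <= 1))
    stop("'clahe_clip' must lie in (0, 1]", call. = FALSE)
  if (cfg$sobel_sensitivity <= 0)
    stop("'sobel_sensitivity' must be positive", call. = FALSE)
  if (cfg$gauss_width < 1L || cfg$gauss_sigma <= 0)
    stop("Gaussian kernel width must be >= 1 and sigma positive", call. = FALSE)
  if (cfg$threshold_coeff < 0)
    stop("'threshold_coeff' must be nonnegative", call. = FALSE)
  if (!(cfg$center_bright_fraction > 0 && cfg$center_bright_fraction <= 1))
    stop("'center_bright_fraction' must lie in (0, 1]", call. = FALSE)
  if (cfg$center_dilate_radius < 1L || cfg$diamond_radius < 1L)
    stop("structuring-element radii must be >= 1", call. = FALSE)
  if (cfg$skeleton_min_branch < 1L || cfg$refine_prune_px < 0L)
    stop("branch-length parameters must be nonnegative (min branch >= 1)",
         call. = FALSE)
  if (cfg$min_component_px < 1L)
    stop("'min_component_px' must be >= 1", call. = FALSE)
  if (cfg$min_mask_area_px < 1L)
    stop("'min_mask_area_px' must be >= 1", call. = FALSE)
  if (!cfg$connectivity %in% c(4L, 8L))
    stop("'connectivity' must be 4 or 8", call. = FALSE)
  if (cfg$pixel_size_um <= 0)
    stop("'pixel_size_um' must be positive", call. = FALSE)
  if (cfg$plane < 1L)
    stop("'plane' must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sprout_config <- function(x, ...) {
  cat("spheroid sprout quantification config\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " x ")))
  }
  invisible(x)
}
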