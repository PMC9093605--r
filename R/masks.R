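# Composition of the three segmentation masks: total spheroid, spheroid
# center, and sprouting area (total minus center).

largest_component <- function(mask, connectivity = 8L) {
  lab <- cpp_label(mask * 1L, connectivity)
  n <- max(lab)
  if (n <= 1L) return(mask)
  counts <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(counts)
}

drop_small_areas <- function(mask, min_area, connectivity = 8L) {
  lab <- cpp_label(mask * 1L, connectivity)
  n <- max(lab)
  if (n == 0L) return(mask)
  counts <- tabulate(lab[lab > 0L], nbins = n)
  matrix(lab %in% which(counts >= min_area), nrow(mask), ncol(mask))
}

fill_mask_holes <- function(mask) {
  as.matrix(EBImage::fillHull(mask * 1L)) > 0
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

diamond_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "diamond")
}

dilate_mask <- function(mask, brush) {
  as.matrix(EBImage::dilate(mask * 1L, brush)) > 0
}

#' Segment the total spheroid area
#'
#' Runs the full mask pipeline on a normalized image: median denoising,
#' adaptive histogram equalization, Sobel edge segmentation, Gaussian
#' spreading of the edge mask, and adaptive thresholding of the resulting
#' edge-density image at its nonzero median plus 0.3 standard deviations.
#' Holes are then filled (the spheroid body is solid tissue) and mask
#' components smaller than `min_mask_area_px` are dropped: such specks
#' are below the footprint of the smallest countable structure, so they
#' could only ever contribute noise components. Detached (migrated)
#' sprout fragments form their own mask components and are retained;
#' set `keep_largest_component` to reduce the mask to the spheroid blob
#' alone, e.g. when crops catch fragments of neighboring spheroids at
#' their borders.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param cfg A [sprout_config()].
#' @return A list with `mask` (logical matrix) and `threshold` (the
#'   adaptive threshold value applied to the edge-density image). A blank
#'   image yields an empty mask and threshold 0 with a warning.
#' @export
total_spheroid_mask <- function(img, cfg = sprout_config()) {
  assert_image(img)
  validate_sprout_config(cfg)
  sm <- median_smooth(img, cfg$noise_median_kernel)
  if (max(sm) == min(sm)) {
    warning("blank image: no structure to segment")
    return(list(mask = matrix(FALSE, nrow(img), ncol(img)), threshold = 0))
  }
  eq <- equalize_adaptive(sm, cfg$clahe_tiles, cfg$clahe_clip)
  edges <- sobel_edge_mask(eq, cfg$sobel_sensitivity)
  if (!any(edges)) {
    warning("no edges detected: returning empty spheroid mask")
    return(list(mask = matrix(FALSE, nrow(img), ncol(img)), threshold = 0))
  }
  dens <- gaussian_spread(edges, cfg$gauss_width, cfg$gauss_sigma)
  th <- nonzero_stats_threshold(dens, cfg$threshold_coeff)
  mask <- th$mask
  if (any(mask)) {
    if (cfg$fill_holes) mask <- fill_mask_holes(mask)
    if (cfg$min_mask_area_px > 1L)
      mask <- drop_small_areas(mask, cfg$min_mask_area_px, cfg$connectivity)
    if (cfg$keep_largest_component && any(mask))
      mask <- largest_component(mask, cfg$connectivity)
  }
  list(mask = mask, threshold = th$threshold)
}

#' Locate the spheroid center
#'
#' The center is the brightest region of the median-smoothed image:
#' pixels at or above `center_bright_fraction` of the smoothed maximum
#' are selected, reduced to their largest connected component, expanded
#' by a disc of `center_dilate_radius` pixels to cover the core's dim
#' rim, and intersected with the total mask.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param total Logical matrix, the total-spheroid mask.
#' @param cfg A [sprout_config()].
#' @return Logical matrix, a subset of `total`.
#' @export
center_mask <- function(img, total, cfg = sprout_config()) {
  assert_image(img)
  assert_mask(total, "total")
  assert_same_shape(img, total, "image and total mask")
  validate_sprout_config(cfg)
  if (!any(total)) return(total)
  sm <- median_smooth(img, cfg$center_median_kernel)
  bright <- sm >= cfg$center_bright_fraction * max(sm)
  bright <- largest_component(bright, cfg$connectivity)
  dilate_mask(bright, disc_brush(cfg$center_dilate_radius)) & total
}

#' Sprouting area: total spheroid minus center
#'
#' @param total Logical matrix, total-spheroid mask.
#' @param center Logical matrix, spheroid-center mask; must be a subset
#'   of `total`.
#' @return Logical matrix, the set difference `total \ center`.
#' @export
sprout_area_mask <- function(total, center) {
  assert_mask(total, "total")
  assert_mask(center, "center")
  assert_same_shape(total, center, "total and center masks")
  if (any(center & !total))
    stop("'center' must be a subset of 'total'", call. = FALSE)
  total & !center
}

#' Compute all three segmentation masks at once
#'
#' Convenience wrapper producing a validated mask set whose invariants
#' (center inside total, sprouting area the exact complement of the
#' center within the total) are asserted before returning.
#'
#' @inheritParams total_spheroid_mask
#' @return A list of class `sprout_masks` with elements `total`, `center`,
#'   `sprout_area` (logical matrices) and `threshold_value`.
#' @export
compute_masks <- function(img, cfg = sprout_config()) {
  tm <- total_spheroid_mask(img, cfg)
  ctr <- center_mask(img, tm$mask, cfg)
  sa <- sprout_area_mask(tm$mask, ctr)
  ms <- structure(list(total = tm$mask, center = ctr, sprout_area = sa,
                       threshold_value = tm$threshold),
                  class = "sprout_masks")
  validate_masks(ms)
  ms
}

validate_masks <- function(ms) {
  stopifnot(inherits(ms, "sprout_masks"))
  if (any(ms$center & !ms$total))
    stop("mask invariant violated: center not inside total", call. = FALSE)
  if (!identical(ms$sprout_area, ms$total & !ms$center))
    stop("mask invariant violated: sprout_area != total \\ center",
         call. = FALSE)
  if (sum(ms$total) != sum(ms$center) + sum(ms$sprout_area))
    stop("mask invariant violated: area counts do not partition",
         call. = FALSE)
  invisible(ms)
}
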