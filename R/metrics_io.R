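# End-to-end per-image analysis, TIFF reading, crop handling and CSV
# output. One image in, one metrics record out; a batch never aborts on a
# single bad image.

metrics_columns <- c("image_id", "total_area_px", "sprout_area_px",
                     "n_sprouts_total", "n_attached", "n_migrated",
                     "csl_px", "csl_um", "threshold_value")

empty_metrics <- function(image_id, threshold = 0) {
  data.frame(image_id = image_id, total_area_px = 0L, sprout_area_px = 0L,
             n_sprouts_total = 0L, n_attached = 0L, n_migrated = 0L,
             csl_px = 0L, csl_um = 0, threshold_value = threshold,
             stringsAsFactors = FALSE)
}

#' Analyze one spheroid image
#'
#' Runs the full quantification pipeline — segmentation of the total
#' spheroid and its center, sprout-skeleton extraction and refinement,
#' component filtering and attached/migrated classification — and returns
#' the per-spheroid metrics record. Degenerate inputs (blank wells,
#' spheroids with no sprouts) produce zeroed sprout metrics with a
#' warning rather than an error.
#'
#' @param img Numeric matrix in \[0, 1\], a single-plane spheroid image.
#' @param cfg A [sprout_config()].
#' @param image_id Identifier written to the `image_id` column.
#' @return One-row data frame with columns `image_id`, `total_area_px`,
#'   `sprout_area_px`, `n_sprouts_total`, `n_attached`, `n_migrated`,
#'   `csl_px`, `csl_um`, `threshold_value`.
#' @export
analyze_image <- function(img, cfg = sprout_config(), image_id = "image") {
  assert_image(img)
  validate_sprout_config(cfg)
  ms <- compute_masks(img, cfg)
  if (!any(ms$total)) return(empty_metrics(image_id, ms$threshold_value))
  sk <- initial_skeleton(ms$total, cfg)
  sk <- subtract_center(sk, ms$center)
  sk <- refine_skeleton(sk, cfg)
  sk <- filter_small_components(sk, cfg)
  comps <- classify_components(sk, ms$center, cfg)
  att <- vapply(comps, function(x) x$attachment == "attached", logical(1))
  csl <- cumulative_sprout_length(sk, cfg)
  data.frame(image_id = image_id,
             total_area_px = as.integer(sum(ms$total)),
             sprout_area_px = as.integer(sum(ms$sprout_area)),
             n_sprouts_total = length(comps),
             n_attached = as.integer(sum(att)),
             n_migrated = as.integer(sum(!att)),
             csl_px = csl$csl_px,
             csl_um = csl$csl_um,
             threshold_value = ms$threshold_value,
             stringsAsFactors = FALSE)
}

#' Extract crop rectangles from a whole-well image
#'
#' Declarative replacement for interactive cropping: each rectangle is
#' given as a 0-based, top-left-origin, half-open region
#' `[row0, row0 + height) x [col0, col0 + width)`.
#'
#' @param well_img Numeric matrix, the stitched well image.
#' @param rects Data frame with columns `image_id`, `row0`, `col0`,
#'   `height`, `width` (see [read_crop_rects()]).
#' @return Named list of sub-rasters, one per rectangle, named by
#'   `image_id`.
#' @export
crop_regions <- function(well_img, rects) {
  if (!is.matrix(well_img)) stop("'well_img' must be a matrix", call. = FALSE)
  needed <- c("image_id", "row0", "col0", "height", "width")
  if (!all(needed %in% names(rects)))
    stop("rects must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  out <- vector("list", nrow(rects))
  names(out) <- rects$image_id
  for (i in seq_len(nrow(rects))) {
    r <- rects[i, ]
    if (r$height < 1L || r$width < 1L || r$row0 < 0L || r$col0 < 0L ||
        r$row0 + r$height > nrow(well_img) ||
        r$col0 + r$width > ncol(well_img))
      stop(sprintf("crop rectangle '%s' lies outside the %dx%d well image",
                   r$image_id, nrow(well_img), ncol(well_img)), call. = FALSE)
    out[[i]] <- well_img[r$row0 + seq_len(r$height),
                         r$col0 + seq_len(r$width), drop = FALSE]
  }
  out
}

#' Read a crop-rectangle table
#'
#' @param path CSV file with header `image_id,row0,col0,height,width`.
#' @return Data frame of validated rectangles.
#' @export
read_crop_rects <- function(path) {
  rects <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("image_id", "row0", "col0", "height", "width")
  if (!all(needed %in% names(rects)))
    stop("crop file must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  rects
}

#' Read a grayscale TIFF as a normalized image
#'
#' Accepts single-channel 8- or 16-bit TIFFs; intensities are normalized
#' to \[0, 1\] by the dtype maximum (so a 16-bit image with maximum value
#' 65535 maps to 1.0). Multi-page files are reduced to the single
#' configured plane; analysis is always single-plane because attachment
#' cannot be resolved across focal planes and intensity projections blur
#' a halo around the spheroid body.
#'
#' @param path Path to the TIFF file.
#' @param plane 1-based page index for multi-page files.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_image <- function(path, plane = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (plane < 1L || plane > length(pages))
    stop(sprintf("plane %d requested but '%s' has %d page(s)",
                 plane, path, length(pages)), call. = FALSE)
  img <- pages[[plane]]
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop("multi-channel (RGB) TIFF not supported: ", path, call. = FALSE)
  }
  # readTIFF already rescales by the sample format's maximum
  pmin(pmax(img, 0), 1)
}

#' Write a normalized image as a 16-bit grayscale TIFF
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write per-spheroid metrics to CSV
#'
#' Fixed header, one row per image, rows sorted by `image_id` so the
#' output is independent of file-discovery order.
#'
#' @param records Data frame of metrics rows as returned by
#'   [analyze_image()] (rows may be `rbind`-ed).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(records, path) {
  if (nrow(records) > 0L && !all(metrics_columns %in% names(records)))
    stop("records are missing metrics columns", call. = FALSE)
  if (nrow(records) == 0L) {
    records <- empty_metrics("x")[0, ]
  } else {
    records <- records[order(records$image_id), metrics_columns, drop = FALSE]
  }
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a metrics CSV back into a data frame
#' @param path CSV written by [write_metrics_csv()].
#' @return Data frame with the standard metrics columns.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Analyze every TIFF in a directory
#'
#' Processes all `.tif`/`.tiff` files, collecting one metrics row per
#' readable image; per-image failures are recorded and reported, never
#' fatal to the batch.
#'
#' @param input_dir Directory of single-spheroid TIFFs.
#' @param cfg A [sprout_config()].
#' @param qc_dir Optional directory for per-image QC overlay PNGs.
#' @return A list with `metrics` (data frame, sorted by image_id) and
#'   `errors` (named character vector of per-image error messages).
#' @export
analyze_directory <- function(input_dir, cfg = sprout_config(),
                              qc_dir = NULL) {
  files <- list.files(input_dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  rows <- list()
  errors <- character()
  for (f in files) {
    id <- sub("\\.tiff?$", "", basename(f), ignore.case = TRUE)
    res <- tryCatch({
      img <- read_image(f, cfg$plane)
      m <- analyze_image(img, cfg, image_id = id)
      if (!is.null(qc_dir))
        qc_overlay(img, cfg, file.path(qc_dir, paste0(id, "_qc.png")))
      m
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors[id] <- res else rows[[id]] <- res
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else empty_metrics("x")[0, ]
  metrics <- metrics[order(metrics$image_id), , drop = FALSE]
  rownames(metrics) <- NULL
  list(metrics = metrics, errors = errors)
}

#' Write a QC overlay PNG for visual audit
#'
#' Renders the original image in gray with the total-mask outline, the
#' center mask and the final skeleton in color.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param cfg A [sprout_config()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
qc_overlay <- function(img, cfg = sprout_config(), path) {
  assert_image(img)
  ms <- compute_masks(img, cfg)
  sk <- matrix(FALSE, nrow(img), ncol(img))
  if (any(ms$total)) {
    sk <- initial_skeleton(ms$total, cfg)
    sk <- refine_skeleton(subtract_center(sk, ms$center), cfg)
    sk <- filter_small_components(sk, cfg)
  }
  outline <- ms$total & !(neighbour_counts(ms$total) == 8 & ms$total)
  rgb <- array(rep(img, 3L), dim = c(nrow(img), ncol(img), 3L))
  rgb[, , 1][outline] <- 1; rgb[, , 2][outline] <- 0.4; rgb[, , 3][outline] <- 0
  rgb[, , 3][ms$center] <- pmin(rgb[, , 3][ms$center] + 0.4, 1)
  rgb[, , 1][sk] <- 0; rgb[, , 2][sk] <- 1; rgb[, , 3][sk] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
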