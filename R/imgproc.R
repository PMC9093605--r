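# Low-level raster operators composed by the mask pipeline. Images are
# plain numeric matrices normalized to [0, 1]; masks are logical matrices
# of the same shape.

assert_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop(sprintf("'%s' must be a nonempty numeric matrix", arg), call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop(sprintf("'%s' must be normalized to [0, 1]", arg), call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask) || length(mask) == 0L)
    stop(sprintf("'%s' must be a nonempty logical matrix", arg), call. = FALSE)
  if (anyNA(mask))
    stop(sprintf("'%s' contains NA", arg), call. = FALSE)
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "rasters") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have mismatched shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(NULL)
}

#' Median smoothing with edge-replicated padding
#'
#' Replaces every pixel by the median of its `kernel` x `kernel`
#' neighborhood; pixels beyond the border are taken as copies of the
#' nearest edge pixel. A kernel of 1 is the identity and is the pipeline
#' default for the denoising step.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param kernel Positive odd integer, neighborhood side length in pixels.
#' @return Numeric matrix of the same shape.
#' @examples
#' m <- matrix(runif(25), 5, 5)
#' identical(median_smooth(m, 1L), m)
#' @export
median_smooth <- function(img, kernel) {
  assert_image(img)
  kernel <- as.integer(kernel)
  if (length(kernel) != 1L || is.na(kernel) || kernel < 1L || kernel %% 2L == 0L)
    stop("'kernel' must be a positive odd integer", call. = FALSE)
  cpp_median_filter(img, kernel)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a contrast clip limit, used to
#' bring dim sprouts up to a contrast at which edge detection can see
#' them. Output intensities lie in \[0, 1\] and, within a tile, preserve
#' the rank order of distinct input intensities.
#'
#' The image is padded by edge replication to a multiple of the tile grid
#' (the underlying equalizer requires exact tiling) and cropped back, so
#' the shape is preserved. The clip fraction `clip` is mapped to the
#' equalizer's clip multiple over its 256-bin histograms.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param tiles Integer pair, tile grid as (row tiles, column tiles).
#' @param clip Fraction in (0, 1], contrast clip limit.
#' @return Numeric matrix of the same shape, values in \[0, 1\].
#' @export
equalize_adaptive <- function(img, tiles = c(8L, 8L), clip = 0.01) {
  assert_image(img)
  tiles <- as.integer(rep_len(tiles, 2L))
  if (any(tiles < 1L)) stop("'tiles' must be >= 1 in each axis", call. = FALSE)
  if (!(clip > 0 && clip <= 1)) stop("'clip' must lie in (0, 1]", call. = FALSE)
  d <- dim(img)
  # a tile must hold at least a few pixels; shrink the grid on tiny images
  tiles <- pmin(tiles, pmax(1L, d %/% 2L))
  # the underlying equalizer needs >= 2 tiles per axis; a single-tile
  # (global) request is emulated by duplicating the image along that axis
  # so both tiles share the global histogram, then cropping back
  work <- img
  if (tiles[1] == 1L) { work <- rbind(work, work); tiles[1] <- 2L }
  if (tiles[2] == 1L) { work <- cbind(work, work); tiles[2] <- 2L }
  dw <- dim(work)
  pad <- (tiles - dw %% tiles) %% tiles
  padded <- work[c(seq_len(dw[1]), rep(dw[1], pad[1])),
                 c(seq_len(dw[2]), rep(dw[2], pad[2])), drop = FALSE]
  bins <- 256L
  out <- EBImage::clahe(padded, nx = tiles[1], ny = tiles[2], bins = bins,
                        limit = max(clip * bins, 1), keep.range = FALSE)
  out <- as.matrix(out)[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  pmin(pmax(out, 0), 1)
}

sobel_kernel_row <- function() {
  # gradient along rows (vertical intensity change)
  matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
}
sobel_kernel_col <- function() t(sobel_kernel_row())

#' Sobel edge segmentation
#'
#' Computes the gradient magnitude from the two 3x3 Sobel kernels
#' (edge-replicated borders) and binarizes it at
#' `sensitivity * RMS(gradient magnitude)`. The threshold is
#' scale-invariant (doubling all intensities leaves the mask unchanged);
#' at the default `sensitivity = 2` it coincides with the classical
#' automatic Sobel cutoff of four times the mean squared gradient
#' magnitude.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param sensitivity Positive scalar; larger values keep fewer edges.
#' @return Logical matrix marking edge pixels.
#' @export
sobel_edge_mask <- function(img, sensitivity = 2.0) {
  assert_image(img)
  if (sensitivity <= 0) stop("'sensitivity' must be positive", call. = FALSE)
  gr <- cpp_conv3(img, sobel_kernel_row())
  gc <- cpp_conv3(img, sobel_kernel_col())
  g <- sqrt(gr * gr + gc * gc)
  thr <- sensitivity * sqrt(mean(g * g))
  g > thr
}

gaussian_kernel2d <- function(width, sigma) {
  # unit-sum square Gaussian; for even widths the center falls between
  # pixels, keeping the kernel symmetric
  ctr <- (width + 1) / 2
  x <- seq_len(width) - ctr
  g1 <- exp(-(x * x) / (2 * sigma * sigma))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Spread a binary edge mask by Gaussian convolution
#'
#' Linear convolution of the mask (as 0/1 reals) with a unit-sum square
#' Gaussian kernel, with zero padding beyond the borders. This turns the
#' sparse edge mask into a smooth edge-density image on which a global
#' threshold can delineate the whole spheroid; it is the "dilation by
#' convolution" step of the segmentation.
#'
#' Convolution is computed by FFT; magnitudes below 1e-10 are snapped to
#' exact zero so that the downstream nonzero-value statistics see the
#' same support as a direct convolution would.
#'
#' @param mask Logical matrix.
#' @param width Integer kernel side length in pixels.
#' @param sigma Positive Gaussian standard deviation in pixels.
#' @return Nonnegative numeric matrix of the same shape; total mass equals
#'   the foreground count up to border truncation.
#' @export
gaussian_spread <- function(mask, width = 100L, sigma = 1.0) {
  assert_mask(mask)
  width <- as.integer(width)
  if (width < 1L) stop("'width' must be >= 1", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  ker <- gaussian_kernel2d(width, sigma)
  out <- conv2_same(mask * 1.0, ker)
  out[abs(out) < 1e-10] <- 0
  pmax(out, 0)
}

# FFT-based 2-D linear convolution, 'same' output window, zero padding.
conv2_same <- function(img, ker) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(ker); kc <- ncol(ker)
  pr <- stats::nextn(nr + kr - 1L, c(2, 3, 5))
  pc <- stats::nextn(nc + kc - 1L, c(2, 3, 5))
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- img
  B <- matrix(0, pr, pc); B[seq_len(kr), seq_len(kc)] <- ker
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (pr * pc)
  r0 <- floor((kr - 1) / 2); c0 <- floor((kc - 1) / 2)
  full[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
}

#' Adaptive threshold from nonzero-value statistics
#'
#' Thresholds an image at the median of its nonzero values plus
#' `coeff` sample standard deviations of those values (N-1 denominator).
#' Pixels strictly greater than the threshold form the foreground. This
#' is the background-removal step applied to the Gaussian-spread edge
#' image; the 0.3 default coefficient was determined empirically for
#' spheroid fluorescence images.
#'
#' @param img Nonnegative numeric matrix.
#' @param coeff Nonnegative scalar weight on the standard deviation.
#' @return A list with `threshold` (scalar) and `mask` (logical matrix).
#'   An all-zero image yields threshold 0 and an empty mask, with a
#'   warning.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 1:3] <- c(2, 4, 6) / 6
#' nonzero_stats_threshold(m, 0.3)$threshold  # median 4/6 + 0.3 * sd
#' @export
nonzero_stats_threshold <- function(img, coeff = 0.3) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop("'img' must be a nonempty numeric matrix", call. = FALSE)
  if (coeff < 0) stop("'coeff' must be nonnegative", call. = FALSE)
  nz <- img[img != 0]
  if (length(nz) == 0L) {
    warning("image has no nonzero pixels; returning empty mask")
    return(list(threshold = 0,
                mask = matrix(FALSE, nrow(img), ncol(img))))
  }
  s <- if (length(nz) > 1L) stats::sd(nz) else 0
  thr <- stats::median(nz) + coeff * s
  list(threshold = thr, mask = img > thr)
}

#' Normalize an integer raster to \[0, 1\] by its dtype maximum
#'
#' Divides by the maximum representable value of the stated bit depth
#' (255 or 65535), not by the per-image maximum, so that absolute
#' thresholds are comparable across images of one acquisition.
#'
#' @param img Numeric matrix of raw integer intensities.
#' @param bits Bit depth of the acquisition, 8 or 16.
#' @return Numeric matrix in \[0, 1\].
#' @export
normalize_intensity <- function(img, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("'bits' must be 8 or 16", call. = FALSE)
  mx <- 2^bits - 1
  if (min(img) < 0 || max(img) > mx)
    stop("raw intensities outside the representable range", call. = FALSE)
  img / mx
}
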