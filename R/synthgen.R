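# Seeded generator of synthetic spheroid-sprouting images with exact
# ground truth, emulating the fluorescence phenotype: one bright,
# roughly circular core with dimmer curvilinear sprouts radiating from
# its boundary, optional detached sprout fragments, and background noise.

#' Specification of a synthetic spheroid image
#'
#' Defaults describe a realistic single-spheroid crop at 2 um per pixel:
#' a 512 x 512 frame, a core of radius 40 px at full intensity, sprouts
#' of 60-150 px drawn at half intensity and 3 px width, and mild
#' background noise. The contrast ordering core > sprout > background is
#' enforced, matching the real assay in which the spheroid body is by far
#' the brightest structure.
#'
#' @param shape Integer pair, (rows, cols) of the frame in pixels.
#' @param core_radius Core disk radius in pixels.
#' @param core_intensity Core intensity in \[0, 1\].
#' @param n_attached Number of sprouts seeded on the core boundary.
#' @param n_detached Number of detached sprout fragments.
#' @param sprout_length_range Min/max attached centerline walk length, px.
#' @param detached_length_range Min/max detached fragment walk length, px.
#' @param sprout_width Stroke width the centerline is dilated to, px.
#' @param sprout_intensity Sprout intensity; must be below
#'   `core_intensity`.
#' @param sprout_curvature Maximum angular drift per unit step, radians.
#' @param sprout_clearance Minimum distance in pixels kept between the
#'   centerlines of distinct sprouts (outside the core); walks violating
#'   it are redrawn, keeping sprouts well separated as in the radially
#'   sprouting phenotype the generator emulates.
#' @param detached_offset_min Minimum clearance between a detached
#'   fragment and the core boundary, px.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param seed Integer seed; identical specs with identical seeds render
#'   bit-identical images.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(512L, 512L),
                           core_radius = 40,
                           core_intensity = 1.0,
                           n_attached = 5L,
                           n_detached = 0L,
                           sprout_length_range = c(60, 150),
                           detached_length_range = c(20, 40),
                           sprout_width = 3L,
                           sprout_intensity = 0.5,
                           sprout_curvature = 0.08,
                           sprout_clearance = 8,
                           detached_offset_min = 30,
                           noise_sigma = 0.03,
                           seed = 1L) {
  spec <- list(shape = as.integer(rep_len(shape, 2L)),
               core_radius = core_radius,
               core_intensity = core_intensity,
               n_attached = as.integer(n_attached),
               n_detached = as.integer(n_detached),
               sprout_length_range = sprout_length_range,
               detached_length_range = detached_length_range,
               sprout_width = as.integer(sprout_width),
               sprout_intensity = sprout_intensity,
               sprout_curvature = sprout_curvature,
               sprout_clearance = sprout_clearance,
               detached_offset_min = detached_offset_min,
               noise_sigma = noise_sigma,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(spec$shape < 8L)) stop("frame too small", call. = FALSE)
  if (spec$core_radius < 1) stop("'core_radius' must be >= 1", call. = FALSE)
  if (!(spec$core_intensity > spec$sprout_intensity &&
        spec$sprout_intensity > 3 * spec$noise_sigma))
    stop("contrast ordering violated: need core > sprout > noise floor",
         call. = FALSE)
  if (spec$n_attached < 0L || spec$n_detached < 0L)
    stop("sprout counts must be nonnegative", call. = FALSE)
  if (diff(spec$sprout_length_range) < 0 ||
      diff(spec$detached_length_range) < 0)
    stop("length ranges must be (min, max) with min <= max", call. = FALSE)
  margin <- spec$sprout_width + 4
  reach_att <- spec$core_radius + spec$sprout_length_range[2] + margin
  reach_det <- spec$core_radius + spec$detached_offset_min +
    spec$detached_length_range[2] + margin
  reach <- max(spec$core_radius + margin,
               if (spec$n_attached > 0L) reach_att else 0,
               if (spec$n_detached > 0L) reach_det else 0)
  if (reach > min(spec$shape) / 2)
    stop("infeasible geometry: sprouts cannot fit inside the frame",
         call. = FALSE)
  invisible(spec)
}

# bounded-curvature random walk of unit steps; returns the de-duplicated
# rasterized centerline as an n x 2 matrix of (row, col)
walk_centerline <- function(start_rc, theta0, n_steps, curvature) {
  pos <- start_rc
  theta <- theta0
  px <- matrix(round(pos), 1, 2)
  for (i in seq_len(n_steps)) {
    theta <- theta + runif(1, -curvature, curvature)
    pos <- pos + c(sin(theta), cos(theta))
    p <- round(pos)
    if (any(p != px[nrow(px), ])) px <- rbind(px, p)
  }
  unique(px)
}

stroke_mask <- function(shape, centerline, width) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[centerline] <- TRUE
  if (width > 1L) m <- dilate_mask(m, EBImage::makeBrush(width, "disc"))
  m
}

#' Render a synthetic spheroid image with ground truth
#'
#' Draws the bright core disk, seeds `n_attached` bounded-curvature
#' random-walk centerlines on the core boundary at angular spacing of at
#' least half the even spacing, draws `n_detached` similar strokes offset
#' outward from the core, dilates each centerline to the sprout width,
#' and adds clipped Gaussian noise. Ground-truth lengths are the exact
#' pixel counts of the rasterized centerlines, so the pipeline's
#' cumulative sprout length can be compared like for like.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `image` (numeric matrix in \[0, 1\]) and `truth`,
#'   itself a list with `core_mask`, `sprouts` (per-sprout `pixels`,
#'   `length_px`, `attached`), `n_attached`, `n_detached` and
#'   `total_centerline_px`.
#' @export
generate_spheroid <- function(spec = synthetic_spec()) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dist <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    core <- dist <= spec$core_radius

    sprouts <- list()
    strokes <- matrix(FALSE, nr, nc)
    placed <- NULL  # pixels of all centerlines drawn so far
    min_d2 <- spec$sprout_clearance^2
    clear_of <- function(cl) {
      if (is.null(placed)) return(TRUE)
      d2 <- outer(cl[, 1], placed[, 1], "-")^2 +
        outer(cl[, 2], placed[, 2], "-")^2
      min(d2) >= min_d2
    }
    add_sprout <- function(cl, attached) {
      sprouts[[length(sprouts) + 1L]] <<-
        list(pixels = cl, length_px = nrow(cl), attached = attached)
      placed <<- rbind(placed, cl)
      strokes <<- strokes | stroke_mask(spec$shape, cl, spec$sprout_width)
    }
    if (spec$n_attached > 0L) {
      n <- spec$n_attached
      slot <- 2 * pi / n
      minsep <- slot / 2
      base <- (seq_len(n) - 1L) * slot
      jit <- runif(n, 0, slot - minsep)
      for (i in seq_len(n)) {
        theta <- base[i] + jit[i]
        start <- ctr + spec$core_radius * c(sin(theta), cos(theta))
        for (try in 1:40) {
          len <- round(runif(1, spec$sprout_length_range[1],
                             spec$sprout_length_range[2]))
          cl <- walk_centerline(start, theta, len, spec$sprout_curvature)
          # the first couple of pixels sit next to the neighbouring
          # sprout's base arc; clearance applies beyond the core rim
          r_cl <- sqrt((cl[, 1] - ctr[1])^2 + (cl[, 2] - ctr[2])^2)
          if (clear_of(cl[r_cl > spec$core_radius + 2, , drop = FALSE])) break
          if (try == 40L)
            stop("infeasible geometry: cannot place well-separated sprouts",
                 call. = FALSE)
        }
        add_sprout(cl, TRUE)
      }
    }
    if (spec$n_detached > 0L) {
      for (i in seq_len(spec$n_detached)) {
        for (try in 1:40) {
          theta <- runif(1, 0, 2 * pi)
          r0 <- spec$core_radius + spec$detached_offset_min + spec$sprout_width
          start <- ctr + r0 * c(sin(theta), cos(theta))
          len <- round(runif(1, spec$detached_length_range[1],
                             spec$detached_length_range[2]))
          cl <- walk_centerline(start, theta, len, spec$sprout_curvature)
          if (clear_of(cl)) break
          if (try == 40L)
            stop("infeasible geometry: cannot place detached fragments",
                 call. = FALSE)
        }
        add_sprout(cl, FALSE)
      }
    }

    img <- matrix(0, nr, nc)
    img[strokes] <- spec$sprout_intensity
    img[core] <- spec$core_intensity
    if (spec$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, spec$noise_sigma)
    img <- pmin(pmax(img, 0), 1)

    truth <- list(core_mask = core,
                  sprouts = sprouts,
                  n_attached = spec$n_attached,
                  n_detached = spec$n_detached,
                  total_centerline_px =
                    sum(vapply(sprouts, `[[`, integer(1), "length_px")))
    list(image = img, truth = truth)
  })
}
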