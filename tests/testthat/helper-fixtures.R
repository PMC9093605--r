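# Fixtures are built in code; oracles are brute-force reference
# implementations kept independent of the package internals they check.

# explicit neighborhood median with edge-replicated padding
oracle_median_filter <- function(img, k) {
  h <- k %/% 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- pmin(pmax(r + (-h:h), 1L), nr)
    cs <- pmin(pmax(c + (-h:h), 1L), nc)
    out[r, c] <- median(img[rs, cs][TRUE])
  }
  out
}

# sort, pick median, compute N-1 standard deviation by hand
oracle_nonzero_threshold <- function(img, coeff) {
  v <- sort(img[img != 0])
  n <- length(v)
  med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  s <- if (n > 1) sqrt(sum((v - mean(v))^2) / (n - 1)) else 0
  med + coeff * s
}

# hand-evaluated Sobel response at one interior pixel
oracle_sobel_at <- function(img, r, c) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  win <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
  gx <- sum(kx * win)
  gy <- sum(t(kx) * win)
  sqrt(gx^2 + gy^2)
}

disk_image <- function(n = 128, radius = 30, value = 1, centre = NULL) {
  if (is.null(centre)) centre <- c((n + 1) / 2, (n + 1) / 2)
  d <- sqrt((row(matrix(0, n, n)) - centre[1])^2 +
            (col(matrix(0, n, n)) - centre[2])^2)
  (d <= radius) * value
}

# straight horizontal skeleton segment
segment_mask <- function(nr = 80, nc = 80, row = 40, cols = 10:60) {
  m <- matrix(FALSE, nr, nc)
  m[row, cols] <- TRUE
  m
}

# Y-shaped skeleton: one trunk splitting into two branches, plus a
# "center" block the trunk starts from
y_fixture <- function() {
  sk <- matrix(FALSE, 120, 120)
  sk[60, 10:60] <- TRUE
  for (i in 1:30) {
    sk[60 - i, 60 + i] <- TRUE
    sk[60 + i, 60 + i] <- TRUE
  }
  centre <- matrix(FALSE, 120, 120)
  centre[55:65, 1:9] <- TRUE
  list(skeleton = sk, centre = centre)
}

# random blob mask from thresholded smoothed noise
random_blob_mask <- function(n = 48, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * n), n, n)
    sm <- median_smooth(x, 5L)
    sm > quantile(sm, 0.8)
  })
}

default_cfg <- function(...) sprout_config(...)

# one full pipeline run on a synthetic image, returning all intermediates
run_pipeline <- function(gen, cfg = sprout_config()) {
  ms <- suppressWarnings(compute_masks(gen$image, cfg))
  sk0 <- initial_skeleton(ms$total, cfg)
  raw <- subtract_center(sk0, ms$center)
  ref <- refine_skeleton(raw, cfg)
  fin <- filter_small_components(ref, cfg)
  comps <- classify_components(fin, ms$center, cfg)
  list(masks = ms, initial = sk0, raw = raw, refined = ref, final = fin,
       components = comps,
       metrics = suppressWarnings(analyze_image(gen$image, cfg, "px")))
}

true_foreground <- function(truth) {
  fg <- truth$core_mask
  for (s in truth$sprouts) fg[s$pixels] <- TRUE
  fg
}
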