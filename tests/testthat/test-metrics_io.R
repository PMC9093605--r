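test_that("analyze_image populates a consistent metrics record", {
  gen <- generate_spheroid(synthetic_spec(n_attached = 5L, seed = 2L))
  cfg <- sprout_config()
  m <- analyze_image(gen$image, cfg, "sph01")
  expect_identical(m$image_id, "sph01")
  expect_identical(m$n_sprouts_total, m$n_attached + m$n_migrated)
  expect_lte(m$sprout_area_px, m$total_area_px)
  expect_equal(m$csl_um, m$csl_px * cfg$pixel_size_um)
  expect_identical(m$n_attached, 5L)
  expect_identical(m$n_migrated, 0L)
  truth <- gen$truth$total_centerline_px
  expect_gte(m$csl_px, 0.85 * truth)
  expect_lte(m$csl_px, 1.15 * truth)
  expect_identical(analyze_image(gen$image, cfg, "sph01"), m)
})

test_that("degenerate images yield zeroed metrics with warnings, no crash", {
  cfg <- sprout_config()
  expect_warning(z <- analyze_image(matrix(0, 96, 96), cfg, "blank"))
  expect_identical(z$total_area_px, 0L)
  expect_identical(z$n_sprouts_total, 0L)
  expect_identical(z$csl_px, 0L)
  core_only <- generate_spheroid(synthetic_spec(shape = c(256L, 256L),
                                                n_attached = 0L, seed = 3L))
  m <- analyze_image(core_only$image, cfg, "coreonly")
  expect_gt(m$total_area_px, 0L)
  expect_identical(m$n_sprouts_total, 0L)
  expect_identical(m$csl_px, 0L)
})

test_that("crops extract exact sub-rasters with 0-based origins", {
  withr::with_seed(17, {
    well <- matrix(runif(120 * 150), 120, 150)
    full <- data.frame(image_id = "all", row0 = 0L, col0 = 0L,
                       height = 120L, width = 150L)
    expect_identical(crop_regions(well, full)$all, well)
    rects <- data.frame(image_id = c("a", "b", "c"),
                        row0 = c(3L, 50L, 0L), col0 = c(7L, 90L, 140L),
                        height = c(20L, 60L, 5L), width = c(30L, 55L, 10L))
    crops <- crop_regions(well, rects)
    for (i in 1:3) {
      r <- rects[i, ]
      expect_identical(dim(crops[[r$image_id]]), c(r$height, r$width))
      expect_identical(crops[[r$image_id]][5, 2],
                       well[r$row0 + 5, r$col0 + 2])
    }
    bad <- data.frame(image_id = "oops", row0 = 110L, col0 = 0L,
                      height = 20L, width = 10L)
    expect_error(crop_regions(well, bad), "oops")
  })
})

test_that("TIFF round-trips preserve 16-bit intensities and normalization", {
  withr::with_seed(23, {
    img <- matrix(sample(0:65535, 64 * 48, TRUE) / 65535, 64, 48)
    path <- withr::local_tempfile(fileext = ".tif")
    write_image(img, path)
    back <- read_image(path)
    expect_equal(back, img, tolerance = 1e-9)
    top <- matrix(1, 4, 4)
    write_image(top, path)
    expect_equal(max(read_image(path)), 1.0)
  })
  expect_error(read_image("no/such/file.tif"), "not found")
})

test_that("metrics CSV round-trips with a fixed header and sorted rows", {
  gen1 <- generate_spheroid(synthetic_spec(shape = c(256L, 256L),
                                           core_radius = 30,
                                           sprout_length_range = c(40, 60),
                                           n_attached = 3L, seed = 5L))
  cfg <- sprout_config()
  recs <- rbind(analyze_image(gen1$image, cfg, "zeta"),
                analyze_image(gen1$image, cfg, "alpha"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(recs, path)
  back <- read_metrics_csv(path)
  expect_identical(names(back),
                   c("image_id", "total_area_px", "sprout_area_px",
                     "n_sprouts_total", "n_attached", "n_migrated",
                     "csl_px", "csl_um", "threshold_value"))
  expect_identical(back$image_id, c("alpha", "zeta"))
  expect_equal(back$csl_px, rep(recs$csl_px[1], 2))
  write_metrics_csv(recs[0, ], path)
  lines <- readLines(path)
  expect_length(lines, 1)
})

test_that("directory analysis survives a corrupt file and stays ordered", {
  dir <- withr::local_tempdir()
  cfg <- sprout_config()
  for (i in 1:3) {
    gen <- generate_spheroid(synthetic_spec(shape = c(256L, 256L),
                                            core_radius = 30,
                                            sprout_length_range = c(40, 60),
                                            n_attached = 3L, seed = i))
    write_image(gen$image, file.path(dir, sprintf("img%02d.tif", 4 - i)))
  }
  writeLines("not a tiff", file.path(dir, "broken.tif"))
  res <- analyze_directory(dir, cfg)
  expect_identical(nrow(res$metrics), 3L)
  expect_identical(res$metrics$image_id, sort(res$metrics$image_id))
  expect_named(res$errors, "broken")
})
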