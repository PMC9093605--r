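test_that("initial skeleton thins a bar to a single-pixel line", {
  cfg <- sprout_config()
  expect_false(any(initial_skeleton(matrix(FALSE, 20, 20), cfg)))
  bar <- matrix(FALSE, 20, 70); bar[9:11, 10:59] <- TRUE
  sk <- initial_skeleton(bar, cfg)
  expect_true(all(sk[bar == FALSE] == FALSE))  # subset of the mask
  expect_lte(abs(sum(sk) - 50), 2)
  expect_true(all(rowSums(sk) %in% c(0, sum(sk))))  # one row only
  withr::with_seed(13, {
    for (i in 1:5) {
      blob <- random_blob_mask(40, seed = i)
      s <- initial_skeleton(blob, cfg)
      expect_true(all(!s | blob))
      expect_identical(sproutquant:::thin_mask(s), s)  # thinning fixed point
    }
  })
})

test_that("center subtraction removes exactly the covered pixels", {
  sk <- segment_mask(80, 80, 40, 11:70)
  none <- matrix(FALSE, 80, 80)
  expect_identical(subtract_center(sk, none), sk)
  expect_false(any(subtract_center(sk, sk | none)))
  centre <- matrix(FALSE, 80, 80); centre[, 31:50] <- TRUE
  cut <- subtract_center(sk, centre)
  expect_identical(sum(cut), 40L)
  expect_identical(max(sproutquant:::cpp_label(cut * 1L, 8L)), 2L)
  expect_error(subtract_center(sk, matrix(FALSE, 10, 10)), "shape")
})

test_that("skeleton refinement preserves curves, bridges gaps, and is idempotent", {
  cfg <- sprout_config()
  expect_false(any(refine_skeleton(matrix(FALSE, 30, 30), cfg)))
  seg <- segment_mask(80, 80, 40, 10:59)
  r1 <- refine_skeleton(seg, cfg)
  expect_lte(abs(sum(r1) - 50), 4)
  expect_identical(refine_skeleton(r1, cfg), r1)
  diagonal <- matrix(FALSE, 80, 80)
  for (i in 10:60) diagonal[i, i] <- TRUE
  d1 <- refine_skeleton(diagonal, cfg)
  expect_identical(refine_skeleton(d1, cfg), d1)
  gap <- matrix(FALSE, 40, 100)
  gap[20, 10:50] <- TRUE; gap[20, 54:90] <- TRUE
  bridged <- refine_skeleton(gap, cfg)
  expect_identical(max(sproutquant:::cpp_label(bridged * 1L, 8L)), 1L)
  # refinement output satisfies the thinning fixed point
  expect_identical(sproutquant:::thin_mask(bridged), bridged)
})

test_that("refinement is idempotent on skeletons from the full pipeline", {
  cfg <- sprout_config()
  for (s in c(3L, 5L)) {
    gen <- generate_spheroid(synthetic_spec(n_attached = 3L + s,
                                            n_detached = 1L, seed = s))
    pl <- run_pipeline(gen, cfg)
    expect_identical(refine_skeleton(pl$refined, cfg), pl$refined)
  }
})

test_that("component filtering drops below-threshold components only", {
  cfg <- sprout_config()
  sk <- matrix(FALSE, 30, 60)
  sk[5, 1:5] <- TRUE     # 5 px: removed
  sk[15, 1:6] <- TRUE    # 6 px: kept (threshold is the retained minimum)
  sk[25, 1:20] <- TRUE   # 20 px: kept
  out <- filter_small_components(sk, cfg)
  expect_false(any(out[5, ]))
  expect_identical(sum(out[15, ]), 6L)
  expect_identical(sum(out[25, ]), 20L)
  expect_false(any(filter_small_components(matrix(FALSE, 5, 5), cfg)))
  withr::with_seed(21, {
    for (i in 1:5) {
      blob <- random_blob_mask(40, seed = i + 50)
      s <- filter_small_components(initial_skeleton(blob, cfg), cfg)
      lab <- sproutquant:::cpp_label(s * 1L, cfg$connectivity)
      if (max(lab) > 0)
        expect_gte(min(tabulate(lab[lab > 0])), cfg$min_component_px)
    }
  })
})

test_that("components partition into attached and migrated", {
  cfg <- sprout_config()
  centre <- disk_image(100, 12) > 0
  sk <- matrix(FALSE, 100, 100)
  sk[50, 63:90] <- TRUE            # starts next to the centre: attached
  sk[10, 10:40] <- TRUE            # far away: migrated
  comps <- classify_components(sk, centre, cfg)
  expect_length(comps, 2)
  att <- sapply(comps, `[[`, "attachment")
  expect_setequal(att, c("attached", "migrated"))
  near <- comps[[which(att == "attached")]]
  expect_true(any(near$pixels[, 2] <= 64))
  expect_identical(sum(sapply(comps, `[[`, "size_px")), sum(sk))
  expect_length(classify_components(matrix(FALSE, 10, 10), centre[1:10, 1:10], cfg), 0)
})

test_that("cumulative sprout length is a pixel count scaled to micrometers", {
  cfg <- sprout_config()
  expect_identical(cumulative_sprout_length(matrix(FALSE, 5, 5), cfg),
                   list(csl_px = 0L, csl_um = 0))
  sk <- segment_mask(10, 60, 5, 6:55)
  csl <- cumulative_sprout_length(sk, cfg)
  expect_identical(csl$csl_px, 50L)
  expect_equal(csl$csl_um, 100)          # 2 um per pixel
  other <- segment_mask(10, 60, 9, 1:12)
  both <- sk | other
  expect_identical(cumulative_sprout_length(both, cfg)$csl_px,
                   csl$csl_px + cumulative_sprout_length(other, cfg)$csl_px)
})

test_that("a Y-shaped sprout counts as one component (known undercounting)", {
  cfg <- sprout_config()
  yf <- y_fixture()
  final <- filter_small_components(refine_skeleton(yf$skeleton, cfg), cfg)
  comps <- classify_components(final, yf$centre, cfg)
  expect_length(comps, 1)
  expect_identical(comps[[1]]$attachment, "attached")
})
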