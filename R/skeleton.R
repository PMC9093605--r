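# Sprout skeleton construction, refinement and analysis: thinning of the
# total-spheroid mask, subtraction of the spheroid center, gap-bridging
# dilation with re-thinning, small-component filtering, attached/migrated
# classification, and the cumulative sprout length.

thin_mask <- function(mask) {
  cpp_thin(mask * 1L) > 0
}

# 8-neighbour counts with pixels beyond the border treated as background
neighbour_counts <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- skel
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  out
}

skel_neighbours <- function(skel, r, c) {
  nr <- nrow(skel); nc <- ncol(skel)
  rs <- max(1L, r - 1L):min(nr, r + 1L)
  cs <- max(1L, c - 1L):min(nc, c + 1L)
  out <- NULL
  for (cc in cs) for (rr in rs) {
    if ((rr != r || cc != c) && skel[rr, cc]) out <- rbind(out, c(rr, cc))
  }
  out
}

# Remove spur branches shorter than min_len pixels. A spur is a path from
# an endpoint to a branch point (a pixel with >= 3 skeletal neighbours);
# the branch point itself is kept. Components that are simple open paths
# (no branch point) are never pruned here; the component-size filter
# decides their fate.
prune_branches <- function(skel, min_len) {
  if (min_len <= 1L || !any(skel)) return(skel)
  counts <- neighbour_counts(skel)
  eps <- which(skel & counts == 1, arr.ind = TRUE)
  if (nrow(eps) == 0L) return(skel)
  drop <- NULL
  for (i in seq_len(nrow(eps))) {
    start <- eps[i, ]
    path <- matrix(start, 1, 2)
    prev <- NULL
    cur <- start
    repeat {
      nb <- skel_neighbours(skel, cur[1], cur[2])
      deg <- if (is.null(nb)) 0L else nrow(nb)
      if (!all(cur == start) && deg >= 3L) {
        spur <- path[-nrow(path), , drop = FALSE]  # keep the branch point
        if (nrow(spur) < min_len) drop <- rbind(drop, spur)
        break
      }
      if (nrow(path) >= min_len) break  # long enough, keep
      nxt <- nb
      if (!is.null(prev) && !is.null(nxt))
        nxt <- nxt[!(nxt[, 1] == prev[1] & nxt[, 2] == prev[2]), , drop = FALSE]
      if (is.null(nxt) || nrow(nxt) == 0L) break  # dead end: open path
      prev <- cur
      cur <- nxt[1, ]
      path <- rbind(path, cur)
    }
  }
  if (!is.null(drop)) skel[drop] <- FALSE
  skel
}

#' Initial sprout skeleton
#'
#' Thins the total-spheroid mask to one-pixel-wide centerlines and prunes
#' branches shorter than `skeleton_min_branch` pixels (the default of 1
#' keeps every branch). The total mask, not the center-free sprouting
#' area, is thinned: the spheroid center is subtracted from the skeleton
#' afterwards, which removes skeletal "sprout extensions" that run inside
#' the spheroid body.
#'
#' @param total Logical matrix, total-spheroid mask.
#' @param cfg A [sprout_config()].
#' @return Logical matrix, a thinning fixed point contained in `total`.
#' @export
initial_skeleton <- function(total, cfg = sprout_config()) {
  assert_mask(total, "total")
  validate_sprout_config(cfg)
  prune_branches(thin_mask(total), cfg$skeleton_min_branch)
}

#' Subtract the spheroid center from a skeleton
#'
#' Removes skeletal pixels inside the center mask, so that only material
#' outside the spheroid body contributes to sprout measurements. The
#' result may transiently violate the one-pixel-wide curve property;
#' [refine_skeleton()] repairs it.
#'
#' @param skel Logical matrix, a skeleton.
#' @param center Logical matrix, spheroid-center mask of the same shape.
#' @return Logical matrix, `skel \ center`.
#' @export
subtract_center <- function(skel, center) {
  assert_mask(skel, "skel")
  assert_mask(center, "center")
  assert_same_shape(skel, center, "skeleton and center mask")
  skel & !center
}

#' Refine a raw sprout skeleton
#'
#' Dilates with a diamond (L1-ball) structuring element of radius
#' `diamond_radius` — bridging gaps of up to twice that radius left by the
#' center subtraction — then re-thins and prunes branches shorter than
#' `refine_prune_px` pixels, restoring the one-pixel-wide curve property.
#'
#' @param raw Logical matrix, typically the output of [subtract_center()].
#' @param cfg A [sprout_config()].
#' @return Logical matrix satisfying the thinning fixed-point property.
#' @export
refine_skeleton <- function(raw, cfg = sprout_config()) {
  assert_mask(raw, "raw")
  validate_sprout_config(cfg)
  if (!any(raw)) return(raw)
  fat <- dilate_mask(raw, diamond_brush(cfg$diamond_radius))
  y <- prune_branches(thin_mask(fat), cfg$refine_prune_px)
  # re-thinning a diamond-dilated curve mishandles open ends by a few
  # pixels in a direction-dependent way (it traces into the pointed cap,
  # or stops just short of it); retracting overgrown ends to the input's
  # own pixels and restoring input pixels lost at ends pins every end to
  # where the pre-dilation skeleton ended, making the operator idempotent
  rounds <- 2L * cfg$diamond_radius + 2L
  y <- retract_to_support(y, raw, rounds)
  extend_to_support(y, raw, rounds)
}

# Walk endpoint pixels of y back until they land on the support mask x,
# deleting at most max_rounds pixels per pass so a locally shifted
# centerline cannot be eaten. Gap bridges are interior pixels of y and
# are never touched.
retract_to_support <- function(y, x, max_rounds) {
  for (i in seq_len(max_rounds)) {
    ends <- y & neighbour_counts(y) <= 1 & !x
    if (!any(ends)) break
    y <- y & !ends
  }
  y
}

# Re-attach support pixels that the re-thinning dropped at open ends:
# grow each endpoint of y along adjacent pixels of x until the original
# end is reached again.
extend_to_support <- function(y, x, max_rounds) {
  for (i in seq_len(max_rounds)) {
    ends <- y & neighbour_counts(y) <= 1
    cand <- x & !y & dilate_mask(ends, EBImage::makeBrush(3L, "box"))
    if (!any(cand)) break
    y <- y | cand
  }
  y
}

#' Drop small skeletal components
#'
#' Removes connected components (under `cfg$connectivity`) with fewer
#' than `min_component_px` pixels; components of exactly that size are
#' kept. This is the noise filter applied to the refined skeleton before
#' sprouts are counted.
#'
#' @param skel Logical matrix, a skeleton.
#' @param cfg A [sprout_config()].
#' @return Logical matrix with every component of size
#'   >= `cfg$min_component_px`.
#' @export
filter_small_components <- function(skel, cfg = sprout_config()) {
  assert_mask(skel, "skel")
  validate_sprout_config(cfg)
  lab <- cpp_label(skel * 1L, cfg$connectivity)
  n <- max(lab)
  if (n == 0L) return(skel)
  counts <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(counts >= cfg$min_component_px)
  matrix(lab %in% keep, nrow(skel), ncol(skel))
}

#' Classify sprouts as attached or migrated
#'
#' Labels the connected components of the final skeleton and classifies
#' each as "attached" if any of its pixels overlaps, or comes within the
#' skeleton-refinement bridging distance (`diamond_radius` plus one
#' diagonal step) of, the spheroid-center mask — i.e. the sprout
#' intersects the center's boundary — and "migrated" otherwise: a sprout
#' disconnected from the spheroid body on the imaged focal plane.
#' The tolerance matters because thinning retracts open curve ends by a
#' pixel or two, leaving genuinely attached sprouts just short of strict
#' overlap.
#'
#' @param skel Logical matrix, the final filtered skeleton.
#' @param center Logical matrix, spheroid-center mask.
#' @param cfg A [sprout_config()].
#' @return A list of sprout components, each a list with `pixels` (n x 2
#'   matrix of row/col indices), `size_px` and `attachment`
#'   ("attached" or "migrated"). The counts partition:
#'   total = attached + migrated.
#' @export
classify_components <- function(skel, center, cfg = sprout_config()) {
  assert_mask(skel, "skel")
  assert_mask(center, "center")
  assert_same_shape(skel, center, "skeleton and center mask")
  validate_sprout_config(cfg)
  lab <- cpp_label(skel * 1L, cfg$connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  # attachment tolerance: the pipeline's own gap-bridging scale
  # (diamond_radius) plus 8-adjacency; thinning retracts open curve ends
  # by a pixel or two, so strict overlap would miss attached sprouts
  touch <- if (any(center)) {
    dilate_mask(dilate_mask(center, diamond_brush(cfg$diamond_radius)),
                EBImage::makeBrush(3L, "box"))
  } else center
  lapply(seq_len(n), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    dimnames(px) <- list(NULL, c("row", "col"))
    list(pixels = px,
         size_px = nrow(px),
         attachment = if (any(touch[px])) "attached" else "migrated")
  })
}

#' Cumulative sprout length
#'
#' Defined as the number of foreground pixels in the final sprout
#' skeleton (a pixel count, not a Euclidean path length), converted to
#' micrometers with the configured pixel size.
#'
#' @param skel Logical matrix, the final filtered skeleton.
#' @param cfg A [sprout_config()].
#' @return A list with `csl_px` (integer) and `csl_um`
#'   (`csl_px * pixel_size_um`).
#' @examples
#' sk <- matrix(FALSE, 10, 60); sk[5, 6:55] <- TRUE
#' cumulative_sprout_length(sk)  # 50 px -> 100 um at 2 um/px
#' @export
cumulative_sprout_length <- function(skel, cfg = sprout_config()) {
  assert_mask(skel, "skel")
  validate_sprout_config(cfg)
  n <- sum(skel)
  list(csl_px = as.integer(n), csl_um = n * cfg$pixel_size_um)
}
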