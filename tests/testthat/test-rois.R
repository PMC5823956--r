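test_that("ImageJ rectangle, oval and polygon ROIs rasterize by pixel-centre containment", {
  # rectangle covering pixel rows 2..5, cols 3..8 of a 20 x 20 field
  f <- tempfile(fileext = ".roi")
  writeBin(ij_roi_bytes("rect", top = 2, left = 3, bottom = 6, right = 9), f)
  rois <- read_imagej_rois(f, c(20, 20))
  expect_length(rois, 1)
  expect_equal(mask_area(rois[[1]]), 24)
  expect_true(all(rois[[1]]$mask[3:6, 4:9]))

  # oval in a 10 x 10 bounding box vs a brute-force pixel-centre-in-ellipse
  # count over the whole field
  writeBin(ij_roi_bytes("oval", top = 4, left = 6, bottom = 14, right = 16),
           f)
  ov <- read_imagej_rois(f, c(25, 25))[[1]]
  brute <- 0
  for (r in 0:24) for (cc in 0:24) {
    if (((cc + 0.5 - 11) / 5)^2 + ((r + 0.5 - 9) / 5)^2 <= 1)
      brute <- brute + 1
  }
  expect_lte(abs(mask_area(ov) - brute), 2)

  # a polygon tracing the same rectangle gives the same mask as the rect ROI
  writeBin(ij_roi_bytes("polygon", top = 2, left = 3, bottom = 6, right = 9,
                        xs = c(3, 9, 9, 3), ys = c(2, 2, 6, 6)), f)
  poly <- read_imagej_rois(f, c(20, 20))[[1]]
  writeBin(ij_roi_bytes("rect", top = 2, left = 3, bottom = 6, right = 9), f)
  rect <- read_imagej_rois(f, c(20, 20))[[1]]
  expect_identical(poly$mask, rect$mask)
})

test_that("zip archives of ROIs are read in archive order; empty archives are format errors", {
  z <- tempfile(fileext = ".zip")
  write_stored_zip(list(
    "b_second.roi" = ij_roi_bytes("rect", 0, 0, 2, 2),
    "a_first.roi" = ij_roi_bytes("rect", 5, 5, 8, 8)), z)
  rois <- read_imagej_rois(z, c(12, 12))
  expect_equal(vapply(rois, function(r) r$label, ""),
               c("b_second", "a_first"))
  expect_equal(vapply(rois, mask_area, 0L), c(4L, 9L))

  empty <- tempfile(fileext = ".zip")
  write_stored_zip(list()[0], empty)
  expect_error(read_imagej_rois(empty, c(12, 12)),
               "no .roi entries|unreadable zip")

  bad <- tempfile(fileext = ".roi")
  writeBin(charToRaw("not a roi file at all"), bad)
  expect_error(read_imagej_rois(bad, c(12, 12)), "not an ImageJ ROI")
})

test_that("ROIs outside the field of view are reported by label", {
  f <- tempfile(fileext = ".roi")
  writeBin(ij_roi_bytes("rect", top = 30, left = 30, bottom = 35,
                        right = 35), f)
  expect_error(read_imagej_rois(f, c(20, 20)), "outside")
})

test_that("neuropil growth reaches the target area and alternates dilations", {
  # single-pixel ROI in a large field: ring area must reach 4x and surround
  # the ROI on all four sides
  roi <- square_mask(41, 41, 21, 21, "px")
  ring <- grow_neuropil(roi, 4)
  expect_gte(mask_area(ring), 4)
  expect_false(ring$mask[21, 21])
  expect_true(ring$mask[20, 21] && ring$mask[22, 21] &&
              ring$mask[21, 20] && ring$mask[21, 22])

  # independent oracle: explicit alternating 4-/8-neighbour dilation loop
  roi5 <- square_mask(51, 51, 24:28, 24:28)
  ring5 <- grow_neuropil(roi5, 4)
  m <- roi5$mask
  diag_step <- FALSE
  repeat {
    if (sum(m & !roi5$mask) >= 100) break
    nxt <- matrix(FALSE, 51, 51)
    for (r in 1:51) for (cc in 1:51) {
      if (m[r, cc]) { nxt[r, cc] <- TRUE; next }
      nb <- if (diag_step)
        expand.grid(dr = c(-1, 1), dc = c(-1, 1))
      else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
      for (i in seq_len(nrow(nb))) {
        rr <- r + nb$dr[i]; ccc <- cc + nb$dc[i]
        if (rr >= 1 && rr <= 51 && ccc >= 1 && ccc <= 51 && m[rr, ccc])
          nxt[r, cc] <- TRUE
      }
    }
    m <- nxt
    diag_step <- !diag_step
  }
  expect_equal(mask_area(ring5), sum(m & !roi5$mask))
  expect_identical(ring5$mask, m & !roi5$mask)
})

test_that("growth clipped by the field boundary warns and flags exhaustion", {
  roi <- square_mask(6, 6, 2:5, 2:5)
  expect_warning(ring <- grow_neuropil(roi, 10), "exhausted")
  expect_true(attr(ring, "exhausted"))
  expect_equal(mask_area(ring), 36 - 16)
  # full-field ROI: nothing left to grow into
  full <- roi_mask(matrix(TRUE, 5, 5), "all")
  expect_error(suppressWarnings(grow_neuropil(full, 1)), "no neuropil")
})

test_that("exclusion masks are removed from the ring", {
  roi <- square_mask(41, 41, 19:23, 19:23)
  other <- square_mask(41, 41, 19:23, 26:30, "other")
  ring <- grow_neuropil(roi, 4, exclusions = list(other))
  expect_false(any(ring$mask & other$mask))
  expect_gte(mask_area(ring), 100)
})

test_that("monotonicity: larger area ratios never shrink the ring", {
  roi <- square_mask(61, 61, 29:33, 29:33)
  areas <- vapply(c(1, 2, 4, 8), function(ar)
    mask_area(grow_neuropil(roi, ar)), 0L)
  expect_true(all(diff(areas) >= 0))
})

test_that("wedge split partitions the ring with near-equal areas", {
  ring <- annulus_mask(41, 41, 20.5, 20.5, 5, 10)
  roi <- annulus_mask(41, 41, 20.5, 20.5, 0, 4.5, "ctr")

  # n = 1 returns the ring unchanged
  rs1 <- split_subregions(ring, roi, 1)
  expect_identical(rs1$subregions[[1]]$mask, ring$mask)

  rs <- split_subregions(ring, roi, 4)
  areas <- vapply(rs$subregions, mask_area, 0L)
  # exact partition: every ring pixel in exactly one wedge
  expect_equal(sum(areas), mask_area(ring))
  un <- Reduce(`|`, lapply(rs$subregions, function(s) s$mask))
  expect_identical(un, ring$mask)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(any(rs$subregions[[i]]$mask & rs$subregions[[j]]$mask))
  # near-equal areas for a symmetric annulus
  expect_lte(max(areas) - min(areas), 0.15 * mean(areas))

  # oracle: per-pixel angle histogram over 4 bins
  ctr <- mask_centroid(roi)
  idx <- which(ring$mask, arr.ind = TRUE)
  th <- atan2(idx[, 1] - 0.5 - ctr[1], idx[, 2] - 0.5 - ctr[2]) %% (2 * pi)
  expect_equal(unname(areas),
               unname(as.vector(table(floor(th / (pi / 2))))))
})

test_that("default region construction gives subregions the ROI's area", {
  roi <- annulus_mask(61, 61, 30.5, 30.5, 0, 6, "cell")
  rs <- build_regions(roi)  # 4 subregions, ring grown to 4x ROI area
  areas <- vapply(rs$subregions, mask_area, 0L)
  expect_equal(rs$n_subregions, 4)
  # each wedge is close to the ROI area (discretisation slack)
  expect_true(all(abs(areas - mask_area(roi)) <= 0.3 * mask_area(roi)))
})

test_that("deficient wedges and oversized n raise informative errors", {
  ring <- annulus_mask(21, 21, 10.5, 10.5, 3, 5)
  roi <- square_mask(21, 21, 10:11, 10:11)
  expect_error(split_subregions(ring, roi, mask_area(ring) + 1L),
               "non-empty")
  # a ring confined to one quadrant leaves other wedges empty
  half <- ring$mask
  half[, 1:10] <- FALSE
  half[1:10, ] <- FALSE
  expect_error(split_subregions(roi_mask(half, "q"), roi, 4), "empty")
})

test_that("region construction is equivariant under 90-degree rotation", {
  m <- matrix(FALSE, 41, 41)
  m[15:22, 18:27] <- TRUE
  m[15:17, 18:20] <- FALSE  # break symmetry
  roi <- roi_mask(m, "cell")
  rot <- function(mm) t(mm)[, nrow(mm):1]  # 90 deg counter-clockwise
  roi_r <- roi_mask(rot(m), "cell")
  ring <- grow_neuropil(roi, 4)
  ring_r <- grow_neuropil(roi_r, 4)
  expect_identical(rot(ring$mask), ring_r$mask)
  rs <- split_subregions(ring, roi, 4)
  rs_r <- split_subregions(ring_r, roi_r, 4)
  rot_areas <- sort(vapply(rs$subregions, mask_area, 0L))
  expect_equal(sort(vapply(rs_r$subregions, mask_area, 0L)), rot_areas)
  # wedges match up to relabelling
  rotated <- lapply(rs$subregions, function(s) rot(s$mask))
  for (s in rs_r$subregions)
    expect_true(any(vapply(rotated, identical, TRUE, y = s$mask)))
})

test_that("mask export round-trips through the ImageJ polygon format", {
  m <- matrix(FALSE, 30, 30)
  m[5:12, 8:20] <- TRUE
  m[5:7, 8:10] <- FALSE  # L-shaped, still simply connected
  roi <- roi_mask(m, "lshape")
  d <- tempfile()
  write_imagej_rois(roi, d)
  back <- read_imagej_rois(d, c(30, 30))
  expect_identical(back[[1]]$mask, m)

  # boolean TIFF stack export
  f <- tempfile(fileext = ".tif")
  write_mask_tiff(list(roi, roi), f)
  pages <- tiff::readTIFF(f, all = TRUE)
  expect_length(pages, 2)
  expect_equal(pages[[1]] > 0.5, m)
})
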