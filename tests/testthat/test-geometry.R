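disk_mask <- function(side, r, cx = side / 2, cy = side / 2) {
  xs <- matrix(seq_len(side), side, side)
  ys <- matrix(seq_len(side), side, side, byrow = TRUE)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

test_that("segmentation recovers a synthetic disk almost exactly and keeps blemishes", {
  cfg <- small_scene()
  img <- render_fruit(cfg, "positive", seed = 17)
  m <- segment_fruit(img)
  # compare against the true rendered disk: IoU from the luminance support
  lum <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3
  true_disk <- lum > 0.15
  iou <- sum(m$mask & true_disk) / sum(m$mask | true_disk)
  expect_gte(iou, 0.98)
  expect_true(all(m$mask[img$truth_mask])) # blemishes are on the fruit
  expect_error(segment_fruit(array(0, c(32, 32, 3))), "no fruit")
})

test_that("normalized contour distance matches the exhaustive all-pairs oracle", {
  set.seed(4)
  for (rep in 1:5) {
    m <- matrix(FALSE, 9, 9)
    m[3:7, 3:7] <- TRUE
    # random notches keep the mask irregular
    m[sample(which(m), 4)] <- FALSE
    if (!any(m)) next
    dm <- normalized_contour_distance(m)
    bg <- which(!m, arr.ind = TRUE)
    bf <- matrix(0, 9, 9)
    for (i in 1:9) for (j in 1:9) {
      if (m[i, j]) bf[i, j] <- min(sqrt((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
    }
    expect_equal(dm$d, bf / max(bf), tolerance = 1e-12)
  }
})

test_that("distance is 1 at a disk centre and ~0 on the contour", {
  m <- disk_mask(41, 15, 21, 21)
  dm <- normalized_contour_distance(m)
  expect_equal(dm$d[21, 21], 1.0)
  contour_vals <- dm$d[m & dm$d > 0 & dm$d <= 1 / dm$normalization + 1e-12]
  expect_gt(length(contour_vals), 0)
  expect_true(all(contour_vals <= 1 / dm$normalization + 1e-12))
  expect_error(normalized_contour_distance(matrix(FALSE, 4, 4)), "empty")
})

test_that("the distance distribution of a disk is rotation invariant", {
  m <- disk_mask(41, 15)
  d1 <- sort(normalized_contour_distance(m)$d[m])
  m90 <- t(m)[, rev(seq_len(41))] # 90-degree rotation
  d2 <- sort(normalized_contour_distance(m90)$d[m90])
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("H(r,d) conserves pooled pixel counts and bins degenerate maps correctly", {
  m <- disk_mask(41, 15)
  dm <- normalized_contour_distance(m)
  rmap <- matrix(0.5, 41, 41)
  h <- relevance_histogram(list(rmap), list(dm), n_r = 20, n_d = 20)
  expect_equal(sum(h$counts), sum(m))
  expect_equal(h$n_pixels, sum(m))
  # uniform relevance 0.5 lands entirely in the bin [0.5, 0.55)
  expect_equal(sum(h$counts[11, ]), sum(m))
  # r = 1 and d = 1 are counted in the final (right-inclusive) bins
  one <- matrix(1, 41, 41)
  h1 <- relevance_histogram(list(one), list(dm))
  expect_equal(sum(h1$counts[20, ]), sum(m))
  expect_equal(sum(h1$counts), sum(m))

  set.seed(2)
  maps <- list(matrix(runif(41 * 41), 41), matrix(runif(41 * 41), 41))
  dms <- list(dm, dm)
  h2 <- relevance_histogram(maps, dms)
  expect_equal(sum(h2$counts), 2 * sum(m))
  expect_error(relevance_histogram(list(matrix(0, 4, 4)), list(dm)), "misaligned")
})

test_that("band summary sums match hand arithmetic and degenerate cases", {
  m <- disk_mask(41, 15)
  dm <- normalized_contour_distance(m)
  # all relevance at the centre: apex band holds everything
  centre <- matrix(0, 41, 41); centre[21, 21] <- 1
  h <- relevance_histogram(list(centre), list(dm))
  b <- band_relevance_summary(h, r_min = 0.8)
  expect_equal(b$mass[b$band == "apex"], sum(h$counts[17:20, ]))
  expect_equal(sum(b$mass), sum(h$counts[17:20, ]))

  # uniform high relevance: band masses proportional to band pixel areas
  h_u <- relevance_histogram(list(matrix(0.9, 41, 41)), list(dm))
  b_u <- band_relevance_summary(h_u, r_min = 0.8)
  expect_equal(b_u$mass / sum(b_u$mass), b_u$pixel_fraction, tolerance = 1e-12)
  expect_equal(b_u$enrichment, rep(1, 3), tolerance = 1e-12)

  # hand-built tiny histogram
  h3 <- structure(
    list(counts = matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3),
         r_edges = c(0, 1 / 3, 2 / 3, 1), d_edges = c(0, 0.1, 0.75, 1),
         n_pixels = 45),
    class = "relevance_histogram"
  )
  b3 <- band_relevance_summary(h3, r_min = 2 / 3,
                               bands = list(periphery = c(0, 0.1),
                                            mid = c(0.1, 0.75),
                                            apex = c(0.75, 1)))
  expect_equal(b3$mass, c(3, 6, 9))
  expect_error(band_relevance_summary(h3, bands = list(x = c(0, 0.2))), "align")
})

test_that("featured/non-featured window extraction equals the brute-force scan", {
  set.seed(9)
  for (rep in 1:5) {
    side <- sample(16:24, 1)
    win <- sample(4:6, 1)
    mask <- disk_mask(side, side / 2 - 2)
    vals <- matrix(runif(side * side), side, side)
    feat <- extract_featured_region(vals, mask, win)
    want <- window_scan_oracle(vals, mask, win, maximize = TRUE)
    expect_equal(feat$row0, want$row0)
    expect_equal(feat$col0, want$col0)
    expect_equal(feat$mean_relevance, want$mean, tolerance = 1e-9)

    want_nf <- window_scan_oracle(
      vals, mask, win, maximize = FALSE,
      exclude_center = c(feat$row0 + win / 2, feat$col0 + win / 2),
      min_sep = 2 * win
    )
    if (is.null(want_nf)) {
      expect_error(
        extract_nonfeatured_region(vals, mask, feat, win, min_separation = 2 * win),
        "separation"
      )
    } else {
      nf <- extract_nonfeatured_region(vals, mask, feat, win, min_separation = 2 * win)
      expect_equal(nf$row0, want_nf$row0)
      expect_equal(nf$col0, want_nf$col0)
    }
  }
})

test_that("window extraction honours unimodal maps, tie rules and infeasibility", {
  mask <- matrix(TRUE, 20, 20)
  blob <- matrix(0, 20, 20)
  blob[10:12, 14:16] <- 1
  feat <- extract_featured_region(blob, mask, 5)
  # window centred on the blob centroid (11, 15) within a pixel
  expect_lte(abs(feat$row0 + 2 - 11), 1)
  expect_lte(abs(feat$col0 + 2 - 15), 1)

  uniform <- matrix(0.4, 20, 20)
  tie <- extract_featured_region(uniform, mask, 5)
  expect_equal(c(tie$row0, tie$col0), c(1L, 1L))

  # RS-NF window has zero mean relevance when the map is zero off the blob
  nf <- extract_nonfeatured_region(blob, mask, feat, 5, min_separation = 10)
  expect_equal(nf$mean_relevance, 0)
  expect_equal(nf$category, "RS-NF")

  expect_error(
    extract_nonfeatured_region(blob, mask, feat, 5, min_separation = 100),
    "separation"
  )
  expect_error(extract_featured_region(blob, mask, 30), "extent")
  tiny <- matrix(FALSE, 20, 20); tiny[1:2, 1:2] <- TRUE
  expect_error(extract_featured_region(blob, tiny, 5), "inside")
})
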