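# Relevance geometry: fruit segmentation on the near-black background,
# normalized contour distance (exact Euclidean distance transform, per-fruit
# max-normalised), the pooled two-dimensional relevance-distance histogram
# H(r,d), the apex/mid/periphery band summary, and extraction of the
# featured / non-featured square sampling windows.

#' Segment the fruit from a near-black background
#'
#' Luminance threshold (midpoint between background and fruit intensity by
#' Otsu's method), largest connected component, morphological closing and
#' hole filling.
#'
#' @param image A `labeled_image` or H x W x 3 array in `[0, 1]`.
#' @param min_area Minimum component area in pixels; below it the scene is
#'   treated as empty.
#' @return A `fruit_mask`: list with `mask` (logical matrix) and `contour`
#'   (two-column matrix of ordered outer boundary pixel coordinates).
#' @export
segment_fruit <- function(image, min_area = 64) {
  x <- if (inherits(image, "labeled_image")) image$pixels else image
  lum <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  thr <- EBImage::otsu(EBImage::Image(lum))
  bw <- EBImage::Image(lum > thr)
  lab <- EBImage::bwlabel(bw)
  sizes <- table(as.vector(EBImage::imageData(lab)))
  sizes <- sizes[names(sizes) != "0"]
  if (length(sizes) == 0 || max(sizes) < min_area) {
    abort("no fruit found: no foreground component above the minimum area")
  }
  keep <- as.integer(names(sizes)[which.max(sizes)])
  comp <- EBImage::Image(EBImage::imageData(lab) == keep)
  comp <- EBImage::closing(comp, EBImage::makeBrush(5, "disc"))
  comp <- EBImage::fillHull(comp)
  mask <- EBImage::imageData(comp) > 0
  contour <- EBImage::ocontour(EBImage::Image(mask))[[1]]
  # ocontour returns 0-based (x, y) = (row-1, col-1) for an Image whose first
  # dimension indexes rows here
  contour <- contour + 1L
  structure(list(mask = mask, contour = contour), class = "fruit_mask")
}

#' Normalized contour distance map
#'
#' Exact Euclidean distance of every fruit pixel to the nearest background
#' pixel, divided by its maximum over the mask: `d` is ~0 at the fruit
#' contour (one pixel of distance, so exactly `1/normalization`) and exactly
#' 1 at the deepest interior point (the apex of a disk-shaped fruit).
#'
#' @param mask A `fruit_mask` or logical matrix.
#' @return A `distance_map`: list with `d` (matrix, 0 outside the mask) and
#'   `normalization` (the maximum distance, pixels).
#' @export
normalized_contour_distance <- function(mask) {
  m <- if (inherits(mask, "fruit_mask")) mask$mask else mask
  if (!any(m)) abort("empty mask")
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
  mx <- max(dt)
  structure(list(d = dt / mx, normalization = mx), class = "distance_map")
}

bin_index <- function(v, n_bins) {
  # left-closed bins over [0, 1] with a right-inclusive final bin
  idx <- floor(pmin(pmax(v, 0), 1) * n_bins) + 1L
  idx[idx > n_bins] <- n_bins
  idx
}

#' Pooled relevance-distance histogram H(r, d)
#'
#' Pools every fruit pixel of every supplied fruit into a 2-D histogram of
#' relevance weight `r` against normalized contour distance `d`. Bins are
#' left-closed over `[0, 1]` with right-inclusive final bins, so `r = 1` and
#' `d = 1` are counted.
#'
#' @param maps List of `relevance_map` (or numeric matrices), one per fruit.
#' @param dmaps List of `distance_map` aligned with `maps`.
#' @param n_r,n_d Number of relevance / distance bins.
#' @return A `relevance_histogram`: `counts` (`n_r x n_d` matrix), `r_edges`,
#'   `d_edges`, `n_pixels`.
#' @export
relevance_histogram <- function(maps, dmaps, n_r = 20L, n_d = 20L) {
  stopifnot(length(maps) == length(dmaps), length(maps) >= 1)
  counts <- matrix(0, n_r, n_d)
  n_pixels <- 0L
  for (i in seq_along(maps)) {
    r <- if (inherits(maps[[i]], "relevance_map")) maps[[i]]$values else maps[[i]]
    dm <- dmaps[[i]]
    d <- if (inherits(dm, "distance_map")) dm$d else dm
    if (!all(dim(r) == dim(d))) abort("relevance and distance maps are misaligned")
    sel <- d > 0 # mask pixels: the distance transform is positive exactly there
    ri <- bin_index(r[sel], n_r)
    di <- bin_index(d[sel], n_d)
    counts <- counts + matrix(tabulate((di - 1L) * n_r + ri, n_r * n_d), n_r, n_d)
    n_pixels <- n_pixels + sum(sel)
  }
  structure(
    list(counts = counts,
         r_edges = seq(0, 1, length.out = n_r + 1L),
         d_edges = seq(0, 1, length.out = n_d + 1L),
         n_pixels = n_pixels),
    class = "relevance_histogram"
  )
}

#' @export
tidy.relevance_histogram <- function(x, ...) {
  n_r <- length(x$r_edges) - 1L; n_d <- length(x$d_edges) - 1L
  tibble(
    r_lo = rep(x$r_edges[-(n_r + 1L)], n_d),
    r_hi = rep(x$r_edges[-1L], n_d),
    d_lo = rep(x$d_edges[-(n_d + 1L)], each = n_r),
    d_hi = rep(x$d_edges[-1L], each = n_r),
    count = as.vector(x$counts)
  )
}

#' @export
autoplot.relevance_histogram <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(r_mid = (.data$r_lo + .data$r_hi) / 2,
                  d_mid = (.data$d_lo + .data$d_hi) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_mid, y = .data$r_mid,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "normalized contour distance d", y = "relevance weight r",
                  fill = "log10(count + 1)",
                  title = sprintf("H(r, d), %d pooled pixels", object$n_pixels)) +
    ggplot2::theme_minimal()
}

#' High-relevance mass per contour-distance band
#'
#' Sums histogram counts with relevance at or above `r_min` inside the
#' periphery (`d` in `[0, 0.1]`), mid (`(0.1, 0.75)`) and apex
#' (`[0.75, 1.0]`) bands. The histogram's d-edges must align with the band
#' boundaries (they do for the default 20 bins).
#'
#' The three bands cover very different pixel areas (on a disk the rim
#' annulus holds roughly a fifth of the pixels, the mid annulus three
#' quarters, the apex core a twentieth), so raw band masses are
#' area-confounded; `enrichment` divides each band's share of the
#' high-relevance mass by its share of all fruit pixels, and is what
#' "relevance accumulates in this band" should be read from.
#'
#' @param hist A `relevance_histogram`.
#' @param r_min High-relevance cutoff (bins whose lower edge is >= `r_min`).
#' @param bands Named list of `c(lo, hi)` distance bands.
#' @return Tibble with `band`, `d_lo`, `d_hi`, `mass`, `mass_fraction`
#'   (fraction of the total high-relevance mass), `pixel_fraction` (band's
#'   share of all pooled fruit pixels) and `enrichment`
#'   (`mass_fraction / pixel_fraction`).
#' @export
band_relevance_summary <- function(hist, r_min = 0.8,
                                   bands = list(periphery = c(0, 0.1),
                                                mid = c(0.1, 0.75),
                                                apex = c(0.75, 1.0))) {
  stopifnot(inherits(hist, "relevance_histogram"))
  edges <- hist$d_edges
  for (b in bands) {
    if (min(abs(edges - b[1])) > 1e-9 || min(abs(edges - b[2])) > 1e-9) {
      abort("histogram d-edges do not align with the requested band boundaries")
    }
  }
  r_sel <- hist$r_edges[-length(hist$r_edges)] >= r_min - 1e-9
  high_r <- colSums(hist$counts[r_sel, , drop = FALSE])
  all_r <- colSums(hist$counts)
  total <- sum(high_r)
  purrr::imap_dfr(bands, function(b, name) {
    d_sel <- hist$d_edges[-length(hist$d_edges)] >= b[1] - 1e-9 &
      hist$d_edges[-1L] <= b[2] + 1e-9
    mass <- sum(high_r[d_sel])
    mass_fraction <- if (total > 0) mass / total else NA_real_
    pixel_fraction <- sum(all_r[d_sel]) / hist$n_pixels
    tibble(band = name, d_lo = b[1], d_hi = b[2], mass = mass,
           mass_fraction = mass_fraction,
           pixel_fraction = pixel_fraction,
           enrichment = mass_fraction / pixel_fraction)
  })
}

# Window-sum machinery via integral images; means are exact up to float
# accumulation, and ties are resolved within a small tolerance so that a
# uniform map deterministically yields the first (smallest row, then column)
# window.
window_means <- function(values, mask, side) {
  H <- nrow(values); W <- ncol(values)
  if (side > H || side > W) abort("window_side exceeds the map extent")
  pad_cumsum <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum) # t(cumsum rows) -> transpose back
    cs <- t(cs)
    rbind(0, cbind(0, cs))
  }
  Sv <- pad_cumsum(values * mask)
  Sm <- pad_cumsum(mask * 1)
  nr <- H - side + 1L; nc <- W - side + 1L
  i2 <- seq_len(nr) + side; i1 <- seq_len(nr)
  j2 <- seq_len(nc) + side; j1 <- seq_len(nc)
  win_sum <- function(S) {
    S[i2, j2, drop = FALSE] - S[i1, j2, drop = FALSE] -
      S[i2, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  }
  vs <- win_sum(Sv)
  ms <- win_sum(Sm)
  inside <- abs(ms - side^2) < 0.5
  if (!any(inside)) abort("no window lies fully inside the mask")
  means <- vs / side^2
  means[!inside] <- NA
  means # rows = row0, cols = col0 (top-left corner positions)
}

pick_window <- function(means, maximize = TRUE, tol = 1e-9) {
  target <- if (maximize) max(means, na.rm = TRUE) else min(means, na.rm = TRUE)
  cand <- which(!is.na(means) & abs(means - target) <= tol * max(1, abs(target)),
                arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  list(row0 = cand[1, 1], col0 = cand[1, 2], mean = means[cand[1, 1], cand[1, 2]])
}

region_tibble <- function(category, row0, col0, side, mean_rel, dmap, fruit_id) {
  mean_d <- NA_real_
  if (!is.null(dmap)) {
    d <- if (inherits(dmap, "distance_map")) dmap$d else dmap
    mean_d <- mean(d[row0:(row0 + side - 1L), col0:(col0 + side - 1L)])
  }
  tibble(fruit_id = fruit_id, category = category,
         row0 = as.integer(row0), col0 = as.integer(col0),
         side = as.integer(side),
         mean_relevance = mean_rel, mean_d = mean_d)
}

#' Extract the featured sampling window
#'
#' The square window of side `window_side`, fully inside the fruit mask, that
#' maximises mean relevance (exhaustive integral-image scan). Ties go to the
#' smallest row, then column.
#'
#' @param map A `relevance_map` or numeric matrix.
#' @param mask A `fruit_mask` or logical matrix.
#' @param window_side Window side, pixels (default 32 at 224 x 224, roughly a
#'   10 mm square on a ~7 cm fruit face).
#' @param dmap Optional `distance_map` used to report the window's mean `d`.
#' @param category Category tag stored on the region (`"RS-F"` or `"C-F"`).
#' @param fruit_id Fruit identifier stored on the region.
#' @return One-row tibble: `fruit_id`, `category`, `row0`, `col0`, `side`,
#'   `mean_relevance`, `mean_d`.
#' @export
extract_featured_region <- function(map, mask, window_side = 32L, dmap = NULL,
                                    category = "RS-F", fruit_id = "fruit_1") {
  v <- if (inherits(map, "relevance_map")) map$values else map
  m <- if (inherits(mask, "fruit_mask")) mask$mask else mask
  means <- window_means(v, m, window_side)
  best <- pick_window(means, maximize = TRUE)
  region_tibble(category, best$row0, best$col0, window_side, best$mean, dmap, fruit_id)
}

#' Extract the non-featured sampling window
#'
#' The square window fully inside the mask that minimises mean relevance,
#' subject to its centre lying at least `min_separation` pixels from the
#' centre of the already extracted featured window (so the two tissue samples
#' do not overlap).
#'
#' @inheritParams extract_featured_region
#' @param featured One-row region tibble from [extract_featured_region()]
#'   for the same fruit.
#' @param min_separation Minimum centre-to-centre distance, pixels
#'   (default twice the window side).
#' @return One-row tibble as in [extract_featured_region()], with category
#'   `"RS-NF"`.
#' @export
extract_nonfeatured_region <- function(map, mask, featured,
                                       window_side = 32L,
                                       min_separation = 2L * window_side,
                                       dmap = NULL, fruit_id = featured$fruit_id[1]) {
  v <- if (inherits(map, "relevance_map")) map$values else map
  m <- if (inherits(mask, "fruit_mask")) mask$mask else mask
  means <- window_means(v, m, window_side)
  fc <- c(featured$row0[1] + featured$side[1] / 2,
          featured$col0[1] + featured$side[1] / 2)
  nr <- nrow(means); nc <- ncol(means)
  ctr_r <- seq_len(nr) + window_side / 2
  ctr_c <- seq_len(nc) + window_side / 2
  dist2 <- outer((ctr_r - fc[1])^2, (ctr_c - fc[2])^2, "+")
  means[dist2 < min_separation^2] <- NA
  if (all(is.na(means))) {
    abort("no window satisfies the separation constraint inside the mask")
  }
  best <- pick_window(means, maximize = FALSE)
  region_tibble("RS-NF", best$row0, best$col0, window_side, best$mean, dmap, fruit_id)
}
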