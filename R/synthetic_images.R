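# Synthetic fruit image generator: disk-shaped fruit on a near-black
# background, two camera profiles, class-dependent subtle blemishes planted at
# controlled normalized contour distances, with pixel-level truth masks.

#' Scene configuration for synthetic fruit images
#'
#' Describes how a synthetic apex-side fruit photograph is rendered: a shaded
#' disk (radial brightness falloff) on a near-black background, with optional
#' low-amplitude colour blemishes planted at controlled normalized contour
#' distances `d` (`d = 0` at the fruit outline, `d = 1` at the centre).
#' Blemishes are the only class-discriminative signal: negatives never carry
#' them, so at `blemish_amplitude = 0` the classes are indistinguishable.
#'
#' @param image_side Image side in pixels (square images).
#' @param fruit_radius_range Length-2 range of fruit radii, pixels.
#' @param background_level Background grey value in `[0, 1]` (near 0).
#' @param base_color Length-3 RGB triple in `[0, 1]` for the fruit skin.
#' @param color_jitter_sd SD of the per-fruit additive RGB jitter; makes the
#'   global mean colour an unreliable class cue so a classifier must localise.
#' @param camera_profiles Named list of camera profiles, each a list with
#'   `brightness_gain` (scalar) and `white_balance` (length-3 per-channel
#'   gains). Applied as a deterministic per-channel affine transform after the
#'   scene (including sensor noise) is rendered.
#' @param blemish_count_range Length-2 integer range of blemishes per positive
#'   fruit.
#' @param blemish_amplitude Peak colour-offset magnitude of a blemish, in
#'   `[0, 1]` pixel units. The default 0.05 keeps planted features subtle.
#' @param blemish_radius_range Length-2 range of blemish radii, pixels.
#' @param blemish_placement Data frame with columns `lo`, `hi`, `weight`
#'   giving a band mixture over normalized contour distance `d` from which
#'   blemish positions are drawn. The default concentrates mass at the apex
#'   (`d` in `[0.75, 1]`) and the periphery (`d` in `[0, 0.1]`).
#' @param noise_sd SD of the additive per-pixel sensor noise.
#' @param seed Default seed used by [generate_dataset()] when none is given.
#'
#' @return A `scene_config` list.
#' @examples
#' cfg <- scene_config(image_side = 64)
#' img <- render_fruit(cfg, label = "positive", seed = 1)
#' range(img$pixels)
#' @export
scene_config <- function(image_side = 224,
                         fruit_radius_range = round(c(0.36, 0.43) * image_side),
                         background_level = 0.03,
                         base_color = c(0.85, 0.55, 0.20),
                         color_jitter_sd = 0.04,
                         camera_profiles = list(
                           A = list(brightness_gain = 1.00, white_balance = c(1.00, 1.00, 1.00)),
                           B = list(brightness_gain = 0.92, white_balance = c(1.06, 1.00, 0.94))
                         ),
                         blemish_count_range = c(1L, 3L),
                         blemish_amplitude = 0.05,
                         blemish_radius_range = round(c(0.055, 0.09) * image_side),
                         blemish_placement = data.frame(
                           lo = c(0.75, 0.0), hi = c(1.0, 0.1), weight = c(0.5, 0.5)
                         ),
                         noise_sd = 0.02,
                         seed = 1L) {
  assert_scalar_number(image_side, "image_side", lower = 8)
  assert_range(fruit_radius_range, "fruit_radius_range", lower = 1)
  assert_scalar_number(background_level, "background_level", 0, 1)
  if (length(base_color) != 3L || any(base_color < 0 | base_color > 1)) {
    abort("`base_color` must be an RGB triple in [0, 1]")
  }
  assert_scalar_number(blemish_amplitude, "blemish_amplitude", 0, 1)
  assert_range(blemish_count_range, "blemish_count_range", lower = 1)
  assert_range(blemish_radius_range, "blemish_radius_range", lower = 1)
  stopifnot(is.data.frame(blemish_placement),
            all(c("lo", "hi", "weight") %in% names(blemish_placement)))
  if (any(blemish_placement$lo < 0) || any(blemish_placement$hi > 1) ||
      any(blemish_placement$lo > blemish_placement$hi)) {
    abort("`blemish_placement` bands must satisfy 0 <= lo <= hi <= 1")
  }
  if (any(blemish_placement$weight < 0) || sum(blemish_placement$weight) <= 0) {
    abort("`blemish_placement` weights must be nonnegative and not all zero")
  }
  if (is.null(names(camera_profiles)) || any(!nzchar(names(camera_profiles)))) {
    abort("`camera_profiles` must be a named list")
  }
  structure(
    list(
      image_side = as.integer(image_side),
      fruit_radius_range = fruit_radius_range,
      background_level = background_level,
      base_color = base_color,
      color_jitter_sd = color_jitter_sd,
      camera_profiles = camera_profiles,
      blemish_count_range = as.integer(blemish_count_range),
      blemish_amplitude = blemish_amplitude,
      blemish_radius_range = blemish_radius_range,
      blemish_placement = blemish_placement,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

draw_blemish_distance <- function(placement) {
  band <- sample.int(nrow(placement), 1L, prob = placement$weight)
  runif(1, placement$lo[band], placement$hi[band])
}

#' Render one synthetic fruit image
#'
#' Renders a shaded fruit disk on a near-black background. For positive
#' labels, blemishes (smooth low-amplitude colour bumps) are planted at
#' normalized contour distances drawn from `config$blemish_placement`, and
#' their pixel support is recorded in a truth mask. The camera profile is a
#' deterministic per-channel affine transform applied after the scene
#' (including sensor noise) is generated, so the same `seed` under two cameras
#' yields images that differ only by that transform (up to clipping).
#'
#' @param config A [scene_config()].
#' @param label `"positive"` or `"negative"`.
#' @param camera_id Name of a profile in `config$camera_profiles`.
#' @param seed Integer seed controlling the scene draw.
#' @param fruit_id Identifier stored on the image.
#'
#' @return A `labeled_image`: list with `pixels` (side x side x 3 array in
#'   `[0, 1]`), `label`, `truth_mask` (logical matrix; all-`FALSE` for
#'   negatives), `camera_id`, `fruit_id`.
#' @export
render_fruit <- function(config, label = c("positive", "negative"),
                         camera_id = names(config$camera_profiles)[1],
                         seed = NULL, fruit_id = "fruit_1") {
  stopifnot(inherits(config, "scene_config"))
  label <- match.arg(label)
  profile <- config$camera_profiles[[camera_id]]
  if (is.null(profile)) {
    abort(sprintf("unknown camera_id '%s'", camera_id))
  }
  if (max(config$blemish_radius_range) >= min(config$fruit_radius_range)) {
    abort("blemish radius range exceeds fruit radius range")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  s <- config$image_side
  radius <- runif(1, config$fruit_radius_range[1], config$fruit_radius_range[2])
  center <- s / 2 + runif(2, -0.02 * s, 0.02 * s)
  jitter <- rnorm(3, 0, config$color_jitter_sd)

  xs <- matrix(seq_len(s), s, s)          # row coordinate
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  rr <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  inside <- rr <= radius
  shade <- 1 - 0.35 * (rr / radius)^2     # radial brightness falloff

  pixels <- array(config$background_level, dim = c(s, s, 3))
  truth_mask <- matrix(FALSE, s, s)
  for (ch in 1:3) {
    plane <- pixels[, , ch]
    plane[inside] <- pmax(0, config$base_color[ch] + jitter[ch]) * shade[inside]
    pixels[, , ch] <- plane
  }

  if (label == "positive") {
    n_blem <- sample(seq(config$blemish_count_range[1], config$blemish_count_range[2]), 1L)
    # brownish darkening, scaled by amplitude
    offset_dir <- c(-1.0, -0.55, -0.15)
    for (b in seq_len(n_blem)) {
      d <- draw_blemish_distance(config$blemish_placement)
      brad <- runif(1, config$blemish_radius_range[1], config$blemish_radius_range[2])
      # centre at the drawn contour distance; blemishes near the rim are
      # clipped by the fruit outline rather than pushed inwards, so planted
      # peripheral features genuinely hug the contour
      cr <- min((1 - d) * radius, radius - 1)
      ang <- runif(1, 0, 2 * pi)
      bc <- center + cr * c(cos(ang), sin(ang))
      bdist2 <- (xs - bc[1])^2 + (ys - bc[2])^2
      bump <- exp(-bdist2 / (2 * (brad / 2)^2)) # smooth profile, sigma = brad/2
      hit <- (bdist2 <= brad^2) & inside
      truth_mask <- truth_mask | hit
      for (ch in 1:3) {
        pixels[, , ch] <- pixels[, , ch] +
          config$blemish_amplitude * offset_dir[ch] * bump * inside
      }
    }
  }

  pixels <- pixels + array(rnorm(s * s * 3, 0, config$noise_sd), dim = c(s, s, 3))
  for (ch in 1:3) {
    pixels[, , ch] <- pixels[, , ch] * profile$brightness_gain * profile$white_balance[ch]
  }
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1

  structure(
    list(pixels = pixels, label = label, truth_mask = truth_mask,
         camera_id = camera_id, fruit_id = fruit_id),
    class = "labeled_image"
  )
}

#' Generate a labelled synthetic fruit dataset
#'
#' Draws one scene seed per fruit (so the same fruit can be re-rendered under
#' another camera with [render_fruit()]) and renders `n_pos` positive and
#' `n_neg` negative fruits under a single camera profile.
#'
#' @inheritParams render_fruit
#' @param n_pos,n_neg Number of positive / negative fruits.
#' @param seed Dataset seed; defaults to `config$seed`.
#' @param id_prefix Prefix for generated fruit ids.
#'
#' @return A `fruit_dataset`: list of `labeled_image` objects with a
#'   `fruit_seeds` attribute (named per-fruit scene seeds).
#' @export
generate_dataset <- function(config, n_pos, n_neg,
                             camera_id = names(config$camera_profiles)[1],
                             seed = config$seed, id_prefix = "fruit") {
  stopifnot(inherits(config, "scene_config"), n_pos >= 0, n_neg >= 0)
  if (!camera_id %in% names(config$camera_profiles)) {
    abort(sprintf("unknown camera_id '%s'", camera_id))
  }
  n <- n_pos + n_neg
  labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
  set.seed(as.integer(seed))
  fruit_seeds <- sample.int(2147483646L, n)
  ids <- sprintf("%s_%03d", id_prefix, seq_len(n))
  images <- purrr::map(seq_len(n), function(i) {
    render_fruit(config, labels[i], camera_id, seed = fruit_seeds[i], fruit_id = ids[i])
  })
  names(fruit_seeds) <- ids
  structure(images, fruit_seeds = fruit_seeds, class = c("fruit_dataset", "list"))
}

#' Tabulate a fruit dataset
#'
#' @param dataset A `fruit_dataset` (or plain list of `labeled_image`).
#' @return A tibble with one row per image: `fruit_id`, `camera_id`, `label`,
#'   `n_truth_pixels`.
#' @export
image_manifest <- function(dataset) {
  purrr::map_dfr(dataset, function(img) {
    tibble(fruit_id = img$fruit_id, camera_id = img$camera_id,
           label = img$label, n_truth_pixels = sum(img$truth_mask))
  })
}

#' Write a fruit dataset to disk
#'
#' Images and truth masks go out as PNG, plus a TSV manifest with columns
#' `fruit_id`, `camera_id`, `label`, `image_path`, `mask_path`.
#'
#' @param dataset A `fruit_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble (also written to
#'   `dir/manifest.tsv`).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(dataset, function(img) {
    image_path <- file.path(dir, paste0(img$fruit_id, "_", img$camera_id, ".png"))
    mask_path <- file.path(dir, paste0(img$fruit_id, "_mask.png"))
    png::writePNG(img$pixels, image_path)
    png::writePNG(img$truth_mask * 1, mask_path)
    tibble(fruit_id = img$fruit_id, camera_id = img$camera_id, label = img$label,
           image_path = image_path, mask_path = mask_path)
  })
  write.table(rows, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
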