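# Explainable-AI relevance maps computed directly on the package's CNN:
# Grad-CAM at any named convolutional layer, guided backpropagation, and
# their combination, guided Grad-CAM.

new_relevance_map <- function(values, method, layer_name, target_class) {
  stopifnot(is.matrix(values))
  structure(
    list(values = values, method = method,
         layer_name = layer_name, target_class = target_class),
    class = "relevance_map"
  )
}

# Accepts either a role name registered in model$named_layers
# ("conv_shallow", "conv_last") or a literal conv layer name ("conv2").
resolve_conv_layer <- function(model, layer_name) {
  resolved <- if (layer_name %in% names(model$named_layers)) {
    unname(model$named_layers[[layer_name]])
  } else {
    layer_name
  }
  types <- purrr::map_chr(model$layers, "type")
  names_ <- purrr::map_chr(model$layers, ~ .x$name %||% "")
  idx <- which(names_ == resolved & types == "conv")
  if (length(idx) != 1) {
    abort(sprintf("'%s' does not name a convolutional layer of this model", layer_name))
  }
  # Grad-CAM uses the rectified feature map: take the ReLU directly after the
  # conv when present, otherwise the conv output itself.
  feature_idx <- idx
  if (idx < length(model$layers) && types[idx + 1] == "relu") feature_idx <- idx + 1L
  list(conv = idx, feature = feature_idx, resolved = resolved)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bilinear upsampling of a relevance grid
#'
#' Center-aligned bilinear interpolation from a coarse `h x w` grid to
#' `H x W`, used to carry a feature-map-resolution class activation map back
#' to image resolution.
#'
#' @param m Numeric matrix.
#' @param H,W Target dimensions.
#' @return `H x W` numeric matrix.
#' @export
bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  ri <- (seq_len(H) - 0.5) * h / H + 0.5
  ci <- (seq_len(W) - 0.5) * w / W + 0.5
  ri <- pmin(pmax(ri, 1), h); ci <- pmin(pmax(ci, 1), w)
  r0 <- pmin(floor(ri), h - 1L); r0[h == 1] <- 1
  c0 <- pmin(floor(ci), w - 1L); c0[w == 1] <- 1
  fr <- ri - r0; fc <- ci - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  top <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  bot <- m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
  top + bot
}

target_class_index <- function(model, target_class) {
  idx <- match(target_class, model$class_levels)
  if (is.na(idx)) abort(sprintf("unknown target class '%s'", target_class))
  idx
}

#' Grad-CAM relevance map
#'
#' Gradient-weighted class activation mapping: channel weights are the
#' spatial means of the class-score gradient at the chosen convolutional
#' layer's rectified feature map, the map is the ReLU of the weighted channel
#' sum, computed at the layer's spatial resolution, bilinearly upsampled to
#' image size, and max-normalised to `[0, 1]` when its maximum is positive.
#' Shallower layers give strictly finer pre-upsampling grids, which is the
#' reason to move the target layer up when the deepest map is too coarse to
#' guide tissue sampling.
#'
#' @param model A `cnn_classifier`.
#' @param image `labeled_image` or pixel array matching the model input.
#' @param target_class Class whose score is explained (default the positive,
#'   rapid-softening class, regardless of the predicted label).
#' @param layer_name Role name (`"conv_last"`, `"conv_shallow"`) or literal
#'   conv layer name.
#' @return A `relevance_map`.
#' @export
grad_cam <- function(model, image, target_class = "positive",
                     layer_name = "conv_last") {
  loc <- resolve_conv_layer(model, layer_name)
  x <- prepare_input(model, image)
  fw <- cnn_forward(model, x)
  dlogits <- as.numeric(seq_along(fw$logits) == target_class_index(model, target_class))
  bw <- cnn_backward(model, fw$cache, dlogits, stop_after = loc$feature)
  dA <- bw$d
  A <- fw$cache$acts[[loc$feature]]
  if (any(!is.finite(dA))) abort("non-finite gradients in Grad-CAM backward pass")
  alpha <- apply(dA, 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) cam <- cam + alpha[k] * A[, , k]
  cam <- pmax(cam, 0)
  up <- bilinear_upsample(cam, dim(x)[1], dim(x)[2])
  up <- pmax(up, 0) # guard tiny negative interpolation residue
  if (max(up) > 0) up <- up / max(up)
  new_relevance_map(up, "grad_cam", loc$resolved, target_class)
}

#' Guided backpropagation saliency
#'
#' Input-gradient saliency in which every ReLU backward pass zeroes the
#' gradient wherever the forward activation or the incoming gradient is
#' negative. The signed per-channel gradients are reduced to a per-pixel
#' magnitude (max over channels of the absolute value). Models without ReLU
#' nonlinearities fall back to the plain input gradient with a warning.
#'
#' @inheritParams grad_cam
#' @return A `relevance_map` of nonnegative magnitudes (not normalised).
#' @export
guided_backprop <- function(model, image, target_class = "positive") {
  x <- prepare_input(model, image)
  fw <- cnn_forward(model, x)
  has_relu <- any(purrr::map_chr(model$layers, "type") == "relu")
  if (!has_relu) {
    warn("model has no ReLU layers; returning the plain input gradient magnitude")
  }
  dlogits <- as.numeric(seq_along(fw$logits) == target_class_index(model, target_class))
  bw <- cnn_backward(model, fw$cache, dlogits, stop_after = 0L, guided = has_relu)
  mag <- apply(abs(bw$d), c(1, 2), max)
  new_relevance_map(mag, "guided_backprop", NA_character_, target_class)
}

#' Guided Grad-CAM relevance map
#'
#' Elementwise product of the upsampled Grad-CAM map and the guided
#' backpropagation magnitude, max-normalised to `[0, 1]`: class-discriminative
#' like Grad-CAM, at pixel resolution like guided backpropagation.
#'
#' @inheritParams grad_cam
#' @return A `relevance_map`.
#' @export
guided_grad_cam <- function(model, image, target_class = "positive",
                            layer_name = "conv_last") {
  gc <- grad_cam(model, image, target_class, layer_name)
  gb <- guided_backprop(model, image, target_class)
  values <- gc$values * gb$values
  if (max(values) > 0) values <- values / max(values)
  new_relevance_map(values, "guided_grad_cam", gc$layer_name, target_class)
}

#' @export
tidy.relevance_map <- function(x, ...) {
  v <- x$values
  tibble(
    row = rep(seq_len(nrow(v)), ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    relevance = as.vector(v)
  )
}

#' @export
autoplot.relevance_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data$relevance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (%s)", object$method,
                                  object$layer_name %||% "input"),
                  x = NULL, y = NULL, fill = "relevance") +
    ggplot2::theme_minimal()
}

#' Write a relevance map to disk
#'
#' @param map A `relevance_map`.
#' @param path Output path; `.png` gives an 8-bit grey PNG of the normalised
#'   map, anything else a TSV matrix.
#' @return Invisibly, `path`.
#' @export
write_relevance_map <- function(map, path) {
  if (grepl("\\.png$", path)) {
    v <- map$values
    if (max(v) > 0) v <- v / max(v)
    png::writePNG(v, path)
  } else {
    write.table(map$values, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
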