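# Shared fixtures: small scene configs, hand-weighted toy networks for the
# XAI oracles, and prediction-record builders.

small_scene <- function(...) {
  scene_config(image_side = 48, ...)
}

# A one-conv-layer toy net: 4x4 single-channel input, conv (2 channels),
# ReLU, flatten, dense to 2 logits. Weights set by the caller so relevance
# maps have hand-derivable closed forms.
toy_net_1conv <- function(conv_w, conv_b = c(0, 0), dense_w, dense_b = c(0, 0),
                          side = 4L) {
  layers <- list(
    list(type = "conv", name = "conv1", cin = 1L, cout = 2L,
         W = conv_w, b = conv_b),
    list(type = "relu", name = "relu1"),
    list(type = "flatten", name = "flatten"),
    list(type = "dense", name = "fc", W = dense_w, b = dense_b)
  )
  new_cnn(layers, side, 1L, c(conv_shallow = "conv1", conv_last = "conv1"))
}

# Two-conv toy net with a pool between, for depth-contrast checks.
toy_net_2conv <- function(side = 8L, seed = 5) {
  set.seed(seed)
  layers <- list(
    list(type = "conv", name = "conv1", cin = 1L, cout = 2L,
         W = matrix(rnorm(9 * 2, 0, 0.5), 9, 2), b = c(0, 0)),
    list(type = "relu", name = "relu1"),
    list(type = "pool", name = "pool1"),
    list(type = "conv", name = "conv2", cin = 2L, cout = 3L,
         W = matrix(rnorm(9 * 2 * 3, 0, 0.5), 18, 3), b = rep(0, 3)),
    list(type = "relu", name = "relu2"),
    list(type = "flatten", name = "flatten"),
    list(type = "dense", name = "fc",
         W = matrix(rnorm((side / 2)^2 * 3 * 2, 0, 0.5), (side / 2)^2 * 3, 2),
         b = c(0, 0))
  )
  new_cnn(layers, side, 1L, c(conv_shallow = "conv1", conv_last = "conv2"))
}

records_tbl <- function(ids, conf, model_id = "A", true_label = NULL) {
  tibble::tibble(
    fruit_id = ids,
    model_id = model_id,
    confidence_positive = conf,
    predicted_label = ifelse(conf >= 0.5, "positive", "negative"),
    true_label = true_label %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force oracle for the joint threshold search: full enumeration with
# the same tie rules, written independently of the implementation.
threshold_search_oracle <- function(conf_a, conf_b, truth_pos, min_pp) {
  grid_a <- sort(unique(c(0.5, conf_a[conf_a >= 0.5])))
  grid_b <- sort(unique(c(0.5, conf_b[conf_b >= 0.5])))
  best <- NULL
  for (ta in grid_a) for (tb in grid_b) {
    call <- conf_a >= ta & conf_b >= tb
    npos <- sum(call)
    prec <- if (npos > 0) sum(call & truth_pos) / npos else NA_real_
    ok <- if (min_pp <= 0) TRUE else isTRUE(prec >= min_pp)
    if (!ok) next
    acc <- mean(call == truth_pos)
    pc <- if (is.na(prec)) -1 else prec
    if (is.null(best) || acc > best$acc ||
        (acc == best$acc && pc > best$pc) ||
        (acc == best$acc && pc == best$pc &&
           (ta < best$ta || (ta == best$ta && tb < best$tb)))) {
      best <- list(ta = ta, tb = tb, acc = acc, prec = prec, pc = pc)
    }
  }
  best
}

# Brute-force mean-relevance window scan used as the geometry oracle.
window_scan_oracle <- function(values, mask, side, maximize = TRUE,
                               exclude_center = NULL, min_sep = 0) {
  H <- nrow(values); W <- ncol(values)
  best <- NULL
  for (r0 in seq_len(H - side + 1)) for (c0 in seq_len(W - side + 1)) {
    rows <- r0:(r0 + side - 1); cols <- c0:(c0 + side - 1)
    if (!all(mask[rows, cols])) next
    if (!is.null(exclude_center)) {
      ctr <- c(r0 + side / 2, c0 + side / 2)
      if (sqrt(sum((ctr - exclude_center)^2)) < min_sep) next
    }
    m <- mean(values[rows, cols])
    better <- if (is.null(best)) TRUE
      else if (maximize) m > best$mean + 1e-12 else m < best$mean - 1e-12
    if (better) best <- list(row0 = r0, col0 = c0, mean = m)
  }
  best
}
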