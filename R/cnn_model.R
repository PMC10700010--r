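# Small VGG-style binary classifier: stacked 3x3 convolution + ReLU + 2x2
# max-pool blocks, a flatten, and a two-way softmax head, trained from
# scratch with stochastic gradient descent (learning rate 0.001, categorical
# cross-entropy, class weights).

CLASS_LEVELS <- c("negative", "positive")

#' Architecture of the small VGG-style binary classifier
#'
#' One convolution per block (3x3, padding 1) followed by ReLU and 2x2
#' max-pooling, then flatten and a two-way softmax head. At least two
#' convolutional layers at distinct depths must be named, so the
#' coarse-vs-fine Grad-CAM contrast (deep last layer versus a shallower
#' layer with a finer spatial grid) can be reproduced.
#'
#' @param input_side Input image side, pixels.
#' @param block_widths Integer vector of per-block channel counts.
#' @param named_layers Named character vector mapping role names (at least
#'   `conv_last` and `conv_shallow`) to internal conv layer names
#'   (`"conv1"`, `"conv2"`, ...).
#' @return A `model_spec` list.
#' @export
model_spec <- function(input_side = 224,
                       block_widths = c(8L, 16L, 32L, 32L),
                       named_layers = c(
                         conv_shallow = paste0("conv", max(1L, length(block_widths) - 1L)),
                         conv_last = paste0("conv", length(block_widths))
                       )) {
  assert_scalar_number(input_side, "input_side", lower = 4)
  stopifnot(length(block_widths) >= 1, all(block_widths >= 1))
  conv_names <- paste0("conv", seq_along(block_widths))
  if (!all(named_layers %in% conv_names)) {
    abort("`named_layers` must refer to existing conv layers")
  }
  if (length(unique(named_layers)) < 2) {
    abort("at least two named convolutional layers at distinct depths are required")
  }
  structure(
    list(input_side = as.integer(input_side),
         block_widths = as.integer(block_widths),
         named_layers = named_layers),
    class = "model_spec"
  )
}

#' Training protocol configuration
#'
#' Mirrors the study protocol: stochastic gradient descent at learning rate
#' 0.001, categorical cross-entropy, 20-100 epochs, class weighting, and a
#' 3:1 train:validation split handled by [split_train_val()]. Momentum,
#' batch size and the augmentation details are free protocol choices.
#'
#' @param epochs Number of epochs (20-100 in the reference protocol; smaller
#'   values are accepted for smoke tests).
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param batch_size Minibatch size.
#' @param class_weights Named numeric weights for `negative`/`positive`;
#'   `NULL` means `n / (2 * n_class)` computed from the training set.
#' @param augment Apply random horizontal/vertical flips and small shifts.
#' @param shift_max Maximum augmentation shift, pixels.
#' @param seed Seed controlling initialisation, batch order and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, learning_rate = 0.001, momentum = 0.9,
                         batch_size = 16L, class_weights = NULL,
                         augment = TRUE, shift_max = 2L, seed = 1L) {
  assert_scalar_number(epochs, "epochs", lower = 1)
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-8)
  assert_scalar_number(momentum, "momentum", 0, 0.999)
  if (!is.null(class_weights)) {
    stopifnot(all(CLASS_LEVELS %in% names(class_weights)), all(class_weights > 0))
  }
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         momentum = momentum, batch_size = as.integer(batch_size),
         class_weights = class_weights, augment = isTRUE(augment),
         shift_max = as.integer(shift_max), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Assemble a CNN from explicit layers
#'
#' Low-level constructor used internally and by toy-network tests of the
#' explainability code. `layers` follow the internal layer list format
#' (`type` in `conv`, `relu`, `pool`, `flatten`, `dense`; conv weights as a
#' `9*cin x cout` matrix in im2col order, dense weights as
#' `n_features x n_out`).
#'
#' @param layers List of layer definitions.
#' @param input_side Input side, pixels.
#' @param input_channels Input channel count.
#' @param named_layers Named character vector of conv layer names.
#' @param center Subtract 0.5 from inputs before the forward pass.
#' @return A `cnn_classifier` (untrained).
#' @export
new_cnn <- function(layers, input_side, input_channels = 3L,
                    named_layers = character(), center = FALSE) {
  structure(
    list(layers = layers, input_side = as.integer(input_side),
         input_channels = as.integer(input_channels),
         named_layers = named_layers, center = isTRUE(center),
         class_levels = CLASS_LEVELS, model_id = "A", curves = NULL),
    class = "cnn_classifier"
  )
}

conv_layer <- function(name, cin, cout, seed_scale = 1) {
  list(type = "conv", name = name, cin = cin, cout = cout,
       W = matrix(rnorm(9 * cin * cout, 0, seed_scale * sqrt(2 / (9 * cin))),
                  9 * cin, cout),
       b = rep(0, cout))
}

#' @keywords internal
#' @noRd
build_cnn <- function(spec, seed = 1L, input_channels = 3L) {
  set.seed(as.integer(seed))
  layers <- list()
  cin <- input_channels
  side <- spec$input_side
  for (i in seq_along(spec$block_widths)) {
    cout <- spec$block_widths[i]
    layers <- c(layers, list(
      conv_layer(paste0("conv", i), cin, cout),
      list(type = "relu", name = paste0("relu", i)),
      list(type = "pool", name = paste0("pool", i))
    ))
    cin <- cout
    side <- side %/% 2L
  }
  if (side < 1) abort("too many pooling blocks for this input side")
  n_feat <- side * side * cin
  layers <- c(layers, list(
    list(type = "flatten", name = "flatten"),
    list(type = "dense", name = "fc",
         W = matrix(rnorm(n_feat * 2, 0, sqrt(1 / n_feat)), n_feat, 2),
         b = rep(0, 2))
  ))
  new_cnn(layers, spec$input_side, input_channels, spec$named_layers, center = TRUE)
}

#' @keywords internal
#' @noRd
prepare_input <- function(model, image) {
  x <- if (inherits(image, "labeled_image")) image$pixels else image
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[1] != model$input_side || dim(x)[2] != model$input_side ||
      dim(x)[3] != model$input_channels) {
    abort(sprintf("image shape %s does not match model input %dx%dx%d",
                  paste(dim(x), collapse = "x"),
                  model$input_side, model$input_side, model$input_channels))
  }
  if (model$center) x - 0.5 else x
}

augment_image <- function(x, shift_max, fill) {
  if (runif(1) < 0.5) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  if (runif(1) < 0.5) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  if (shift_max > 0) {
    sh <- sample(seq(-shift_max, shift_max), 2, replace = TRUE)
    if (any(sh != 0)) {
      H <- dim(x)[1]; W <- dim(x)[2]
      out <- array(fill, dim(x))
      src_r <- seq_len(H) - sh[1]; src_c <- seq_len(W) - sh[2]
      ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
      out[which(ok_r), which(ok_c), ] <- x[src_r[ok_r], src_c[ok_c], , drop = FALSE]
      x <- out
    }
  }
  x
}

#' Stratified train/validation split
#'
#' Randomly partitions a labelled dataset into disjoint, exhaustive train and
#' validation sets, stratified by class, at a `ratio`:1 ratio (3:1 in the
#' reference protocol).
#'
#' @param dataset A `fruit_dataset` or list of `labeled_image`.
#' @param ratio Train:validation ratio (train parts per one validation part).
#' @param seed Seed for the shuffle.
#' @return List with elements `train` and `val`.
#' @export
split_train_val <- function(dataset, ratio = 3, seed = 1L) {
  stopifnot(length(dataset) > 0)
  labels <- purrr::map_chr(dataset, "label")
  if (length(unique(labels)) < 2) {
    abort("both classes must be present in the dataset")
  }
  set.seed(as.integer(seed))
  train_idx <- integer()
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n_train <- round(length(idx) * ratio / (ratio + 1))
    train_idx <- c(train_idx, idx[seq_len(n_train)])
  }
  train_idx <- sort(train_idx)
  list(train = dataset[train_idx], val = dataset[setdiff(seq_along(dataset), train_idx)])
}

#' Train the binary CNN classifier
#'
#' Minibatch SGD with momentum on the class-weighted categorical
#' cross-entropy. Returns the trained model with per-epoch loss/accuracy
#' curves for the training set and, if given, the validation set.
#'
#' @param train List of `labeled_image` for training (both classes present).
#' @param val Optional validation list of `labeled_image`.
#' @param spec A [model_spec()].
#' @param cfg A [train_config()].
#' @param model_id Identifier stored on the model (e.g. `"A"` or `"B"`).
#' @return A trained `cnn_classifier`; `$curves` holds a tibble with columns
#'   `epoch`, `set`, `loss`, `accuracy`.
#' @export
train_classifier <- function(train, val = NULL, spec = model_spec(),
                             cfg = train_config(), model_id = "A") {
  labels <- purrr::map_chr(train, "label")
  if (!all(CLASS_LEVELS %in% labels)) {
    abort("both classes must be present in the training set")
  }
  model <- build_cnn(spec, seed = cfg$seed)
  model$model_id <- model_id
  y <- match(labels, CLASS_LEVELS)
  if (is.null(cfg$class_weights)) {
    n <- length(y)
    counts <- tabulate(y, 2L)
    w_class <- n / (2 * counts)
  } else {
    w_class <- unname(cfg$class_weights[CLASS_LEVELS])
  }
  xs <- purrr::map(train, ~ prepare_input(model, .x))
  fill <- -0.5 * model$center # background after centring is approx -0.5

  velocity <- purrr::map(model$layers, function(l) {
    if (!is.null(l$W)) list(vW = l$W * 0, vb = l$b * 0)
  })
  curves <- list()
  set.seed(as.integer(cfg$seed) + 1L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(xs))
    epoch_loss <- 0; epoch_correct <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      gacc <- NULL
      for (j in batch) {
        x <- xs[[j]]
        if (cfg$augment) x <- augment_image(x, cfg$shift_max, fill)
        fw <- cnn_forward(model, x)
        p <- fw$probs
        yi <- y[j]
        loss <- -w_class[yi] * log(max(p[yi], 1e-12))
        if (!is.finite(loss)) {
          abort(sprintf("non-finite loss at epoch %d (diverged); lower the learning rate", epoch))
        }
        epoch_loss <- epoch_loss + loss
        epoch_correct <- epoch_correct + (which.max(p) == yi)
        dlogits <- w_class[yi] * (p - (seq_len(2) == yi))
        bw <- cnn_backward(model, fw$cache, dlogits, want_params = TRUE)
        if (is.null(gacc)) {
          gacc <- bw$grads
        } else {
          for (li in seq_along(gacc)) {
            if (!is.null(gacc[[li]])) {
              gacc[[li]]$dW <- gacc[[li]]$dW + bw$grads[[li]]$dW
              gacc[[li]]$db <- gacc[[li]]$db + bw$grads[[li]]$db
            }
          }
        }
      }
      nb <- length(batch)
      for (li in seq_along(model$layers)) {
        if (!is.null(gacc[[li]])) {
          velocity[[li]]$vW <- cfg$momentum * velocity[[li]]$vW -
            cfg$learning_rate * gacc[[li]]$dW / nb
          velocity[[li]]$vb <- cfg$momentum * velocity[[li]]$vb -
            cfg$learning_rate * gacc[[li]]$db / nb
          model$layers[[li]]$W <- model$layers[[li]]$W + velocity[[li]]$vW
          model$layers[[li]]$b <- model$layers[[li]]$b + velocity[[li]]$vb
        }
      }
    }
    curves[[length(curves) + 1L]] <- tibble(
      epoch = epoch, set = "train",
      loss = epoch_loss / length(xs), accuracy = epoch_correct / length(xs)
    )
    if (!is.null(val) && length(val) > 0) {
      vp <- predict(model, val)
      vy <- match(purrr::map_chr(val, "label"), CLASS_LEVELS)
      vprob <- ifelse(vy == 2L, vp$confidence_positive, 1 - vp$confidence_positive)
      vloss <- mean(-w_class[vy] * log(pmax(vprob, 1e-12)))
      vacc <- mean((vp$confidence_positive >= 0.5) == (vy == 2L))
      curves[[length(curves) + 1L]] <- tibble(
        epoch = epoch, set = "val", loss = vloss, accuracy = vacc
      )
    }
  }
  model$curves <- dplyr::bind_rows(curves)
  model
}

#' Predict fate confidences for images
#'
#' Applies the trained model to each image at the 0.5 decision threshold
#' (a confidence of exactly 0.5 is called positive).
#'
#' @param object A trained `cnn_classifier`.
#' @param images A `fruit_dataset` or list of `labeled_image` / arrays.
#' @param threshold Decision threshold on the positive-class confidence.
#' @param ... Unused.
#' @return A tibble with one row per image: `fruit_id`, `model_id`,
#'   `confidence_positive`, `predicted_label`, `true_label` (NA when the
#'   input carries no label).
#' @export
predict.cnn_classifier <- function(object, images, threshold = 0.5, ...) {
  purrr::imap_dfr(images, function(img, i) {
    x <- prepare_input(object, img)
    p <- cnn_forward(object, x, keep_cache = FALSE)$probs
    conf <- p[2]
    tibble(
      fruit_id = if (inherits(img, "labeled_image")) img$fruit_id else paste0("image_", i),
      model_id = object$model_id,
      confidence_positive = conf,
      predicted_label = ifelse(conf >= threshold, "positive", "negative"),
      true_label = if (inherits(img, "labeled_image")) img$label else NA_character_
    )
  })
}

#' Evaluate prediction records
#'
#' Computes the ROC curve and its AUC, overall accuracy, per-class precision
#' and recall, and the confusion matrix at the given threshold.
#'
#' @param records Prediction tibble from [predict.cnn_classifier()], with
#'   `true_label` filled in and both classes present.
#' @param threshold Decision threshold.
#' @return A `classifier_metrics` list: `auc`, `accuracy`, `precision`,
#'   `recall` (named by class), `confusion` (2x2 matrix), `roc` (tibble with
#'   `fpr`, `tpr`, `threshold`), `n`.
#' @export
evaluate_predictions <- function(records, threshold = 0.5) {
  stopifnot(all(c("confidence_positive", "true_label") %in% names(records)))
  truth <- records$true_label
  if (any(is.na(truth))) abort("records must carry true labels")
  if (length(unique(truth)) < 2) {
    abort("AUC undefined: only one class present in the records")
  }
  conf <- records$confidence_positive
  roc_obj <- pROC::roc(response = truth, predictor = conf,
                       levels = CLASS_LEVELS, direction = "<", quiet = TRUE)
  pred <- ifelse(conf >= threshold, "positive", "negative")
  confusion <- table(
    predicted = factor(pred, CLASS_LEVELS),
    truth = factor(truth, CLASS_LEVELS)
  )
  precision <- vapply(CLASS_LEVELS, function(cl) {
    called <- sum(confusion[cl, ])
    if (called == 0) NA_real_ else confusion[cl, cl] / called
  }, numeric(1))
  recall <- vapply(CLASS_LEVELS, function(cl) {
    actual <- sum(confusion[, cl])
    if (actual == 0) NA_real_ else confusion[cl, cl] / actual
  }, numeric(1))
  structure(
    list(
      auc = as.numeric(pROC::auc(roc_obj)),
      accuracy = mean(pred == truth),
      precision = precision,
      recall = recall,
      confusion = unclass(confusion),
      roc = tibble(
        fpr = 1 - roc_obj$specificities,
        tpr = roc_obj$sensitivities,
        threshold = roc_obj$thresholds
      ) |> dplyr::arrange(.data$fpr, .data$tpr),
      threshold = threshold,
      n = nrow(records)
    ),
    class = "classifier_metrics"
  )
}

#' Penultimate-layer feature embeddings
#'
#' Returns the flattened activations feeding the fully connected head, one
#' row per image; the usual input to a 2-D projection such as tSNE.
#'
#' @param model A trained `cnn_classifier`.
#' @param images List of `labeled_image` or arrays.
#' @return Numeric matrix, images in rows.
#' @export
extract_embeddings <- function(model, images) {
  flat_idx <- which(purrr::map_chr(model$layers, "type") == "flatten")
  if (length(flat_idx) == 0) abort("model has no flatten layer")
  emb <- purrr::map(images, function(img) {
    fw <- cnn_forward(model, prepare_input(model, img))
    fw$cache$acts[[flat_idx[length(flat_idx)]]]
  })
  do.call(rbind, emb)
}

#' @export
tidy.cnn_classifier <- function(x, ...) {
  if (is.null(x$curves)) return(tibble())
  x$curves
}

#' @export
glance.cnn_classifier <- function(x, ...) {
  n_par <- sum(purrr::map_dbl(x$layers, ~ length(.x$W) + length(.x$b)))
  last_val <- if (!is.null(x$curves)) dplyr::filter(x$curves, .data$set == "val") else tibble()
  tibble(
    model_id = x$model_id,
    n_parameters = n_par,
    epochs = if (is.null(x$curves)) NA_integer_ else max(x$curves$epoch),
    val_accuracy = if (nrow(last_val)) last_val$accuracy[which.max(last_val$epoch)] else NA_real_
  )
}

#' @export
tidy.classifier_metrics <- function(x, ...) {
  tibble(
    class = rep(CLASS_LEVELS, 2),
    metric = rep(c("precision", "recall"), each = 2),
    value = c(x$precision, x$recall)
  )
}

#' @export
glance.classifier_metrics <- function(x, ...) {
  tibble(auc = x$auc, accuracy = x$accuracy,
         positive_precision = x$precision[["positive"]],
         negative_precision = x$precision[["negative"]],
         n = x$n)
}

#' @export
autoplot.classifier_metrics <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("ROC curve (AUC = %.3f, n = %d)", object$auc, object$n)
    ) +
    ggplot2::theme_minimal()
}
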