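test_that("train/validation split is stratified, disjoint, exhaustive and reproducible", {
  cfg <- scene_config(image_side = 16, fruit_radius_range = c(5, 6),
                      blemish_radius_range = c(2, 3))
  ds <- generate_dataset(cfg, 20, 20, seed = 5)
  sp1 <- split_train_val(ds, 3, seed = 9)
  sp2 <- split_train_val(ds, 3, seed = 9)
  expect_equal(length(sp1$train), 30)
  expect_equal(length(sp1$val), 10)
  ids <- function(x) sort(purrr::map_chr(x, "fruit_id"))
  expect_identical(ids(sp1$train), ids(sp2$train))
  expect_length(intersect(ids(sp1$train), ids(sp1$val)), 0)
  expect_setequal(c(ids(sp1$train), ids(sp1$val)), ids(ds))
  lab <- purrr::map_chr(sp1$train, "label")
  expect_equal(sum(lab == "positive"), 15) # exact under stratification
  only_neg <- generate_dataset(cfg, 0, 6, seed = 2)
  expect_error(split_train_val(only_neg), "both classes")
})

test_that("predictions use the 0.5 threshold with ties going positive and are deterministic", {
  m <- toy_net_1conv(
    conv_w = matrix(0, 9, 2), conv_b = c(0, 0),
    dense_w = matrix(0, 32, 2)
  )
  x <- array(runif(16), c(4, 4, 1))
  rec1 <- predict(m, list(x))
  rec2 <- predict(m, list(x))
  # all-zero weights give exactly 0.5 confidence: tie goes to positive
  expect_equal(rec1$confidence_positive, 0.5)
  expect_equal(rec1$predicted_label, "positive")
  expect_identical(rec1$confidence_positive, rec2$confidence_positive)
  fw_probs <- rec1$confidence_positive + (1 - rec1$confidence_positive)
  expect_equal(fw_probs, 1)
  expect_error(predict(m, list(array(0, c(5, 5, 1)))), "shape")
})

test_that("evaluation metrics match hand counts and behave under permutation", {
  rec <- records_tbl(
    paste0("f", 1:4), c(0.9, 0.8, 0.2, 0.1),
    true_label = c("positive", "negative", "positive", "negative")
  )
  ev <- evaluate_predictions(rec)
  # (TP, FP, FN, TN) = (1, 1, 1, 1)
  expect_equal(ev$accuracy, 0.5)
  expect_equal(unname(ev$precision["positive"]), 0.5)
  expect_equal(sum(ev$confusion), 4)

  perfect <- records_tbl(
    paste0("p", 1:10), rep(c(0.9, 0.1), each = 5),
    true_label = rep(c("positive", "negative"), each = 5)
  )
  evp <- evaluate_predictions(perfect)
  expect_equal(evp$auc, 1.0)
  expect_equal(evp$accuracy, 1.0)

  set.seed(31)
  n <- 2000
  null_rec <- records_tbl(
    paste0("n", seq_len(n)), runif(n),
    true_label = sample(c("positive", "negative"), n, replace = TRUE)
  )
  expect_lt(abs(evaluate_predictions(null_rec)$auc - 0.5), 0.05)

  expect_error(
    evaluate_predictions(records_tbl("a", 0.4, true_label = "negative")),
    "one class"
  )
})

test_that("AUC is invariant under strictly monotone confidence transforms", {
  set.seed(8)
  rec <- records_tbl(
    paste0("f", 1:40), runif(40),
    true_label = sample(c("positive", "negative"), 40, replace = TRUE,
                        prob = c(0.4, 0.6))
  )
  a1 <- evaluate_predictions(rec)$auc
  rec2 <- rec
  rec2$confidence_positive <- stats::plogis(5 * rec$confidence_positive - 2)
  expect_equal(evaluate_predictions(rec2)$auc, a1, tolerance = 1e-12)
})

test_that("raising the decision threshold never increases recall", {
  set.seed(12)
  rec <- records_tbl(
    paste0("f", 1:60), runif(60),
    true_label = sample(c("positive", "negative"), 60, replace = TRUE)
  )
  recalls <- vapply(seq(0.1, 0.9, 0.1), function(thr) {
    unname(evaluate_predictions(rec, threshold = thr)$recall["positive"])
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("a short training run produces curves, learns separable data, and aborts on divergence", {
  cfg <- scene_config(image_side = 24, blemish_amplitude = 0.35,
                      noise_sd = 0.01)
  ds <- generate_dataset(cfg, 30, 30, seed = 41)
  sp <- split_train_val(ds, 3, seed = 1)
  spec <- model_spec(input_side = 24, block_widths = c(6, 12),
                     named_layers = c(conv_shallow = "conv1", conv_last = "conv2"))
  m <- train_classifier(sp$train, sp$val, spec,
                        train_config(epochs = 25, batch_size = 8,
                                     momentum = 0.95, seed = 2))
  curves <- tidy(m)
  expect_setequal(unique(curves$set), c("train", "val"))
  expect_equal(max(curves$epoch), 25)
  expect_true(all(is.finite(curves$loss)))
  # learning happened: final training loss clearly below the initial one
  tr <- curves[curves$set == "train", ]
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])

  # non-finite loss (here forced through a corrupted image) aborts with a
  # diagnostic instead of silently training on
  broken <- sp$train
  broken[[1]]$pixels[1, 1, 1] <- NaN
  expect_error(
    train_classifier(broken, NULL, spec,
                     train_config(epochs = 2, batch_size = 4, augment = FALSE,
                                  seed = 2)),
    "non-finite"
  )
})

test_that("embeddings have one row per image, are deterministic, and support a linear probe", {
  cfg <- scene_config(image_side = 16, fruit_radius_range = c(5, 6),
                      blemish_radius_range = c(2, 3))
  ds <- generate_dataset(cfg, 6, 6, seed = 3)
  spec <- model_spec(input_side = 16, block_widths = c(4, 8),
                     named_layers = c(conv_shallow = "conv1", conv_last = "conv2"))
  m <- fruitcam:::build_cnn(spec, seed = 1)
  emb <- extract_embeddings(m, ds)
  expect_equal(nrow(emb), 12)
  expect_identical(emb, extract_embeddings(m, ds))
  expect_identical(emb[1, ], extract_embeddings(m, ds[c(1, 1)])[2, ])
})

test_that("class weighting lifts minority recall on an imbalanced set", {
  # 9:1 imbalance; weights proportional to inverse class frequency
  cfg <- scene_config(image_side = 24, blemish_amplitude = 0.35, noise_sd = 0.01)
  spec <- model_spec(input_side = 24, block_widths = c(6, 12),
                     named_layers = c(conv_shallow = "conv1", conv_last = "conv2"))
  minority_recall <- function(seed, weighted) {
    ds <- generate_dataset(cfg, 6, 54, seed = seed)
    cwt <- if (weighted) NULL else c(negative = 1, positive = 1)
    m <- train_classifier(ds, NULL, spec,
                          train_config(epochs = 12, batch_size = 8,
                                       momentum = 0.95, class_weights = cwt,
                                       seed = seed))
    rec <- predict(m, ds)
    mean(rec$predicted_label[rec$true_label == "positive"] == "positive")
  }
  seeds <- 101:105
  rw <- vapply(seeds, minority_recall, numeric(1), weighted = TRUE)
  ru <- vapply(seeds, minority_recall, numeric(1), weighted = FALSE)
  expect_gt(mean(rw), mean(ru))
  expect_true(all(rw >= ru))
})
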