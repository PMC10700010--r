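# Config-driven orchestration of the full loop: simulate images -> train the
# two camera models -> predict and ensemble -> explain -> extract sampling
# regions -> simulate counts conditioned on the selected fruits -> run the
# two-criteria differential-expression comparison -> report. One global seed
# fans out deterministically to per-stage seeds.

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Any entry can be overridden;
#' the defaults give a desk-scale run (small images, few epochs) that
#' completes in minutes. Passing a YAML file path to [run_pipeline()] reads
#' the same structure.
#'
#' @param image_side Image side for all rendered fruits, pixels.
#' @param n_train_pos,n_train_neg Per-camera training-set class counts.
#' @param n_test_pos,n_test_neg Test-set class counts (each test fruit is
#'   rendered under both cameras).
#' @param blemish_amplitude Planted blemish amplitude.
#' @param blemish_placement Band data frame passed to [scene_config()].
#' @param block_widths CNN block widths.
#' @param epochs,batch_size Training protocol knobs.
#' @param k_pos,k_neg Extreme-sample counts for tissue sampling.
#' @param window_side Sampling window side, pixels.
#' @param xai_layer Layer used for guided Grad-CAM (`"conv_shallow"` keeps
#'   the relevance grid fine enough to place a sampling window).
#' @param n_genes Genes in the count simulation.
#' @param n_bins Histogram bins per axis.
#' @return A nested list with class `pipeline_config`.
#' @export
pipeline_config <- function(image_side = 48L,
                            n_train_pos = 40L, n_train_neg = 40L,
                            n_test_pos = 20L, n_test_neg = 20L,
                            blemish_amplitude = 0.2,
                            blemish_placement = data.frame(
                              lo = c(0.75, 0.0), hi = c(1.0, 0.1),
                              weight = c(0.5, 0.5)
                            ),
                            block_widths = c(8L, 16L, 32L),
                            epochs = 15L, batch_size = 8L,
                            k_pos = 4L, k_neg = 4L,
                            window_side = NULL,
                            xai_layer = "conv_shallow",
                            n_genes = 2000L,
                            n_bins = 20L) {
  structure(as.list(environment()), class = c("pipeline_config", "list"))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$blemish_placement)) {
      raw$blemish_placement <- as.data.frame(raw$blemish_placement)
    }
    config <- do.call(pipeline_config, raw)
  }
  stopifnot(inherits(config, "pipeline_config"))
  config
}

stage_artifact <- function(manifest, stage, name, path) {
  manifest$stages[[stage]]$artifacts[[name]] <-
    list(path = path, md5 = unname(tools::md5sum(path)))
  manifest
}

write_tsv_artifact <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full explainable-CNN-to-transcriptome pipeline
#'
#' Executes all seven stages on synthetic data and writes every tabular
#' artifact (TSV) plus a JSON run manifest recording per-stage seeds and
#' content hashes of all files. Reruns with the same config and seed
#' reproduce all artifacts bit-exactly.
#'
#' @param config A [pipeline_config()] or path to a YAML file of the same
#'   structure.
#' @param output_dir Directory to write artifacts into.
#' @param seed Single global seed; per-stage seeds are derived from it.
#' @return A `pipeline_run`: list with `manifest`, and in-memory results
#'   `models`, `metrics`, `ensemble`, `hist`, `bands`, `regions`, `sim`,
#'   `de` (tables, overlap, pca, enrichment).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir, seed = 1L) {
  config <- read_pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list())
  run_stage <- function(name, idx, fn) {
    stage_seed <- derive_seed(seed, idx)
    manifest$stages[[name]] <<- list(seed = stage_seed, artifacts = list())
    tryCatch(fn(stage_seed), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  window_side <- config$window_side %||% max(8L, round(config$image_side / 7))

  # 1. simulate images ------------------------------------------------------
  scfg <- scene_config(image_side = config$image_side,
                       blemish_amplitude = config$blemish_amplitude,
                       blemish_placement = config$blemish_placement)
  data <- run_stage("simulate_images", 1L, function(s) {
    train_a <- generate_dataset(scfg, config$n_train_pos, config$n_train_neg,
                                camera_id = "A", seed = s, id_prefix = "trainA")
    train_b <- generate_dataset(scfg, config$n_train_pos, config$n_train_neg,
                                camera_id = "B", seed = s + 1, id_prefix = "trainB")
    test_a <- generate_dataset(scfg, config$n_test_pos, config$n_test_neg,
                               camera_id = "A", seed = s + 2, id_prefix = "test")
    seeds <- attr(test_a, "fruit_seeds")
    test_b <- purrr::imap(test_a, function(img, i) {
      render_fruit(scfg, img$label, "B", seed = seeds[[img$fruit_id]],
                   fruit_id = img$fruit_id)
    })
    list(train_a = train_a, train_b = train_b, test_a = test_a, test_b = test_b)
  })
  manifest <- stage_artifact(
    manifest, "simulate_images", "test_manifest",
    write_tsv_artifact(image_manifest(data$test_a),
                       file.path(output_dir, "test_manifest.tsv"))
  )

  # 2. train models A and B -------------------------------------------------
  trained <- run_stage("train", 2L, function(s) {
    spec <- model_spec(input_side = config$image_side,
                       block_widths = config$block_widths)
    fit_one <- function(dataset, id, s_off) {
      split <- split_train_val(dataset, ratio = 3, seed = s + s_off)
      cfg <- train_config(epochs = config$epochs, batch_size = config$batch_size,
                          seed = s + s_off)
      model <- train_classifier(split$train, split$val, spec, cfg, model_id = id)
      val_records <- predict(model, split$val)
      list(model = model, metrics = evaluate_predictions(val_records))
    }
    list(A = fit_one(data$train_a, "A", 0L), B = fit_one(data$train_b, "B", 1L))
  })
  manifest <- stage_artifact(
    manifest, "train", "curves",
    write_tsv_artifact(
      dplyr::bind_rows(A = tidy(trained$A$model), B = tidy(trained$B$model),
                       .id = "model_id"),
      file.path(output_dir, "training_curves.tsv")
    )
  )

  # 3. predict + ensemble ----------------------------------------------------
  ens <- run_stage("ensemble", 3L, function(s) {
    rec_a <- predict(trained$A$model, data$test_a)
    rec_b <- predict(trained$B$model, data$test_b)
    r <- confidence_correlation(rec_a, rec_b)
    thr <- threshold_search(rec_a, rec_b, min_positive_precision = 0.8)
    sel <- select_extreme_samples(rec_a, rec_b, config$k_pos, config$k_neg)
    list(rec_a = rec_a, rec_b = rec_b, r = r, thresholds = thr, selection = sel)
  })
  manifest <- stage_artifact(
    manifest, "ensemble", "predictions",
    write_tsv_artifact(dplyr::bind_rows(ens$rec_a, ens$rec_b),
                       file.path(output_dir, "predictions.tsv"))
  )
  manifest <- stage_artifact(
    manifest, "ensemble", "selection",
    write_tsv_artifact(ens$selection, file.path(output_dir, "selection.tsv"))
  )

  # 4. explain: guided Grad-CAM on predicted positives ----------------------
  xai <- run_stage("explain", 4L, function(s) {
    pos_ids <- ens$rec_a$fruit_id[ens$rec_a$predicted_label == "positive"]
    if (length(pos_ids) == 0) {
      return(list(maps = list(), dmaps = list(), masks = list(), empty = TRUE))
    }
    imgs <- data$test_a[purrr::map_chr(data$test_a, "fruit_id") %in% pos_ids]
    maps <- list(); dmaps <- list(); masks <- list()
    for (img in imgs) {
      mask <- segment_fruit(img)
      maps[[img$fruit_id]] <- guided_grad_cam(trained$A$model, img,
                                              layer_name = config$xai_layer)
      dmaps[[img$fruit_id]] <- normalized_contour_distance(mask)
      masks[[img$fruit_id]] <- mask
    }
    list(maps = maps, dmaps = dmaps, masks = masks, empty = FALSE)
  })
  hist <- NULL; bands <- NULL
  if (!xai$empty) {
    hist <- relevance_histogram(xai$maps, xai$dmaps,
                                n_r = config$n_bins, n_d = config$n_bins)
    bands <- band_relevance_summary(hist)
    manifest <- stage_artifact(
      manifest, "explain", "band_summary",
      write_tsv_artifact(bands, file.path(output_dir, "band_summary.tsv"))
    )
    manifest <- stage_artifact(
      manifest, "explain", "histogram",
      write_tsv_artifact(tidy(hist), file.path(output_dir, "relevance_histogram.tsv"))
    )
  }

  # 5. sampling regions ------------------------------------------------------
  regions <- run_stage("regions", 5L, function(s) {
    sel <- ens$selection
    out <- list()
    n_paired <- 0L
    for (i in seq_len(nrow(sel))) {
      fid <- sel$fruit_id[i]
      img <- data$test_a[[which(purrr::map_chr(data$test_a, "fruit_id") == fid)]]
      mask <- xai$masks[[fid]] %||% segment_fruit(img)
      map <- xai$maps[[fid]] %||% guided_grad_cam(trained$A$model, img,
                                                  layer_name = config$xai_layer)
      dmap <- xai$dmaps[[fid]] %||% normalized_contour_distance(mask)
      cat_f <- if (sel$role[i] == "positive") "RS-F" else "C-F"
      feat <- extract_featured_region(map, mask, window_side, dmap, cat_f, fid)
      out[[length(out) + 1L]] <- feat
      if (sel$role[i] == "positive") {
        nf <- tryCatch(
          extract_nonfeatured_region(map, mask, feat, window_side,
                                     dmap = dmap, fruit_id = fid),
          error = function(e) NULL
        )
        if (!is.null(nf)) {
          out[[length(out) + 1L]] <- nf
          n_paired <- n_paired + 1L
        }
      }
    }
    list(table = dplyr::bind_rows(out), n_paired = n_paired)
  })
  manifest <- stage_artifact(
    manifest, "regions", "regions",
    write_tsv_artifact(regions$table, file.path(output_dir, "regions.tsv"))
  )

  # 6. simulate counts conditioned on the selected fruits -------------------
  sim <- run_stage("simulate_counts", 6L, function(s) {
    ccfg <- count_sim_config(
      n_genes = config$n_genes,
      n_fruits_rs = config$k_pos,
      n_paired = max(3L, min(regions$n_paired, config$k_pos)),
      n_fruits_c = config$k_neg,
      seed = s
    )
    simulate_counts(ccfg)
  })
  manifest <- stage_artifact(
    manifest, "simulate_counts", "sample_meta",
    write_tsv_artifact(sim$sample_meta, file.path(output_dir, "sample_meta.tsv"))
  )

  # 7. differential expression ----------------------------------------------
  de <- run_stage("de", 7L, function(s) {
    r <- rpkm(sim$counts, sim$gene_lengths)
    groups <- sim$sample_meta$group
    keep_i <- filter_expressed(r, groups, c("RS-F", "C-F"))
    keep_ii <- filter_expressed(r, groups, c("RS-F", "RS-NF"))
    tab_i <- de_unpaired(sim$counts[keep_i, ], groups,
                         gene_lengths = sim$gene_lengths[keep_i])
    tab_ii <- de_paired(sim$counts[keep_ii, ], groups, sim$sample_meta$fruit_id,
                        gene_lengths = sim$gene_lengths[keep_ii])
    ov <- overlap_and_concordance(tab_i, tab_ii)
    pca <- pca_expression(r[rowMeans(r) > 1, , drop = FALSE], groups)
    sets <- list(
      planted_i_up = sim$truth$degs_criteria_i_up,
      planted_i_down = sim$truth$degs_criteria_i_down,
      planted_ii_up = sim$truth$degs_criteria_ii_up,
      planted_ii_down = sim$truth$degs_criteria_ii_down
    )
    deg_ii <- tab_ii$gene[tab_ii$fdr < 0.1]
    enr <- enrichment_hypergeometric(deg_ii, sets, tab_ii$gene)
    list(rpkm = r, table_i = tab_i, table_ii = tab_ii, overlap = ov,
         pca = pca, enrichment = enr)
  })
  manifest <- stage_artifact(
    manifest, "de", "criteria_i",
    write_tsv_artifact(de$table_i, file.path(output_dir, "deg_criteria_i.tsv"))
  )
  manifest <- stage_artifact(
    manifest, "de", "criteria_ii",
    write_tsv_artifact(de$table_ii, file.path(output_dir, "deg_criteria_ii.tsv"))
  )
  manifest <- stage_artifact(
    manifest, "de", "enrichment",
    write_tsv_artifact(de$enrichment, file.path(output_dir, "enrichment.tsv"))
  )

  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  structure(
    list(manifest = manifest, manifest_path = manifest_path,
         output_dir = output_dir, config = config,
         models = list(A = trained$A$model, B = trained$B$model),
         metrics = list(A = trained$A$metrics, B = trained$B$metrics),
         ensemble = ens, hist = hist, bands = bands,
         regions = regions$table, sim = sim, de = de),
    class = "pipeline_run"
  )
}

#' Summarise a completed pipeline run
#'
#' Writes the figure set (ROC curves, confidence scatter, H(r,d) heat map,
#' DEG heat map, criteria overlap scatter) under `output_dir/report/` and
#' returns the summary tables. A run with no predicted positives is flagged
#' (no relevance panels can be drawn).
#'
#' @param run A `pipeline_run`.
#' @return List with `summary` (one-row tibble of headline numbers),
#'   `figures` (paths written), and `flags` (character vector of anomalies).
#' @export
report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  fig_dir <- file.path(run$output_dir, "report")
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  flags <- character()
  figures <- character()
  save_fig <- function(plot, name) {
    path <- file.path(fig_dir, name)
    ggplot2::ggsave(path, plot, width = 6, height = 5, dpi = 120)
    figures <<- c(figures, path)
  }
  save_fig(autoplot(run$metrics$A), "roc_model_A.png")
  save_fig(autoplot(run$metrics$B), "roc_model_B.png")
  save_fig(plot_confidence_scatter(run$ensemble$rec_a, run$ensemble$rec_b),
           "confidence_scatter.png")
  if (!is.null(run$hist)) {
    save_fig(autoplot(run$hist), "relevance_histogram.png")
  } else {
    flags <- c(flags, "no predicted positives: relevance histogram panel omitted")
  }
  deg_genes <- run$de$table_i$gene[run$de$table_i$p < 0.05]
  if (length(deg_genes) >= 2) {
    save_fig(plot_deg_heatmap(run$de$rpkm, head(deg_genes, 50),
                              run$sim$sample_meta$group),
             "deg_heatmap.png")
  }
  shared <- intersect(run$de$table_i$gene, run$de$table_ii$gene)
  ov_df <- tibble(
    lfc_i = run$de$table_i$log2fc[match(shared, run$de$table_i$gene)],
    lfc_ii = run$de$table_ii$log2fc[match(shared, run$de$table_ii$gene)]
  )
  save_fig(
    ggplot2::ggplot(ov_df, ggplot2::aes(x = .data$lfc_i, y = .data$lfc_ii)) +
      ggplot2::geom_point(alpha = 0.3) +
      ggplot2::labs(x = "log2FC criteria (i)", y = "log2FC criteria (ii)",
                    title = sprintf("Fold-change concordance (r = %.3f)",
                                    run$de$overlap$r)) +
      ggplot2::theme_minimal(),
    "concordance_scatter.png"
  )
  summary <- tibble(
    auc_A = run$metrics$A$auc, auc_B = run$metrics$B$auc,
    confidence_r = run$ensemble$r,
    ensemble_accuracy = run$ensemble$thresholds$accuracy,
    ensemble_positive_precision = run$ensemble$thresholds$positive_precision,
    modal_band = if (!is.null(run$bands)) {
      run$bands$band[which.max(run$bands$enrichment)]
    } else NA_character_,
    common_up = run$de$overlap$common_up,
    common_down = run$de$overlap$common_down,
    concordance_r = run$de$overlap$r,
    pc1_var_frac = run$de$pca$var_frac[1]
  )
  write.table(summary, file.path(fig_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(summary = summary, figures = figures, flags = flags)
}
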