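# Two-model ensemble: confidence correlation, AND-rule confidence-threshold
# search under a positive-precision constraint, and extreme-confidence sample
# selection for downstream tissue sampling.

join_records <- function(records_a, records_b) {
  stopifnot(all(c("fruit_id", "confidence_positive") %in% names(records_a)),
            all(c("fruit_id", "confidence_positive") %in% names(records_b)))
  joined <- dplyr::inner_join(
    dplyr::select(records_a, "fruit_id",
                  conf_a = "confidence_positive",
                  dplyr::any_of("true_label")),
    dplyr::select(records_b, "fruit_id", conf_b = "confidence_positive"),
    by = "fruit_id"
  )
  if (nrow(joined) < nrow(records_a) || nrow(joined) < nrow(records_b)) {
    warn("records were matched by fruit_id; unmatched rows dropped")
  }
  joined
}

#' Pearson correlation of two models' confidences
#'
#' @param records_a,records_b Prediction tibbles (matched by `fruit_id`).
#' @return Pearson r.
#' @export
confidence_correlation <- function(records_a, records_b) {
  joined <- join_records(records_a, records_b)
  if (nrow(joined) < 3) abort("need at least 3 matched records")
  if (sd(joined$conf_a) == 0 || sd(joined$conf_b) == 0) {
    abort("zero variance in one model's confidences; correlation undefined")
  }
  cor(joined$conf_a, joined$conf_b)
}

#' Joint confidence-threshold search
#'
#' A fruit is called positive when both models exceed their thresholds
#' (`conf_A >= t_A` AND `conf_B >= t_B`, the AND filtering rule). Thresholds
#' are searched on the grid of observed confidences at or above the default
#' 0.5, plus 0.5 itself (the accuracy surface is piecewise constant between
#' observed values). The returned pair maximises accuracy subject to positive
#' precision at or above `min_positive_precision`; ties are broken by higher
#' positive precision, then lower `t_A`, then lower `t_B`.
#'
#' @param records_a,records_b Prediction tibbles matched by `fruit_id`;
#'   `records_a` must carry `true_label` (or supply `true_labels`).
#' @param true_labels Optional named character vector of true labels by
#'   `fruit_id`, overriding `records_a$true_label`.
#' @param min_positive_precision Precision floor for positive calls.
#' @return One-row tibble: `t_a`, `t_b`, `accuracy`, `positive_precision`,
#'   `n_positive_calls`, `feasible`. When no grid point attains the precision
#'   floor, `feasible` is `FALSE` and the other fields are `NA`.
#' @export
threshold_search <- function(records_a, records_b, true_labels = NULL,
                             min_positive_precision = 0.8) {
  joined <- join_records(records_a, records_b)
  if (!is.null(true_labels)) {
    joined$true_label <- unname(true_labels[joined$fruit_id])
  }
  if (is.null(joined$true_label) || any(is.na(joined$true_label))) {
    abort("true labels are required for the threshold search")
  }
  truth_pos <- joined$true_label == "positive"
  grid_a <- sort(unique(c(0.5, joined$conf_a[joined$conf_a >= 0.5])))
  grid_b <- sort(unique(c(0.5, joined$conf_b[joined$conf_b >= 0.5])))

  best <- NULL
  for (ta in grid_a) {
    call_a <- joined$conf_a >= ta
    for (tb in grid_b) {
      pos_call <- call_a & joined$conf_b >= tb
      n_pos <- sum(pos_call)
      precision <- if (n_pos > 0) sum(pos_call & truth_pos) / n_pos else NA_real_
      ok <- if (min_positive_precision <= 0) TRUE else isTRUE(precision >= min_positive_precision)
      if (!ok) next
      acc <- mean(pos_call == truth_pos)
      prec_cmp <- if (is.na(precision)) -1 else precision
      cand <- list(t_a = ta, t_b = tb, accuracy = acc,
                   precision = precision, prec_cmp = prec_cmp, n_pos = n_pos)
      if (is.null(best) ||
          acc > best$accuracy ||
          (acc == best$accuracy && prec_cmp > best$prec_cmp) ||
          (acc == best$accuracy && prec_cmp == best$prec_cmp &&
             (ta < best$t_a || (ta == best$t_a && tb < best$t_b)))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(tibble(t_a = NA_real_, t_b = NA_real_, accuracy = NA_real_,
                  positive_precision = NA_real_, n_positive_calls = NA_integer_,
                  feasible = FALSE))
  }
  tibble(t_a = best$t_a, t_b = best$t_b, accuracy = best$accuracy,
         positive_precision = best$precision,
         n_positive_calls = as.integer(best$n_pos), feasible = TRUE)
}

#' Select extreme-confidence samples
#'
#' Positives are the `k_pos` fruits with the highest `min(conf_A, conf_B)`
#' (highest confidence by both models); negatives are, among the remaining
#' fruits, the `k_neg` with the lowest `max(conf_A, conf_B)` (low confidence
#' under both). Ties and ordering fall back to `fruit_id` order, so the
#' selection is invariant to record order.
#'
#' @param records_a,records_b Prediction tibbles matched by `fruit_id`.
#' @param k_pos,k_neg Number of positive / negative samples to select.
#' @return Tibble with columns `fruit_id`, `role` (`"positive"`/`"negative"`),
#'   `score` (the ranking score used).
#' @export
select_extreme_samples <- function(records_a, records_b, k_pos = 10L, k_neg = 10L) {
  joined <- join_records(records_a, records_b)
  if (k_pos + k_neg > nrow(joined)) {
    abort("k_pos + k_neg exceeds the number of matched records")
  }
  joined <- joined |>
    dplyr::mutate(score_pos = pmin(.data$conf_a, .data$conf_b),
                  score_neg = pmax(.data$conf_a, .data$conf_b)) |>
    dplyr::arrange(.data$fruit_id)
  pos <- joined |>
    dplyr::arrange(dplyr::desc(.data$score_pos), .data$fruit_id) |>
    head(k_pos)
  neg <- joined |>
    dplyr::filter(!.data$fruit_id %in% pos$fruit_id) |>
    dplyr::arrange(.data$score_neg, .data$fruit_id) |>
    head(k_neg)
  dplyr::bind_rows(
    tibble(fruit_id = pos$fruit_id, role = "positive", score = pos$score_pos),
    tibble(fruit_id = neg$fruit_id, role = "negative", score = neg$score_neg)
  )
}

#' Confidence scatter of two models
#'
#' @param records_a,records_b Prediction tibbles matched by `fruit_id`.
#' @return A ggplot: model A confidence against model B confidence, coloured
#'   by true label when available.
#' @export
plot_confidence_scatter <- function(records_a, records_b) {
  joined <- join_records(records_a, records_b)
  r <- tryCatch(confidence_correlation(records_a, records_b), error = function(e) NA_real_)
  aes <- if (!is.null(joined$true_label)) {
    ggplot2::aes(x = .data$conf_a, y = .data$conf_b, colour = .data$true_label)
  } else {
    ggplot2::aes(x = .data$conf_a, y = .data$conf_b)
  }
  ggplot2::ggplot(joined, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Model A confidence (positive)",
                  y = "Model B confidence (positive)",
                  colour = "true label",
                  title = sprintf("Confidence scatter (r = %.3f)", r)) +
    ggplot2::theme_minimal()
}
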