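# Negative-binomial RNA-seq count simulator with the three-group, paired,
# heterogeneous design of the fruit study: 10 featured samples from predicted
# rapid-softening fruits (RS-F), of which 4 fruits also yield a non-featured
# sample (RS-NF), and 10 featured samples from predicted control fruits
# (C-F). Fruit-level (criteria i) effects are expressed in only a fraction of
# the RS fruits ("responders"), and one control fruit is mislabelled (a
# wrongly predicted control carrying the full RS effect). Region-level
# (criteria ii) effects distinguish the featured from the non-featured sample
# within each paired fruit.

#' Configuration for the paired NB count simulation
#'
#' @param n_genes Number of genes.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of
#'   coding-sequence lengths (bp); lengths are floored at 150 bp.
#' @param baseline_log2_mean,baseline_log2_sd Normal parameters of the
#'   per-gene baseline log2 relative expression.
#' @param dispersion_shape,dispersion_rate Gamma parameters of the per-gene
#'   NB dispersion (defaults give mean 0.2, bulk of mass in ~0.05-0.5).
#' @param n_fruits_rs Number of predicted rapid-softening fruits (one RS-F
#'   sample each).
#' @param n_paired How many RS fruits also yield an RS-NF sample.
#' @param n_fruits_c Number of predicted control fruits (one C-F sample each).
#' @param frac_up,frac_down Fractions of genes planted as fruit-level
#'   (criteria i) up-/down-regulated in responder RS fruits.
#' @param effect_lfc Criteria-(i) log2 fold-change magnitude.
#' @param responder_fraction Fraction of RS fruits actually expressing the
#'   criteria-(i) effect (the study saw roughly half).
#' @param mislabeled_controls Number of control fruits carrying the full RS
#'   effect (a wrong prediction; the study had one).
#' @param frac_up_paired,frac_down_paired Fractions of genes planted as
#'   region-level (criteria ii) up-/down-regulated in RS-F relative to RS-NF.
#' @param paired_effect_lfc Criteria-(ii) log2 fold-change magnitude.
#' @param fruit_random_effect_sd SD (log2) of the per-gene, per-fruit random
#'   effect shared by both samples of a fruit — the reason a paired test is
#'   more powerful than an unpaired one here.
#' @param libsize_range Range of target library sizes, reads.
#' @param seed Simulation seed.
#' @return A `count_sim_config` list.
#' @export
count_sim_config <- function(n_genes = 10000L,
                             gene_length_meanlog = log(1200), gene_length_sdlog = 0.6,
                             baseline_log2_mean = 4, baseline_log2_sd = 2,
                             dispersion_shape = 2.5, dispersion_rate = 12.5,
                             n_fruits_rs = 10L, n_paired = 4L, n_fruits_c = 10L,
                             frac_up = 0.05, frac_down = 0.05, effect_lfc = 2,
                             responder_fraction = 0.5, mislabeled_controls = 1L,
                             frac_up_paired = 0.03, frac_down_paired = 0.03,
                             paired_effect_lfc = 2,
                             fruit_random_effect_sd = 0.5,
                             libsize_range = c(5e6, 15e6),
                             seed = 1L) {
  if (n_paired > n_fruits_rs) abort("n_paired cannot exceed n_fruits_rs")
  if (mislabeled_controls > n_fruits_c) abort("mislabeled_controls cannot exceed n_fruits_c")
  fr <- c(frac_up, frac_down, frac_up_paired, frac_down_paired)
  if (any(fr < 0 | fr > 1) || frac_up + frac_down + frac_up_paired + frac_down_paired > 1) {
    abort("DEG fractions must be in [0, 1] and sum to at most 1")
  }
  assert_scalar_number(responder_fraction, "responder_fraction", 0, 1)
  assert_range(libsize_range, "libsize_range", lower = 1)
  structure(as.list(environment()), class = "count_sim_config")
}

#' Simulate a paired NB count matrix with planted DEG truth
#'
#' Counts are NB with mean `library_size x relative expression`, where the
#' per-gene relative expression combines a length-aware baseline, a per-fruit
#' random effect shared by both samples of a fruit, the fruit-level criteria-
#' (i) effect (responder RS fruits and mislabelled controls, both samples of
#' the fruit, so it cancels in the paired contrast), and the region-level
#' criteria-(ii) effect (featured RS-F sample only, all paired fruits). An
#' effect magnitude of zero empties the corresponding truth set.
#'
#' @param config A [count_sim_config()].
#' @param return_means Also return the `expected_mu` matrix of NB means used
#'   for every draw (for moment checks).
#' @return A `count_sim`: list with `counts` (genes x samples integer matrix),
#'   `gene_lengths` (bp), `sample_meta` (tibble: `sample_id`, `group`,
#'   `fruit_id`, `library_size`), and `truth` (planted gene-id sets
#'   `degs_criteria_i_up/down`, `degs_criteria_ii_up/down`, `responder_fruits`,
#'   `mislabeled_controls`).
#' @export
simulate_counts <- function(config = count_sim_config(), return_means = FALSE) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(as.integer(config$seed))
  g <- config$n_genes
  gene_ids <- sprintf("gene_%05d", seq_len(g))
  lengths <- pmax(150, rlnorm(g, config$gene_length_meanlog, config$gene_length_sdlog))
  baseline <- rnorm(g, config$baseline_log2_mean, config$baseline_log2_sd)
  dispersion <- rgamma(g, config$dispersion_shape, config$dispersion_rate)

  # sample layout: RS-F per RS fruit, RS-NF for the first n_paired RS fruits,
  # C-F per control fruit
  rs_fruits <- sprintf("rs_%02d", seq_len(config$n_fruits_rs))
  c_fruits <- sprintf("c_%02d", seq_len(config$n_fruits_c))
  paired_fruits <- rs_fruits[seq_len(config$n_paired)]
  meta <- dplyr::bind_rows(
    tibble(sample_id = paste0(rs_fruits, "_F"), group = "RS-F", fruit_id = rs_fruits),
    tibble(sample_id = paste0(paired_fruits, "_NF"), group = "RS-NF", fruit_id = paired_fruits),
    tibble(sample_id = paste0(c_fruits, "_F"), group = "C-F", fruit_id = c_fruits)
  )
  n_samples <- nrow(meta)

  # planted truth
  pick <- function(pool, frac) {
    n <- round(frac * g)
    if (n == 0) character() else sample(pool, n)
  }
  avail <- gene_ids
  i_up <- pick(avail, config$frac_up); avail <- setdiff(avail, i_up)
  i_down <- pick(avail, config$frac_down); avail <- setdiff(avail, i_down)
  ii_up <- pick(avail, config$frac_up_paired); avail <- setdiff(avail, ii_up)
  ii_down <- pick(avail, config$frac_down_paired)
  if (config$effect_lfc == 0) i_up <- i_down <- character()
  if (config$paired_effect_lfc == 0) ii_up <- ii_down <- character()

  n_resp <- round(config$responder_fraction * config$n_fruits_rs)
  responders <- if (n_resp > 0) sample(rs_fruits, n_resp) else character()
  mislabeled <- if (config$mislabeled_controls > 0) {
    sample(c_fruits, config$mislabeled_controls)
  } else character()

  fruit_ids <- unique(meta$fruit_id)
  fruit_effect <- matrix(rnorm(g * length(fruit_ids), 0, config$fruit_random_effect_sd),
                         g, length(fruit_ids), dimnames = list(gene_ids, fruit_ids))

  sgn_i <- numeric(g); names(sgn_i) <- gene_ids
  sgn_i[i_up] <- 1; sgn_i[i_down] <- -1
  sgn_ii <- numeric(g); names(sgn_ii) <- gene_ids
  sgn_ii[ii_up] <- 1; sgn_ii[ii_down] <- -1

  target_libsize <- runif(n_samples, config$libsize_range[1], config$libsize_range[2])
  counts <- matrix(0L, g, n_samples, dimnames = list(gene_ids, meta$sample_id))
  expected_mu <- if (return_means) counts * 0
  for (j in seq_len(n_samples)) {
    fruit <- meta$fruit_id[j]
    log2mu <- baseline + fruit_effect[, fruit]
    if (fruit %in% responders || fruit %in% mislabeled) {
      log2mu <- log2mu + sgn_i * config$effect_lfc
    }
    if (meta$group[j] == "RS-F" && fruit %in% paired_fruits) {
      log2mu <- log2mu + sgn_ii * config$paired_effect_lfc
    }
    w <- (lengths / 1000) * 2^log2mu
    mu <- target_libsize[j] * w / sum(w)
    if (return_means) expected_mu[, j] <- mu
    counts[, j] <- rnbinom(g, mu = mu, size = 1 / pmax(dispersion, 1e-8))
  }
  meta$library_size <- unname(colSums(counts))

  structure(
    list(
      counts = counts,
      gene_lengths = setNames(lengths, gene_ids),
      sample_meta = meta,
      truth = list(
        degs_criteria_i_up = i_up, degs_criteria_i_down = i_down,
        degs_criteria_ii_up = ii_up, degs_criteria_ii_down = ii_down,
        responder_fruits = responders, mislabeled_controls = mislabeled
      ),
      expected_mu = expected_mu,
      dispersion = setNames(dispersion, gene_ids),
      config = config
    ),
    class = "count_sim"
  )
}

#' Write a count simulation to disk
#'
#' Counts as a genes x samples TSV, metadata as TSV, truth sets as JSON.
#'
#' @param sim A `count_sim`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_count_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    meta = file.path(dir, "sample_meta.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write.table(sim$counts, paths["counts"], sep = "\t", quote = FALSE)
  write.table(sim$sample_meta, paths["meta"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(gene_id = names(sim$gene_lengths), length_bp = sim$gene_lengths),
    paths["lengths"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(sim$truth, paths["truth"], pretty = TRUE)
  invisible(paths)
}
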