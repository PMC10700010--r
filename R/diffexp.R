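# The two-criteria differential-expression stage: RPKM computation and
# expression filtering, the unpaired RS-F vs C-F contrast (DESeq2 Wald), the
# paired RS-F vs RS-NF contrast (edgeR GLM with fruit as a blocking factor),
# DEG overlap and fold-change concordance, the PCA summary, and
# hypergeometric gene-set enrichment.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (length_kb * libsize_millions)`.
#'
#' @param counts Genes x samples count matrix.
#' @param gene_lengths Gene lengths in bp, aligned with rows.
#' @param library_sizes Per-sample library sizes; defaults to column sums.
#' @return RPKM matrix of the same shape.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  stopifnot(nrow(counts) == length(gene_lengths))
  if (any(gene_lengths <= 0)) abort("gene lengths must be positive")
  if (any(library_sizes <= 0)) abort("library sizes must be positive")
  sweep(counts / (gene_lengths / 1000), 2, library_sizes / 1e6, "/")
}

#' Expression filter on group-mean RPKM
#'
#' A gene is retained iff its mean RPKM exceeds the threshold (strictly) in
#' at least one of the two compared groups.
#'
#' @param rpkm_matrix RPKM matrix (genes x samples, rownames = gene ids).
#' @param groups Group label per sample.
#' @param group_pair The two groups compared.
#' @param threshold RPKM threshold (strict inequality).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(rpkm_matrix, groups, group_pair = c("RS-F", "C-F"),
                             threshold = 1) {
  stopifnot(length(groups) == ncol(rpkm_matrix), length(group_pair) == 2)
  for (gp in group_pair) {
    if (!any(groups == gp)) abort(sprintf("group '%s' has no samples", gp))
  }
  m1 <- rowMeans(rpkm_matrix[, groups == group_pair[1], drop = FALSE])
  m2 <- rowMeans(rpkm_matrix[, groups == group_pair[2], drop = FALSE])
  rownames(rpkm_matrix)[m1 > threshold | m2 > threshold]
}

deg_table <- function(gene, log2fc, p, criteria, mean_rpkm_num = NA_real_,
                      mean_rpkm_den = NA_real_) {
  tibble(
    gene = gene,
    log2fc = log2fc,
    p = p,
    fdr = p.adjust(p, "BH"),
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none")),
    criteria = criteria,
    mean_rpkm_num = mean_rpkm_num,
    mean_rpkm_den = mean_rpkm_den
  )
}

rpkm_group_means <- function(counts, gene_lengths, keep_samples, groups, pair) {
  if (is.null(gene_lengths)) return(list(num = NA_real_, den = NA_real_))
  r <- rpkm(counts, gene_lengths)
  list(
    num = rowMeans(r[, keep_samples & groups == pair[1], drop = FALSE]),
    den = rowMeans(r[, keep_samples & groups == pair[2], drop = FALSE])
  )
}

#' Unpaired differential expression (criteria i, RS-F vs C-F)
#'
#' DESeq2 Wald test of the `numerator` group against the `denominator` group
#' across fruits: NB GLM per gene with trended, shrunken dispersion
#' estimates. Independent filtering and Cook's-distance screening are
#' disabled so every tested gene reports a p-value; all-zero genes get
#' `p = 1`, `log2fc = 0` by convention. The significance convention of this
#' contrast is raw `P < 0.05`.
#'
#' @param counts Genes x samples integer count matrix.
#' @param groups Group label per sample (columns).
#' @param numerator,denominator Groups contrasted; the log2 fold change is
#'   numerator over denominator.
#' @param gene_lengths Optional lengths (bp) used to report group-mean RPKM.
#' @return A `DEGTable` tibble: `gene`, `log2fc`, `p`, `fdr` (BH),
#'   `direction`, `criteria`, `mean_rpkm_num`, `mean_rpkm_den`.
#' @export
de_unpaired <- function(counts, groups, numerator = "RS-F", denominator = "C-F",
                        gene_lengths = NULL) {
  keep <- groups %in% c(numerator, denominator)
  if (sum(groups == numerator) < 2 || sum(groups == denominator) < 2) {
    abort("need at least two samples per group")
  }
  sub <- counts[, keep, drop = FALSE]
  grp <- factor(groups[keep], levels = c(denominator, numerator))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = sub,
    colData = S4Vectors::DataFrame(group = grp),
    design = ~group
  )
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, contrast = c("group", numerator, denominator),
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  lfc <- res$log2FoldChange
  p <- res$pvalue
  zero <- rowSums(sub) == 0
  lfc[zero | is.na(lfc)] <- 0
  p[zero | is.na(p)] <- 1
  means <- rpkm_group_means(counts, gene_lengths, keep, groups,
                            c(numerator, denominator))
  deg_table(rownames(sub), lfc, p, "i", means$num, means$den)
}

#' Paired differential expression (criteria ii, RS-F vs RS-NF)
#'
#' edgeR NB GLM with fruit identity as a blocking factor
#' (`~ fruit + group`), quasi-likelihood F-test on the group coefficient:
#' within-fruit region differences are tested against within-fruit
#' variability. The significance convention of this contrast is BH
#' `FDR < 0.1`.
#'
#' @param counts Genes x samples integer count matrix.
#' @param groups Group label per sample.
#' @param fruit_ids Fruit identity per sample; every tested fruit must
#'   contribute exactly one sample of each group (a complete pair).
#' @param numerator,denominator Groups contrasted.
#' @param gene_lengths Optional lengths (bp) used to report group-mean RPKM.
#' @return A `DEGTable` tibble as in [de_unpaired()], `criteria = "ii"`.
#' @export
de_paired <- function(counts, groups, fruit_ids, numerator = "RS-F",
                      denominator = "RS-NF", gene_lengths = NULL) {
  keep <- groups %in% c(numerator, denominator)
  grp0 <- groups[keep]
  fruit0 <- fruit_ids[keep]
  tab <- table(fruit0, grp0)
  if (any(tab > 1)) {
    abort("ambiguous pairing: a fruit has more than one sample in a group")
  }
  # only fruits contributing one sample of each group form pairs; fruits
  # without a partner (e.g. RS-F fruits lacking an RS-NF sample) are dropped
  complete <- rownames(tab)[tab[, numerator] == 1 & tab[, denominator] == 1]
  if (length(complete) < 3) abort("need at least three complete pairs")
  keep[keep] <- fruit0 %in% complete
  sub <- counts[, keep, drop = FALSE]
  grp <- groups[keep]
  fruit <- fruit_ids[keep]
  grp <- factor(grp, levels = c(denominator, numerator))
  fruit <- factor(fruit)
  design <- stats::model.matrix(~ fruit + grp)
  dge <- edgeR::DGEList(counts = sub)
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmQLFit(dge, design)
  test <- edgeR::glmQLFTest(fit, coef = ncol(design))
  tt <- test$table
  lfc <- tt$logFC
  p <- tt$PValue
  zero <- rowSums(sub) == 0
  lfc[zero | is.na(lfc)] <- 0
  p[zero | is.na(p)] <- 1
  means <- rpkm_group_means(counts, gene_lengths, keep, groups,
                            c(numerator, denominator))
  deg_table(rownames(sub), lfc, p, "ii", means$num, means$den)
}

#' DEG overlap and fold-change concordance between the two criteria
#'
#' DEGs are `p < p_threshold` in criteria (i) and `fdr < fdr_threshold` in
#' criteria (ii); the common up/down counts require matching direction, and
#' the Pearson correlation of log2 fold changes is computed over the union of
#' the two DEG sets.
#'
#' @param table_i,table_ii `DEGTable` tibbles over a shared gene universe.
#' @param p_threshold Raw-p cutoff for criteria (i).
#' @param fdr_threshold BH-FDR cutoff for criteria (ii).
#' @return One-row tibble: `common_up`, `common_down`, `r`, `n_union`,
#'   `n_deg_i`, `n_deg_ii`. `r` is `NA` when the union is empty.
#' @export
overlap_and_concordance <- function(table_i, table_ii,
                                    p_threshold = 0.05, fdr_threshold = 0.1) {
  shared <- intersect(table_i$gene, table_ii$gene)
  ti <- table_i[match(shared, table_i$gene), ]
  tii <- table_ii[match(shared, table_ii$gene), ]
  deg_i <- ti$p < p_threshold
  deg_ii <- tii$fdr < fdr_threshold
  common_up <- sum(deg_i & deg_ii & ti$direction == "up" & tii$direction == "up")
  common_down <- sum(deg_i & deg_ii & ti$direction == "down" & tii$direction == "down")
  union_sel <- deg_i | deg_ii
  r <- if (sum(union_sel) >= 3) {
    suppressWarnings(cor(ti$log2fc[union_sel], tii$log2fc[union_sel]))
  } else {
    NA_real_
  }
  tibble(common_up = common_up, common_down = common_down, r = r,
         n_union = sum(union_sel), n_deg_i = sum(deg_i), n_deg_ii = sum(deg_ii))
}

#' Expression PCA with per-component group tests
#'
#' PCA on `log2(RPKM + 1)`, gene-centred; reports the variance fraction of
#' every component, per-sample scores, and two-sided t-tests comparing every
#' pair of groups on each of the first `n_test_pcs` components.
#'
#' @param rpkm_matrix RPKM matrix (genes x samples).
#' @param groups Group label per sample.
#' @param n_test_pcs How many leading components to test.
#' @return An `expression_pca`: `var_frac` (numeric), `scores` (tibble:
#'   `sample_id`, `group`, `PC1`, `PC2`, ...), `tests` (tibble: `pc`,
#'   `group_1`, `group_2`, `p`).
#' @export
pca_expression <- function(rpkm_matrix, groups, n_test_pcs = 2L) {
  stopifnot(ncol(rpkm_matrix) >= 3)
  x <- log2(rpkm_matrix + 1)
  x <- x[apply(x, 1, sd) > 0, , drop = FALSE]
  if (nrow(x) == 0) abort("constant expression matrix: PCA undefined")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x, .name_repair = "minimal")
  scores <- dplyr::bind_cols(
    tibble(sample_id = colnames(rpkm_matrix), group = groups), scores
  )
  pairs <- utils::combn(unique(groups), 2, simplify = FALSE)
  tests <- purrr::map_dfr(seq_len(min(n_test_pcs, ncol(pc$x))), function(k) {
    purrr::map_dfr(pairs, function(pr) {
      a <- pc$x[groups == pr[1], k]; b <- pc$x[groups == pr[2], k]
      p <- if (length(a) >= 2 && length(b) >= 2) t.test(a, b)$p.value else NA_real_
      tibble(pc = paste0("PC", k), group_1 = pr[1], group_2 = pr[2], p = p)
    })
  })
  structure(list(var_frac = var_frac, scores = scores, tests = tests),
            class = "expression_pca")
}

#' @export
glance.expression_pca <- function(x, ...) {
  tibble(pc1_var_frac = x$var_frac[1],
         pc2_var_frac = if (length(x$var_frac) > 1) x$var_frac[2] else NA_real_,
         min_pc1_p = suppressWarnings(min(x$tests$p[x$tests$pc == "PC1"], na.rm = TRUE)),
         n_samples = nrow(x$scores))
}

#' @export
autoplot.expression_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2]),
      title = "Expression PCA (log2(RPKM + 1))"
    ) +
    ggplot2::theme_minimal()
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each gene set against the DEG set within
#' the universe, BH-adjusted across sets.
#'
#' @param deg_set Character vector of DEG ids (subset of `universe`).
#' @param gene_sets Named list of gene-id vectors.
#' @param universe Character vector of all tested gene ids.
#' @return Tibble: `set`, `set_size`, `overlap`, `p`, `fdr`, ordered by `p`.
#' @export
enrichment_hypergeometric <- function(deg_set, gene_sets, universe) {
  if (length(universe) == 0) abort("empty universe")
  deg_set <- intersect(deg_set, universe)
  res <- purrr::imap_dfr(gene_sets, function(genes, name) {
    genes <- intersect(genes, universe)
    k <- length(intersect(genes, deg_set))
    p <- phyper(k - 1, length(genes), length(universe) - length(genes),
                length(deg_set), lower.tail = FALSE)
    tibble(set = name, set_size = length(genes), overlap = k, p = p)
  })
  res$fdr <- p.adjust(res$p, "BH")
  dplyr::arrange(res, .data$p)
}

#' DEG heat map of normalised expression
#'
#' @param rpkm_matrix RPKM matrix.
#' @param genes Genes to draw (rows).
#' @param groups Group label per sample, used to order columns.
#' @return A ggplot tile map of per-gene z-scores of `log2(RPKM + 1)`.
#' @export
plot_deg_heatmap <- function(rpkm_matrix, genes, groups) {
  genes <- intersect(genes, rownames(rpkm_matrix))
  x <- log2(rpkm_matrix[genes, , drop = FALSE] + 1)
  z <- t(scale(t(x)))
  z[is.na(z)] <- 0
  ord <- order(groups)
  df <- tibble(
    gene = rep(genes, length(ord)),
    sample_id = rep(colnames(x)[ord], each = length(genes)),
    group = rep(groups[ord], each = length(genes)),
    z = as.vector(z[, ord])
  )
  df$sample_id <- factor(df$sample_id, levels = colnames(x)[ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group), scales = "free_x", space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z")
}
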